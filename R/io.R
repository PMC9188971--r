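#' Write / read a cohort on disk
#'
#' Storage layout: one delimited matrix file per participant per presentation
#' block (concept label column + one column per voxel), plus a JSON manifest
#' recording participants, language tags, block files, grid geometry and the
#' canonical concept order. Readers align rows by concept label, so files with
#' permuted rows round-trip to the same dataset.
#'
#' @param ds an [activation_dataset()].
#' @param dir output directory (created if needed).
#' @return `write_cohort()`: the manifest path, invisibly.
#'   `read_cohort()`: an [activation_dataset()].
#' @export
write_cohort <- function(ds, dir) {
  stopifnot(inherits(ds, "activation_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(ds$data)
  files <- vector("list", d[1L])
  for (p in seq_len(d[1L])) {
    pf <- character(d[2L])
    for (b in seq_len(d[2L])) {
      m <- ds$data[p, b, , ]
      df <- data.frame(concept = ds$concepts$labels, m, check.names = FALSE)
      colnames(df) <- c("concept", paste0("v", seq_len(d[4L])))
      fn <- sprintf("%s_block%02d.csv", ds$participant_ids[p], b)
      utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(dir, fn), row.names = FALSE, quote = FALSE)
      pf[b] <- fn
    }
    files[[p]] <- pf
  }
  manifest <- list(
    participants = ds$participant_ids,
    language = ds$language,
    blocks = stats::setNames(files, ds$participant_ids),
    grid = list(shape = ds$grid$shape,
                affine = ds$grid$affine,
                mask_index = which(ds$grid$mask) - 1L),
    concepts = list(labels = ds$concepts$labels,
                    categories = as.list(ds$concepts$categories),
                    word_length = as.list(ds$concepts$word_length))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @param manifest_path path to a manifest written by [write_cohort()].
#' @rdname write_cohort
#' @export
read_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  required <- c("participants", "language", "blocks", "grid", "concepts")
  missing <- setdiff(required, names(man))
  if (length(missing))
    stop("manifest missing required keys: ", paste(missing, collapse = ", "),
         " (required: ", paste(required, collapse = ", "), ")")
  dir <- dirname(manifest_path)
  shape <- as.integer(man$grid$shape)
  mask <- array(FALSE, dim = shape)
  mask[as.integer(man$grid$mask_index) + 1L] <- TRUE
  grid <- voxel_grid(shape, matrix(unlist(man$grid$affine), 4L, 4L), mask)
  wl <- if (length(man$concepts$word_length))
    unlist(man$concepts$word_length) else NULL
  cs <- concept_set(man$concepts$labels, unlist(man$concepts$categories), wl)
  nv <- n_voxels(grid)
  ids <- man$participants
  n_blocks <- length(man$blocks[[1L]])
  data <- array(NA_real_, dim = c(length(ids), n_blocks, length(cs$labels), nv),
                dimnames = list(ids, NULL, cs$labels, NULL))
  for (p in seq_along(ids)) {
    for (b in seq_len(n_blocks)) {
      fn <- file.path(dir, man$blocks[[ids[p]]][b])
      df <- utils::read.csv(fn, check.names = FALSE)
      m <- as.matrix(df[, -1L, drop = FALSE])
      if (ncol(m) != nv)
        stop(sprintf("participant file %s has %d voxels, expected %d",
                     basename(fn), ncol(m), nv))
      rows <- match(cs$labels, df[[1L]])
      if (anyNA(rows))
        stop(sprintf("participant file %s missing concepts", basename(fn)))
      data[p, b, , ] <- m[rows, , drop = FALSE]
    }
  }
  activation_dataset(data, ids, man$language, grid, cs, check = FALSE)
}
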