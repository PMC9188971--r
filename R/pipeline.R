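#' Combine two cohorts into one dataset
#'
#' Stacks participants of two cohorts sharing a grid, concept set and block
#' count; language tags are preserved per participant.
#'
#' @param dsA,dsB [activation_dataset()]s on the same grid and concepts.
#' @return A combined [activation_dataset()].
#' @export
combine_cohorts <- function(dsA, dsB) {
  stopifnot(inherits(dsA, "activation_dataset"),
            inherits(dsB, "activation_dataset"))
  if (!identical(dsA$concepts$labels, dsB$concepts$labels) ||
      !identical(dim(dsA$data)[2:4], dim(dsB$data)[2:4]))
    stop("cohorts must share concepts, blocks and grid")
  d <- dim(dsA$data)
  nd <- c(d[1L] + dim(dsB$data)[1L], d[2:4])
  dat <- array(NA_real_, dim = nd,
               dimnames = list(c(dsA$participant_ids, dsB$participant_ids),
                               NULL, dsA$concepts$labels, NULL))
  dat[seq_len(d[1L]), , , ] <- dsA$data
  dat[d[1L] + seq_len(dim(dsB$data)[1L]), , , ] <- dsB$data
  activation_dataset(dat, c(dsA$participant_ids, dsB$participant_ids),
                     c(dsA$language, dsB$language), dsA$grid, dsA$concepts,
                     check = FALSE)
}

#' Synthetic region labels for a grid
#'
#' Partitions the in-mask voxels into contiguous runs, one per region of an
#' allocation, with region sizes proportional to the allocated counts. Used
#' to exercise the per-region voxel allocation on simulated data, standing in
#' for an anatomical parcellation.
#'
#' @param grid a [voxel_grid()].
#' @param allocation named region -> count vector
#'   (default [default_roi_allocation()]).
#' @return Character vector of length `n_voxels(grid)` of region names.
#' @export
synthetic_roi_labels <- function(grid, allocation = default_roi_allocation()) {
  nv <- n_voxels(grid)
  total <- sum(allocation)
  if (nv < total)
    stop("grid too small for the allocation")
  sizes <- pmax(floor(nv * allocation / total), allocation)
  while (sum(sizes) > nv) sizes[which.max(sizes - allocation)] <-
    sizes[which.max(sizes - allocation)] - 1L
  sizes[length(sizes)] <- sizes[length(sizes)] + (nv - sum(sizes))
  rep(names(allocation), times = sizes)
}

#' Pipeline configuration
#'
#' Collects every stage parameter in one serializable list: the generator
#' spec, feature counts, factor counts, clustering thresholds, permutation
#' iterations and the master seed.
#'
#' @param spec a [generative_spec()] (simulation source of the cohorts).
#' @param k stable voxels used as classifier features.
#' @param roi_allocation named region allocation for the factor-analysis
#'   voxels.
#' @param n_factors_first,n_factors_second factor counts for the two levels.
#' @param threshold,min_cluster,connectivity,sphere_radius
#'   [factor_locations()] parameters.
#' @param n_perm permutation iterations for significance tests.
#' @param seed master RNG seed.
#' @param out_dir optional output directory; when set, tables and a JSON
#'   manifest are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(spec = generative_spec(), k = 120L,
                       roi_allocation = default_roi_allocation(),
                       n_factors_first = 7L, n_factors_second = 6L,
                       threshold = 0.4, min_cluster = 15L,
                       connectivity = 6L, sphere_radius = 6,
                       n_perm = 1000L, seed = 1L, out_dir = NULL) {
  structure(list(spec = spec, k = k, roi_allocation = roi_allocation,
                 n_factors_first = n_factors_first,
                 n_factors_second = n_factors_second,
                 threshold = threshold, min_cluster = min_cluster,
                 connectivity = connectivity, sphere_radius = sphere_radius,
                 n_perm = n_perm, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) two cohorts, then: cross-participant stability and
#' per-region voxel allocation; within-participant, between-participant and
#' factor-location-based cross-language decoding; two-level factor analysis
#' (per cohort and combined) with factor matching across cohorts; and
#' rating-based leave-one-concept-out encoding against synthetic ratings.
#' When `config$out_dir` is set, writes the per-concept accuracy table, the
#' factor-score extremes table, the cross-cohort factor correlation matrix,
#' and a JSON manifest holding the full configuration and seed.
#'
#' @param config a [run_config()].
#' @param cohorts optional named list of two [activation_dataset()]s; by
#'   default [simulate_cohorts()] is run on `config$spec`.
#' @return A list of class `pipeline_result` with elements `decode`
#'   (within/between per cohort, cross-language), `factors` (per-cohort and
#'   combined second-level solutions, match, locations), `encoding`, `table2`
#'   and `config`.
#' @export
run_pipeline <- function(config = run_config(), cohorts = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (is.null(cohorts)) {
    sim <- simulate_cohorts(config$spec)
    cohorts <- sim$cohorts
    truth <- sim$truth
  }
  stopifnot(length(cohorts) == 2L)
  cohort_names <- names(cohorts)
  combined <- combine_cohorts(cohorts[[1L]], cohorts[[2L]])

  # stability + factor-analysis voxel allocation
  stab_all <- voxel_stability_between(combined)
  roi <- synthetic_roi_labels(combined$grid, config$roi_allocation)
  fa_voxels <- allocate_by_roi(stab_all, roi, config$roi_allocation)

  # decoding: within and between, per cohort
  decode <- list()
  for (g in seq_along(cohorts)) {
    ds <- cohorts[[g]]
    wacc <- lapply(seq_along(ds$participant_ids), function(p)
      within_participant_cv(ds, p, k = config$k))
    per_concept <- Reduce(`+`, lapply(wacc, `[[`, "per_concept")) /
      length(wacc)
    decode[[paste0(cohort_names[g], "_within")]] <-
      new_decode_result("within_participant", per_concept,
                        sum(vapply(wacc, `[[`, 0L, "folds")),
                        unlist(lapply(wacc, `[[`, "posteriors"),
                               recursive = FALSE))
    decode[[paste0(cohort_names[g], "_between")]] <-
      between_participant_cv(ds, k = config$k)
  }

  # two-level factor analysis: per cohort and combined
  fl_all <- lapply(seq_along(combined$participant_ids), function(p)
    first_level(combined, p, fa_voxels, config$n_factors_first))
  names(fl_all) <- combined$participant_ids
  by_cohort <- split(seq_along(combined$language), combined$language)
  sl_cohort <- lapply(by_cohort, function(idx)
    second_level(fl_all[idx], config$n_factors_second))
  sl_combined <- second_level(fl_all, config$n_factors_second)
  fmatch <- match_factors(sl_cohort[[1L]], sl_cohort[[2L]])

  # factor locations of the combined solution (mean first-level loading per
  # voxel, weighted by each first-level factor's match to the group factor)
  locs <- combined_factor_locations(sl_combined, fl_all, combined$grid,
                                    fa_voxels, config)

  # cross-language decoding on the factor-location voxels
  loc_vox <- sphere_voxels(locs, combined$grid)
  if (!length(loc_vox)) loc_vox <- fa_voxels
  decode$cross_language <- cross_language_classify(cohorts[[1L]],
                                                   cohorts[[2L]],
                                                   feature_voxels = loc_vox)

  # rating-based encoding (synthetic ratings from planted truth when known)
  encoding <- NULL
  if (!is.null(truth)) {
    ratings <- synthetic_ratings(truth, seed = config$seed)
    encoding <- encode_evaluate(combined, ratings, loc_vox,
                                n_perm = config$n_perm, seed = config$seed)
  }

  tab2 <- make_table2(decode, combined$concepts)
  result <- structure(
    list(decode = decode,
         factors = list(first_level = fl_all, second_level = sl_cohort,
                        combined = sl_combined, match = fmatch,
                        locations = locs, fa_voxels = fa_voxels),
         encoding = encoding, table2 = tab2, truth = truth,
         config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

# Project the group factor onto voxels: for each participant, take the
# first-level factor that best matches the group factor (|correlation| of
# score vectors), sign-align its voxel loadings, and average across the
# participants that express the factor (best-match |r| >= the loading
# threshold). Cohort-specific factors are thus located from the cohort that
# carries them instead of being diluted by the other cohort.
combined_factor_locations <- function(sl, first_levels, grid, fa_voxels,
                                      config) {
  n_group <- ncol(sl$factor_scores)
  locs <- vector("list", n_group)
  for (j in seq_len(n_group)) {
    gscore <- sl$factor_scores[, j]
    contrib <- vapply(first_levels, function(fl) {
      r <- stats::cor(fl$factor_scores, gscore)
      b <- which.max(abs(r))
      c(abs(r[b]), sign(r[b]) * fl$loadings[, b])
    }, numeric(1L + length(fa_voxels)))
    expressing <- contrib[1L, ] >= config$threshold
    if (!any(expressing)) expressing <- rep(TRUE, ncol(contrib))
    mean_loading <- rowMeans(contrib[-1L, expressing, drop = FALSE])
    locs[[j]] <- suppressWarnings(
      factor_locations(mean_loading, grid, fa_voxels,
                       threshold = config$threshold,
                       min_cluster = config$min_cluster,
                       connectivity = config$connectivity,
                       sphere_radius = config$sphere_radius,
                       factor = colnames(sl$factor_scores)[j]))
  }
  names(locs) <- colnames(sl$factor_scores)
  locs
}

#' Per-concept decoding accuracy table
#'
#' One row per concept (canonical category-block order) plus a Mean row; one
#' column per available decoding scheme.
#'
#' @param decode named list of `decode_result`s.
#' @param concepts the [concept_set()] fixing the row order.
#' @return A data frame with a `concept` column and one numeric column per
#'   scheme.
#' @export
make_table2 <- function(decode, concepts = default_concepts()) {
  stopifnot(length(decode) >= 1L)
  cols <- lapply(decode, function(d) d$per_concept[concepts$labels])
  tab <- data.frame(concept = concepts$labels, as.data.frame(cols),
                    check.names = FALSE)
  rownames(tab) <- NULL
  tab[nrow(tab) + 1L, ] <- c("Mean", as.list(colMeans(tab[, -1L, drop = FALSE])))
  tab
}

write_pipeline_outputs <- function(result) {
  out <- result$config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$table2, file.path(out, "decoding_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(result$factors$match$cross_correlation,
                   file.path(out, "factor_cross_correlation.csv"))
  sc <- result$factors$combined$factor_scores
  extremes <- do.call(rbind, lapply(colnames(sc), function(f) {
    ord <- order(sc[, f], decreasing = TRUE)
    data.frame(factor = f,
               rank = c(seq_len(6L), seq(nrow(sc) - 5L, nrow(sc))),
               concept = rownames(sc)[ord][c(1:6, (nrow(sc) - 5L):nrow(sc))],
               score = sc[ord, f][c(1:6, (nrow(sc) - 5L):nrow(sc))])
  }))
  utils::write.csv(extremes, file.path(out, "factor_score_extremes.csv"),
                   row.names = FALSE)
  manifest <- list(config = unclass_config(result$config),
                   seed = result$config$seed,
                   package_version = as.character(utils::packageVersion("neurodims")),
                   decode_means = lapply(result$decode, `[[`, "mean"))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

unclass_config <- function(config) {
  cf <- unclass(config)
  cf$spec <- unclass(cf$spec)
  cf
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (nm in names(x$decode))
    cat(sprintf("  %-20s mean rank accuracy %.3f\n", nm, x$decode[[nm]]$mean))
  if (!is.null(x$encoding))
    cat(sprintf("  %-20s grand mean %.3f (p = %.2g)\n", "encoding",
                x$encoding$grand_mean, x$encoding$p_value))
  cat(sprintf("  matched cross-cohort factors: mean |r| = %.3f\n",
              mean(x$factors$match$pairs$abs_r)))
  invisible(x)
}
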