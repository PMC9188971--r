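#' Voxel stability maps
#'
#' A voxel is stable when its tuning curve — the vector of its activation
#' levels across the concepts — is reproducible. Stability is the mean
#' pairwise Pearson correlation of the voxel's tuning curves, either across
#' presentation blocks within one participant (`voxel_stability_within`) or
#' across participants after presentation-averaging
#' (`voxel_stability_between`). Voxels whose tuning curve has zero variance
#' in some unit are flagged undefined (`NA`) and excluded from ranking.
#'
#' @param ds an [activation_dataset()].
#' @param participant participant index or id.
#' @param blocks presentation blocks to use (training blocks only; default
#'   all). At least 2.
#' @return An object of class `stability_map`: per-voxel scores in [-1, 1]
#'   (or `NA`), with `mode` and `source` provenance fields.
#' @export
voxel_stability_within <- function(ds, participant, blocks = NULL) {
  stopifnot(inherits(ds, "activation_dataset"))
  if (is.character(participant))
    participant <- match(participant, ds$participant_ids)
  if (is.null(blocks)) blocks <- seq_len(dim(ds$data)[2L])
  if (length(blocks) < 2L) stop("need at least 2 blocks")
  curves <- lapply(blocks, function(b) ds$data[participant, b, , ])
  scores <- mean_pairwise_cor(curves)
  new_stability_map(scores, "within_participant",
                    list(participant = ds$participant_ids[participant],
                         blocks = blocks))
}

#' @param participants participant indices or ids (training participants
#'   only; default all). At least 2. Data are presentation-averaged per
#'   participant before correlating.
#' @rdname voxel_stability_within
#' @export
voxel_stability_between <- function(ds, participants = NULL) {
  stopifnot(inherits(ds, "activation_dataset"))
  if (is.null(participants)) participants <- seq_len(dim(ds$data)[1L])
  if (is.character(participants))
    participants <- match(participants, ds$participant_ids)
  if (length(participants) < 2L) stop("need at least 2 participants")
  avg <- average_presentations(ds)
  curves <- avg[participants]
  scores <- mean_pairwise_cor(curves)
  new_stability_map(scores, "cross_participant",
                    list(participants = ds$participant_ids[participants]))
}

new_stability_map <- function(scores, mode, source) {
  structure(list(scores = scores, mode = mode, source = source),
            class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  ok <- !is.na(x$scores)
  cat(sprintf("stability_map (%s): %d voxels, %d defined, mean %.3f\n",
              x$mode, length(x$scores), sum(ok),
              mean(x$scores[ok])))
  invisible(x)
}

# mean over all unit pairs of the per-voxel Pearson correlation of
# concept-tuning curves; curves: list of concept x voxel matrices
mean_pairwise_cor <- function(curves) {
  nv <- ncol(curves[[1L]])
  n <- length(curves)
  centered <- lapply(curves, function(m) sweep(m, 2L, colMeans(m)))
  ss <- vapply(centered, function(m) colSums(m^2), numeric(nv))
  dead <- matrix(ss == 0, nrow = nv)
  acc <- numeric(nv)
  npair <- 0L
  for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
    num <- colSums(centered[[a]] * centered[[b]])
    den <- sqrt(ss[, a] * ss[, b])
    acc <- acc + num / den
    npair <- npair + 1L
  }
  scores <- acc / npair
  scores[rowSums(dead) > 0L] <- NA_real_
  scores
}

#' Select the k most stable voxels
#'
#' @param map a `stability_map`.
#' @param k number of voxels to keep (default 120).
#' @return Integer vector of voxel indices, descending by score; ties broken
#'   by ascending voxel index.
#' @export
select_top_k <- function(map, k = 120L) {
  stopifnot(inherits(map, "stability_map"))
  ok <- which(!is.na(map$scores))
  if (k > length(ok))
    stop(sprintf("k = %d exceeds %d defined voxels", k, length(ok)))
  ord <- ok[order(-map$scores[ok], ok)]
  ord[seq_len(k)]
}

#' Allocate stable voxels per region of interest
#'
#' Selects, within each labeled region, that region's allocated number of
#' most stable voxels; the default allocation (40 + 30 + 60 + 60 + 60 + 160)
#' totals 410 voxels across six regions.
#'
#' @param map a `stability_map`.
#' @param roi_labels character vector (length = voxels) naming each voxel's
#'   region, or `NA` for voxels outside any region.
#' @param allocation named integer vector, region -> voxel count.
#' @return Integer vector of voxel indices (per-region top scores, regions in
#'   `allocation` order).
#' @export
allocate_by_roi <- function(map, roi_labels, allocation) {
  stopifnot(inherits(map, "stability_map"))
  if (length(roi_labels) != length(map$scores))
    stop("roi_labels must label every voxel")
  out <- integer(0)
  for (region in names(allocation)) {
    need <- allocation[[region]]
    if (need == 0L) next
    in_region <- which(roi_labels == region & !is.na(map$scores))
    if (length(in_region) < need)
      stop(sprintf("region '%s' has %d defined voxels, %d allocated",
                   region, length(in_region), need))
    ord <- in_region[order(-map$scores[in_region], in_region)]
    out <- c(out, ord[seq_len(need)])
  }
  out
}

#' The default per-region voxel allocation for the factor analysis
#'
#' Six broad regions contributing 40, 30, 60, 60, 60 and 160 voxels — a
#' total of 410 — in proportion to how densely stable voxels populate them.
#'
#' @return Named integer vector summing to 410.
#' @export
default_roi_allocation <- function() {
  c(left_ifg = 40L, left_posterior_cingulate = 30L, frontal = 60L,
    occipital = 60L, temporal = 60L, parietal = 160L)
}
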