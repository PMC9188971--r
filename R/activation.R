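#' Per-trial z-scoring across voxels
#'
#' Each trial's voxel vector is centered and scaled across voxels so that the
#' pattern, not the overall level, carries the signal. Sample SD (n - 1)
#' convention, matching [scale()].
#'
#' @param x numeric vector (one trial) or matrix (trials in rows).
#' @return Object of the same shape with each trial at mean 0, SD 1.
#' @export
ztrial <- function(x) {
  if (is.matrix(x)) {
    m <- rowMeans(x)
    s <- apply(x, 1L, stats::sd)
    if (any(s == 0)) stop("zero trial variance: trial(s) ",
                          paste(which(s == 0), collapse = ", "))
    return((x - m) / s)
  }
  s <- stats::sd(x)
  if (s == 0) stop("zero trial variance")
  (x - mean(x)) / s
}

#' Trial-level percent-signal-change time series
#'
#' Raw per-trial voxel time courses (percent signal change relative to the
#' fixation baseline, one image per second) before windowed averaging.
#' Onsets are 0-based sample offsets into the time axis: the image acquired
#' `t` seconds after the start of a trial's recording is sample `t`.
#'
#' @param values trial x voxel x second numeric array of PSC values.
#' @param onsets integer vector, 0-based stimulus onset sample per trial.
#' @param trial_labels character vector, concept per trial.
#' @param presentation_block integer vector, block index per trial; every
#'   concept must appear exactly once per block.
#' @return An object of class `trial_timeseries`.
#' @export
trial_timeseries <- function(values, onsets, trial_labels, presentation_block) {
  stopifnot(length(dim(values)) == 3L)
  n <- dim(values)[1L]
  if (length(onsets) != n || length(trial_labels) != n ||
      length(presentation_block) != n)
    stop("onsets, trial_labels, presentation_block must have one entry per trial")
  if (!all(is.finite(values))) stop("PSC values must be finite")
  for (b in unique(presentation_block)) {
    lab <- trial_labels[presentation_block == b]
    if (anyDuplicated(lab))
      stop(sprintf("duplicate concept within block %s: %s", b,
                   paste(unique(lab[duplicated(lab)]), collapse = ", ")))
  }
  structure(list(values = values, onsets = as.integer(onsets),
                 trial_labels = as.character(trial_labels),
                 presentation_block = as.integer(presentation_block)),
            class = "trial_timeseries")
}

#' Windowed mean activation per trial (MPSC)
#'
#' The activation evoked by a concept is the mean of the images acquired in a
#' window around the hemodynamic peak — by default the four images 5-8 s
#' after stimulus onset — z-scored across voxels within each trial. Output is
#' organized presentation x concept x voxel.
#'
#' @param ts a [trial_timeseries()].
#' @param window_offset seconds from onset to the first image in the window.
#' @param window_length number of one-second images averaged.
#' @return presentation x concept x voxel numeric array with concept dimnames,
#'   each trial vector at mean 0, SD 1 across voxels.
#' @export
compute_mpsc <- function(ts, window_offset = 5, window_length = 4) {
  stopifnot(inherits(ts, "trial_timeseries"))
  d <- dim(ts$values)
  n_trials <- d[1L]; n_vox <- d[2L]; n_t <- d[3L]
  first <- ts$onsets + window_offset        # 0-based sample index
  last <- first + window_length - 1L
  bad <- which(first < 0L | last > n_t - 1L)
  if (length(bad))
    stop("window exceeds trial span for trial(s) ",
         paste(bad, collapse = ", "))
  blocks <- sort(unique(ts$presentation_block))
  concepts <- unique(ts$trial_labels)
  out <- array(NA_real_,
               dim = c(length(blocks), length(concepts), n_vox),
               dimnames = list(NULL, concepts, NULL))
  for (tr in seq_len(n_trials)) {
    idx <- (first[tr]:last[tr]) + 1L
    v <- rowMeans(ts$values[tr, , idx, drop = FALSE][1, , ])
    b <- match(ts$presentation_block[tr], blocks)
    cc <- match(ts$trial_labels[tr], concepts)
    out[b, cc, ] <- ztrial(v)
  }
  if (anyNA(out)) stop("some (block, concept) cells have no trial")
  out
}

#' Cohort activation dataset
#'
#' The central container: a participant x presentation x concept x voxel
#' array of trial activation patterns (windowed-mean PSC, z-scored across
#' voxels per trial) on a shared [voxel_grid()], with a language tag per
#' participant and a common [concept_set()].
#'
#' @param data 4-d numeric array, participant x presentation x concept x
#'   voxel; the concept dimension must carry dimnames.
#' @param participant_ids character vector of participant identifiers.
#' @param language character vector (length 1 or one per participant).
#' @param grid a [voxel_grid()] with `n_voxels(grid) == dim(data)[4]`.
#' @param concepts a [concept_set()] matching the concept dimnames.
#' @param check if `TRUE` (default) verify per-trial normalization
#'   (mean 0, SD 1 across voxels within tolerance 1e-6).
#' @return An object of class `activation_dataset`.
#' @export
activation_dataset <- function(data, participant_ids, language, grid, concepts,
                               check = TRUE) {
  stopifnot(length(dim(data)) == 4L)
  d <- dim(data)
  if (length(participant_ids) != d[1L])
    stop("participant_ids length must match dim(data)[1]")
  language <- rep_len(as.character(language), d[1L])
  if (anyNA(data)) stop("activation data must have no missing values")
  labs <- dimnames(data)[[3L]]
  if (is.null(labs)) stop("concept dimension must carry dimnames")
  if (!setequal(labs, concepts$labels))
    stop("concept dimnames do not match the concept set")
  # canonical concept order
  data <- data[, , match(concepts$labels, labs), , drop = FALSE]
  if (n_voxels(grid) != d[4L])
    stop("grid mask size does not match voxel dimension")
  if (isTRUE(check)) {
    flat <- matrix(aperm(data, c(4L, 1L, 2L, 3L)), nrow = d[4L])
    mu <- colMeans(flat)
    sdv <- apply(flat, 2L, stats::sd)
    if (any(abs(mu) > 1e-6) || any(abs(sdv - 1) > 1e-6))
      stop("per-trial normalization violated (mean 0 / SD 1 across voxels)")
  }
  dimnames(data)[[1L]] <- as.character(participant_ids)
  structure(list(data = data,
                 participant_ids = as.character(participant_ids),
                 language = language, grid = grid, concepts = concepts),
            class = "activation_dataset")
}

#' @export
print.activation_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "activation_dataset: %d participants (%s), %d presentations, %d concepts, %d voxels\n",
    d[1L], paste(unique(x$language), collapse = "/"), d[2L], d[3L], d[4L]))
  invisible(x)
}

#' @export
dim.activation_dataset <- function(x) dim(x$data)

#' Average activation over presentation blocks
#'
#' Collapses the presentation dimension by arithmetic mean over a subset of
#' blocks, giving each participant one concept x voxel signature matrix.
#'
#' @param ds an [activation_dataset()].
#' @param which integer vector of block indices (default all).
#' @return List (one per participant, named) of concept x voxel matrices.
#' @export
average_presentations <- function(ds, which = NULL) {
  stopifnot(inherits(ds, "activation_dataset"))
  if (is.null(which)) which <- seq_len(dim(ds$data)[2L])
  if (length(which) == 0L) stop("block subset must be nonempty")
  out <- lapply(seq_len(dim(ds$data)[1L]), function(p) {
    sub <- ds$data[p, which, , , drop = FALSE]
    m <- colMeans(array(sub, dim = dim(sub)[2:4]))
    rownames(m) <- ds$concepts$labels
    m
  })
  names(out) <- ds$participant_ids
  out
}

#' Subset an activation dataset by participant
#' @param ds an [activation_dataset()].
#' @param participants indices or ids to keep.
#' @return An [activation_dataset()] restricted to those participants.
#' @export
subset_participants <- function(ds, participants) {
  if (is.character(participants))
    participants <- match(participants, ds$participant_ids)
  activation_dataset(ds$data[participants, , , , drop = FALSE],
                     ds$participant_ids[participants],
                     ds$language[participants], ds$grid, ds$concepts,
                     check = FALSE)
}
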