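#' Leave-one-concept-out encoding from behavioral ratings
#'
#' Per voxel, ordinary least squares of activation on the rating dimensions
#' (with intercept) over the training concepts, evaluated at the held-out
#' concept's ratings. With 27 training concepts and at most a handful of
#' dimensions the fit is well-posed without regularization.
#'
#' @param activations concept x voxel matrix (rownames = concepts).
#' @param ratings a [ratings_table()] or concept x dimension matrix.
#' @param holdout the concept to leave out and predict.
#' @return Numeric predicted voxel vector for `holdout`.
#' @export
fit_predict_loco <- function(activations, ratings, holdout) {
  rt <- if (inherits(ratings, "ratings_table")) ratings$values else as.matrix(ratings)
  concepts <- rownames(activations)
  if (is.null(concepts) || !all(concepts %in% rownames(rt)))
    stop("ratings not aligned to activation concepts")
  rt <- rt[concepts, , drop = FALSE]
  if (!holdout %in% concepts) stop("holdout concept not present")
  train <- setdiff(concepts, holdout)
  X <- cbind(`(Intercept)` = 1, rt[train, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient rating design; collinear dimension(s): ",
         paste(drop_cols, collapse = ", "))
  }
  B <- qr.coef(qx, activations[train, , drop = FALSE])
  as.vector(c(1, rt[holdout, ]) %*% B)
}

#' Euclidean-distance rank accuracy of a predicted pattern
#'
#' Ranks the Euclidean distance between the predicted pattern and every
#' concept's observed pattern; accuracy is `(N - r)/(N - 1)` for the true
#' concept's rank (average rank under ties).
#'
#' @param predicted numeric voxel vector.
#' @param observed_all concept x voxel matrix of observed patterns.
#' @param true_concept the concept `predicted` should match.
#' @return Accuracy in [0, 1].
#' @export
distance_rank_accuracy <- function(predicted, observed_all, true_concept) {
  if (length(predicted) != ncol(observed_all))
    stop("dimension mismatch between predicted and observed patterns")
  i <- match(true_concept, rownames(observed_all))
  if (is.na(i)) stop("true_concept absent")
  d <- sqrt(colSums((t(observed_all) - predicted)^2))
  r <- rank(d, ties.method = "average")[[i]]
  n <- nrow(observed_all)
  (n - r) / (n - 1)
}

# Hat rows for leave-pair-out prediction: row (i, j) maps the activation
# matrix (concepts x voxels) to the prediction for concept i when concepts
# i and j are both excluded from the fit. Returns the n*(n-1) x n matrix H
# (ordered pairs stacked i-major) plus the pair index.
lpo_hat_matrix <- function(rt) {
  n <- nrow(rt)
  X <- cbind(1, rt)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- c("(Intercept)", colnames(rt))[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient rating design; collinear dimension(s): ",
         paste(drop_cols, collapse = ", "))
  }
  pairs <- cbind(i = rep(seq_len(n), each = n - 1L),
                 j = unlist(lapply(seq_len(n), function(i) setdiff(seq_len(n), i))))
  H <- matrix(0, nrow(pairs), n)
  for (k in seq_len(nrow(pairs))) {
    keep <- setdiff(seq_len(n), pairs[k, ])
    Xt <- X[keep, , drop = FALSE]
    h <- X[pairs[k, 1L], , drop = FALSE] %*%
      solve(crossprod(Xt), t(Xt))
    H[k, keep] <- h
  }
  list(H = H, pairs = pairs)
}

# pair-comparison accuracies given hat rows and (possibly relabeled)
# activations; returns per-concept accuracy over the n-1 comparisons
lpo_accuracy <- function(hat, A) {
  P <- hat$H %*% A
  pi_ <- hat$pairs[, 1L]; pj <- hat$pairs[, 2L]
  dself <- rowSums(P^2) + rowSums(A^2)[pi_] - 2 * rowSums(P * A[pi_, , drop = FALSE])
  dother <- rowSums(P^2) + rowSums(A^2)[pj] - 2 * rowSums(P * A[pj, , drop = FALSE])
  wins <- (dself < dother) + 0.5 * (dself == dother)
  as.vector(tapply(wins, pi_, mean))
}

#' Evaluate rating-based encoding over a cohort
#'
#' For each participant, predicts every concept's activation pattern in the
#' factor-location voxels from the other concepts' ratings and scores how
#' reliably the prediction is closer (in Euclidean distance) to the held-out
#' concept's observed pattern than to the alternatives, averaging first over
#' concepts then over participants.
#'
#' Two scoring schemes are available. `"pair"` (default) excludes both the
#' predicted and the comparison concept from each fit, so every comparison
#' is out-of-sample: chance level is exactly 0.5 and the permutation test
#' (which relabels the observed patterns and re-derives the predictions) is
#' exactly calibrated. `"loco"` fits once per held-out concept and ranks its
#' distance among all observed patterns, permuting labels of the predicted
#' images with fits kept fixed; because the competing distances are
#' in-sample, this classic scheme carries a small pessimistic bias under the
#' null.
#'
#' @param ds an [activation_dataset()].
#' @param ratings a [ratings_table()] (use [average_ratings()] when two
#'   rater groups are available).
#' @param locations voxel indices, a `factor_location`, or a list of
#'   `factor_location`s (sphere voxels are used).
#' @param n_perm permutation iterations (default 1000).
#' @param seed RNG seed for the permutation test.
#' @param scoring `"pair"` (leave-pair-out, unbiased) or `"loco"` (single
#'   fit per held-out concept, distance ranked among all 28).
#' @return An object of class `encoding_result`: `per_concept` (averaged
#'   over participants), `per_participant` means, `grand_mean`, `p_value`,
#'   `predictions` (plain leave-one-concept-out predicted patterns),
#'   `n_perm`, `scoring`.
#' @export
encode_evaluate <- function(ds, ratings, locations, n_perm = 1000L,
                            seed = 1L, scoring = c("pair", "loco")) {
  stopifnot(inherits(ds, "activation_dataset"))
  scoring <- match.arg(scoring)
  vox <- if (is.numeric(locations)) as.integer(locations)
         else sphere_voxels(locations, ds$grid)
  if (!length(vox)) stop("no location voxels")
  concepts <- ds$concepts$labels
  n <- length(concepts)
  avg <- average_presentations(ds)
  np <- length(avg)
  rt <- if (inherits(ratings, "ratings_table")) ratings$values
        else as.matrix(ratings)
  rt <- rt[concepts, , drop = FALSE]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  acc <- matrix(NA_real_, np, n, dimnames = list(ds$participant_ids, concepts))
  predictions <- vector("list", np)
  null_parts <- matrix(NA_real_, np, n_perm)

  if (scoring == "pair") {
    hat <- lpo_hat_matrix(rt)
    perms <- lapply(seq_len(n_perm), function(it) sample.int(n))
    for (p in seq_len(np)) {
      A <- avg[[p]][, vox, drop = FALSE]
      acc[p, ] <- lpo_accuracy(hat, A)
      null_parts[p, ] <- vapply(perms, function(perm)
        mean(lpo_accuracy(hat, A[perm, , drop = FALSE])), numeric(1L))
      predictions[[p]] <- t(vapply(concepts, function(cc)
        fit_predict_loco(A, rt, cc), numeric(length(vox))))
    }
  } else {
    perms <- lapply(seq_len(n_perm), function(it) sample.int(n))
    for (p in seq_len(np)) {
      A <- avg[[p]][, vox, drop = FALSE]
      pred <- t(vapply(concepts, function(cc)
        fit_predict_loco(A, rt, cc), numeric(length(vox))))
      predictions[[p]] <- pred
      D <- as.matrix(stats::dist(rbind(pred, A)))[seq_len(n),
                                                  n + seq_len(n)]
      m <- t(apply(D, 1L, function(d)
        (n - rank(d, ties.method = "average")) / (n - 1)))
      acc[p, ] <- m[cbind(seq_len(n), seq_len(n))]
      null_parts[p, ] <- vapply(perms, function(perm)
        mean(m[cbind(seq_len(n), perm)]), numeric(1L))
    }
  }
  grand <- mean(rowMeans(acc))
  null <- colMeans(null_parts)
  structure(list(per_concept = colMeans(acc),
                 per_participant = rowMeans(acc),
                 accuracy = acc, grand_mean = grand,
                 p_value = (1 + sum(null >= grand)) / (1 + n_perm),
                 null = null, n_perm = n_perm, seed = seed,
                 scoring = scoring, predictions = predictions,
                 location_voxels = vox),
            class = "encoding_result")
}

#' @export
print.encoding_result <- function(x, ...) {
  cat(sprintf(
    "encoding_result (%s scoring): grand mean rank accuracy %.3f (chance 0.5), p = %.2g, %d voxels\n",
    x$scoring, x$grand_mean, x$p_value, length(x$location_voxels)))
  invisible(x)
}
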