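#' Principal-axis factor analysis
#'
#' Iterated principal-axis factoring: initial communalities are squared
#' multiple correlations, the reduced correlation matrix is re-factored until
#' the largest communality change drops below `tol` (default 1e-4, at most
#' `max_iter` iterations), with varimax rotation and regression-method factor
#' scores (standardized to mean 0, SD 1) by default. Factors are sorted by
#' explained variance and sign-anchored so each factor's largest-magnitude
#' loading is positive.
#'
#' With fewer observations than variables (the usual case here: 28 concepts
#' against hundreds of voxels) the correlation matrix is singular; a ridge of
#' 1e-8 is added before inversion, with a warning.
#'
#' @param X observation x variable numeric matrix (standardized internally).
#' @param n_factors number of factors to extract.
#' @param rotate `"varimax"` (default) or `"none"`.
#' @param max_iter,tol iteration control for the communality loop.
#' @return An object of class `fa_solution`: `loadings` (variable x factor),
#'   `factor_scores` (observation x factor, standardized),
#'   `variance_explained` (per-factor fraction of total variance),
#'   `communalities`, `level`, `meta`.
#' @export
principal_axis_fa <- function(X, n_factors, rotate = c("varimax", "none"),
                              max_iter = 100L, tol = 1e-4) {
  rotate <- match.arg(rotate)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < n_factors + 1L)
    stop("need at least n_factors + 1 observations")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ", paste(which(sds == 0), collapse = ", "))
  Z <- scale(X)
  R <- stats::cor(X)

  # one eigendecomposition of R serves both the SMC start (ridge-inverse)
  # and the regression scores (pseudo-inverse)
  egR <- eigen(R, symmetric = TRUE)
  singular <- min(egR$values) < max(egR$values) * 1e-12
  if (singular && n > p)
    warning("singular correlation matrix; adding ridge 1e-8")
  # with n <= p singularity is structural; the ridge applies quietly
  Rinv <- egR$vectors %*% (t(egR$vectors) / (pmax(egR$values, 0) + 1e-8))
  h2 <- pmin(pmax(1 - 1 / diag(Rinv), 0), 0.999)  # SMC start

  L <- NULL
  delta <- Inf
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    eg <- eigen(Rh, symmetric = TRUE)
    ev <- pmax(eg$values[seq_len(n_factors)], 0)
    L <- eg$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(ev), n_factors)
    h2_new <- pmin(rowSums(L^2), 0.999)
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf(
      "principal-axis iteration did not converge in %d iterations (last communality change %.2e)",
      max_iter, delta))

  if (rotate == "varimax" && n_factors > 1L) {
    # start from a fixed non-trivial rotation: the identity start is a
    # stationary point of the varimax criterion for exactly symmetric
    # loading configurations (e.g. tied eigenvalues from cloned inputs)
    Q0 <- qr.Q(qr(matrix(sin(seq_len(n_factors^2)), n_factors)))
    L1 <- L %*% Q0
    rot <- stats::varimax(L1, normalize = TRUE)
    L <- L1 %*% rot$rotmat
  }

  # order by explained variance, anchor signs
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (j in seq_len(n_factors)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }

  # regression-method scores; pseudo-inverse keeps rank-deficient
  # correlation matrices from amplifying null-space rounding noise
  pos <- egR$values > max(egR$values) * 1e-10
  Rpinv <- egR$vectors[, pos, drop = FALSE] %*%
    (t(egR$vectors[, pos, drop = FALSE]) / egR$values[pos])
  scores <- Z %*% Rpinv %*% L
  scores <- apply(scores, 2L, function(v) {
    s <- stats::sd(v)
    if (s == 0) v else (v - mean(v)) / s
  })
  dimnames(L) <- list(colnames(X), paste0("F", seq_len(n_factors)))
  dimnames(scores) <- list(rownames(X), colnames(L))
  structure(list(loadings = L, factor_scores = scores,
                 variance_explained = colSums(L^2) / p,
                 communalities = stats::setNames(rowSums(L^2), colnames(X)),
                 rotation = rotate, n_iter = it, level = NA_character_,
                 meta = list()),
            class = "fa_solution")
}

#' @export
print.fa_solution <- function(x, ...) {
  cat(sprintf(
    "fa_solution (%s level): %d variables, %d observations, %d factors, %.1f%% variance\n",
    ifelse(is.na(x$level), "?", x$level), nrow(x$loadings),
    nrow(x$factor_scores), ncol(x$loadings),
    100 * sum(x$variance_explained)))
  invisible(x)
}

#' First-level (within-participant) factor analysis
#'
#' Factors one participant's presentation-averaged activation (concepts as
#' observations, selected stable voxels as variables), partitioning the
#' voxels into subsets with similar concept tuning. Default 7 factors over
#' the 410 allocated voxels.
#'
#' @param ds an [activation_dataset()].
#' @param participant participant index or id.
#' @param voxel_subset voxel indices (typically from [allocate_by_roi()]).
#' @param n_factors factors to extract (default 7).
#' @param ... passed to [principal_axis_fa()].
#' @return An `fa_solution` with `level = "first"`.
#' @export
first_level <- function(ds, participant, voxel_subset, n_factors = 7L, ...) {
  stopifnot(inherits(ds, "activation_dataset"))
  if (is.character(participant))
    participant <- match(participant, ds$participant_ids)
  avg <- average_presentations(ds)[[participant]]
  X <- avg[, voxel_subset, drop = FALSE]
  colnames(X) <- paste0("v", voxel_subset)
  sol <- principal_axis_fa(X, n_factors, ...)
  sol$level <- "first"
  sol$meta <- list(participant = ds$participant_ids[participant],
                   voxels = voxel_subset)
  sol
}

#' Second-level (group) factor analysis
#'
#' Concatenates every participant's first-level factor scores column-wise
#' (16 participants x 7 factors = 112 score vectors over the 28 concepts)
#' and factors the result, seeking dimensions consistent across participants
#' and cohorts. Default 6 factors.
#'
#' @param first_levels list of first-level `fa_solution`s sharing the
#'   concept set.
#' @param n_factors factors to extract (default 6).
#' @param ... passed to [principal_axis_fa()].
#' @return An `fa_solution` with `level = "second"`; `meta$n_input_vectors`
#'   records the concatenated column count.
#' @export
second_level <- function(first_levels, n_factors = 6L, ...) {
  stopifnot(length(first_levels) >= 1L)
  obs <- rownames(first_levels[[1L]]$factor_scores)
  for (s in first_levels)
    if (!identical(rownames(s$factor_scores), obs))
      stop("first-level solutions disagree on the concept set")
  X <- do.call(cbind, lapply(seq_along(first_levels), function(i) {
    m <- first_levels[[i]]$factor_scores
    colnames(m) <- sprintf("p%02d_%s", i, colnames(m))
    m
  }))
  sol <- principal_axis_fa(X, n_factors, ...)
  sol$level <- "second"
  sol$meta <- list(n_participants = length(first_levels),
                   n_input_vectors = ncol(X))
  sol
}

#' Correlate factor scores with behavioral ratings
#'
#' Pearson correlation (with two-sided p) between every factor's scores and
#' every rating dimension, concepts aligned by label. A constant rating or
#' score column yields `NA` with a warning.
#'
#' @param sol an `fa_solution` whose `factor_scores` rows are concepts.
#' @param ratings a [ratings_table()] over the same concepts.
#' @return List of two factor x dimension matrices, `r` and `p`.
#' @export
score_rating_correlation <- function(sol, ratings) {
  stopifnot(inherits(sol, "fa_solution"), inherits(ratings, "ratings_table"))
  sc <- sol$factor_scores
  rt <- ratings$values
  if (is.null(rownames(sc)) || !all(rownames(sc) %in% rownames(rt)))
    stop("concepts not aligned between scores and ratings")
  rt <- rt[rownames(sc), , drop = FALSE]
  r <- matrix(NA_real_, ncol(sc), ncol(rt),
              dimnames = list(colnames(sc), colnames(rt)))
  p <- r
  for (i in seq_len(ncol(sc))) for (j in seq_len(ncol(rt))) {
    if (stats::sd(sc[, i]) == 0 || stats::sd(rt[, j]) == 0) {
      warning("constant column; correlation undefined for ",
              colnames(sc)[i], " x ", colnames(rt)[j])
      next
    }
    ct <- stats::cor.test(sc[, i], rt[, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p)
}
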