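#' Gaussian naive Bayes classifier for concept decoding
#'
#' Per-class feature means with a pooled (tied) within-class variance per
#' feature and uniform class priors — the standard configuration for
#' decoding a balanced concept set from a handful of trials per class.
#' A variance floor of `1e-6` times the mean pooled variance guards
#' degenerate features. Per-class variances are available with
#' `pooled_variance = FALSE`.
#'
#' @param x sample x feature numeric matrix.
#' @param labels class label per sample.
#' @param priors optional named per-class prior probabilities (default
#'   uniform).
#' @param pooled_variance use a single pooled within-class variance per
#'   feature (default) rather than per-class variances.
#' @param feature_indices optional provenance: which voxels the columns are.
#' @return An object of class `gnb` with elements `class_means`,
#'   `feature_variances`, `priors`, `classes`, `feature_indices`.
#' @export
gnb_train <- function(x, labels, priors = NULL, pooled_variance = TRUE,
                      feature_indices = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), ncol(x) >= 1L)
  classes <- unique(labels)
  if (any(tabulate(match(labels, classes)) < 1L))
    stop("every class needs at least one sample")
  nf <- ncol(x)
  means <- matrix(NA_real_, length(classes), nf,
                  dimnames = list(classes, colnames(x)))
  css <- matrix(0, length(classes), nf)   # within-class sum of squares
  ns <- integer(length(classes))
  for (i in seq_along(classes)) {
    rows <- which(labels == classes[i])
    ns[i] <- length(rows)
    xi <- x[rows, , drop = FALSE]
    means[i, ] <- colMeans(xi)
    css[i, ] <- colSums(sweep(xi, 2L, means[i, ])^2)
  }
  if (pooled_variance) {
    df <- max(nrow(x) - length(classes), 1L)
    v <- colSums(css) / df
    mv <- mean(v)
    floor_eps <- if (mv > 0) 1e-6 * mv else 1e-6
    variances <- pmax(v, floor_eps)
  } else {
    df <- pmax(ns - 1L, 1L)
    v <- css / df
    mv <- mean(v)
    floor_eps <- if (mv > 0) 1e-6 * mv else 1e-6
    variances <- pmax(v, floor_eps)
  }
  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / length(classes), length(classes)),
                              classes)
  } else {
    priors <- priors[classes]
    priors <- priors / sum(priors)
  }
  structure(list(class_means = means, feature_variances = variances,
                 priors = priors, classes = classes,
                 pooled_variance = pooled_variance,
                 feature_indices = feature_indices),
            class = "gnb")
}

#' @export
print.gnb <- function(x, ...) {
  cat(sprintf("gnb: %d classes, %d features (%s variance)\n",
              length(x$classes), ncol(x$class_means),
              if (x$pooled_variance) "pooled" else "per-class"))
  invisible(x)
}

#' Posterior class probabilities under a trained GNB
#'
#' Computes `log p(c) + sum_f log N(x_f; mean_cf, var_f)` per class in log
#' space and normalizes so the posteriors sum to one.
#'
#' @param object a [gnb_train()] model.
#' @param newdata feature vector, or sample x feature matrix.
#' @param log return log posteriors instead.
#' @param ... unused.
#' @return Named posterior vector, or a sample x class matrix.
#' @export
predict.gnb <- function(object, newdata, log = FALSE, ...) {
  x <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(x) != ncol(object$class_means))
    stop(sprintf("feature dimension mismatch: got %d, model has %d",
                 ncol(x), ncol(object$class_means)))
  if (!all(is.finite(x))) stop("newdata must be finite")
  nc <- length(object$classes)
  v <- object$feature_variances
  out <- matrix(NA_real_, nrow(x), nc,
                dimnames = list(rownames(x), object$classes))
  for (i in seq_len(nc)) {
    vi <- if (object$pooled_variance) v else v[i, ]
    d <- sweep(x, 2L, object$class_means[i, ])
    out[, i] <- base::log(object$priors[i]) -
      0.5 * sum(base::log(2 * pi * vi)) -
      0.5 * as.vector(d^2 %*% (1 / vi))
  }
  # normalize with log-sum-exp
  mx <- apply(out, 1L, max)
  lse <- mx + base::log(rowSums(exp(out - mx)))
  out <- out - lse
  if (!log) out <- exp(out)
  if (!is.matrix(newdata)) out[1L, ] else out
}

#' Normalized rank accuracy of a ranked prediction
#'
#' `(N - r) / (N - 1)` where `r` is the rank of the correct alternative in
#' the posterior-ordered list of all `N` alternatives (average rank under
#' ties). 1 means ranked first, 0 ranked last; chance level is 0.5.
#'
#' @param posteriors named numeric vector of scores over alternatives.
#' @param true_label the correct alternative.
#' @return Accuracy in [0, 1].
#' @export
rank_accuracy <- function(posteriors, true_label) {
  if (length(posteriors) < 2L) stop("need at least 2 alternatives")
  i <- match(true_label, names(posteriors))
  if (is.na(i)) stop("true_label absent from posteriors")
  r <- rank(-posteriors, ties.method = "average")[[i]]
  n <- length(posteriors)
  (n - r) / (n - 1)
}

#' Ranked prediction for one test pattern
#'
#' @param model a [gnb_train()] model.
#' @param x test feature vector.
#' @param true_label correct concept.
#' @return An object of class `ranked_prediction`: posterior-ordered concept
#'   list, the posteriors, the true label, and its normalized rank accuracy.
#' @export
ranked_prediction <- function(model, x, true_label) {
  post <- predict(model, x)
  structure(list(ranking = names(sort(post, decreasing = TRUE)),
                 posteriors = post, true_label = true_label,
                 normalized_rank_accuracy = rank_accuracy(post, true_label)),
            class = "ranked_prediction")
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat(sprintf("ranked_prediction: '%s' at accuracy %.3f (top: %s)\n",
              x$true_label, x$normalized_rank_accuracy, x$ranking[1L]))
  invisible(x)
}
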