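#' Cross-validated concept decoding
#'
#' Three schemes mirror three questions about concept representations.
#' Within-participant: are a participant's concept patterns reliable and
#' distinct? Train on 4 of the 6 presentation blocks, test on the average of
#' the 2 held-out blocks, over all choose(6, 2) = 15 folds; voxel stability
#' and feature selection are recomputed on the training blocks of each fold.
#' Between-participant: are patterns shared across speakers? Leave one
#' participant out; features are the top-k cross-participant stable voxels of
#' the training participants; training samples are their presentation-averaged
#' signatures. Cross-language: train on all of one cohort, test on each
#' participant of the other, both directions averaged.
#'
#' @param ds an [activation_dataset()].
#' @param participant participant index or id.
#' @param k number of stable voxels used as features (default 120).
#' @param test_blocks held-out blocks per fold (default 2).
#' @return An object of class `decode_result`: `per_concept` mean accuracies,
#'   grand `mean`, `scheme`, number of `folds`, and per-fold posterior
#'   matrices (rownames = true labels) for permutation testing.
#' @export
within_participant_cv <- function(ds, participant, k = 120L,
                                  test_blocks = 2L) {
  stopifnot(inherits(ds, "activation_dataset"))
  if (is.character(participant))
    participant <- match(participant, ds$participant_ids)
  n_blocks <- dim(ds$data)[2L]
  if (n_blocks < test_blocks + 1L)
    stop("need more blocks than the held-out test size")
  concepts <- ds$concepts$labels
  folds <- utils::combn(n_blocks, test_blocks, simplify = FALSE)
  acc <- matrix(NA_real_, length(folds), length(concepts),
                dimnames = list(NULL, concepts))
  posts <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_b <- folds[[f]]
    train_b <- setdiff(seq_len(n_blocks), test_b)
    stab <- voxel_stability_within(ds, participant, train_b)
    feats <- select_top_k(stab, k)
    xtr <- do.call(rbind, lapply(train_b, function(b)
      ds$data[participant, b, , feats, drop = TRUE]))
    ytr <- rep(concepts, times = length(train_b))
    model <- gnb_train(xtr, ytr, feature_indices = feats)
    sub <- ds$data[participant, test_b, , feats, drop = FALSE]
    xte <- colMeans(array(sub, dim = dim(sub)[2:4]))
    post <- predict(model, xte, log = TRUE)
    rownames(post) <- concepts
    posts[[f]] <- post
    acc[f, ] <- vapply(seq_along(concepts), function(i)
      rank_accuracy(post[i, ], concepts[i]), numeric(1L))
  }
  new_decode_result("within_participant", colMeans(acc), length(folds), posts)
}

#' @param language restrict to participants with this language tag (default:
#'   all participants in `ds`).
#' @rdname within_participant_cv
#' @export
between_participant_cv <- function(ds, language = NULL, k = 120L) {
  stopifnot(inherits(ds, "activation_dataset"))
  if (!is.null(language)) ds <- subset_participants(ds, which(ds$language == language))
  np <- dim(ds$data)[1L]
  if (np < 3L) stop("need at least 3 participants in the group")
  concepts <- ds$concepts$labels
  avg <- average_presentations(ds)
  acc <- matrix(NA_real_, np, length(concepts),
                dimnames = list(ds$participant_ids, concepts))
  posts <- vector("list", np)
  for (p in seq_len(np)) {
    train_p <- setdiff(seq_len(np), p)
    stab <- voxel_stability_between(ds, train_p)
    feats <- select_top_k(stab, k)
    xtr <- do.call(rbind, lapply(avg[train_p], function(m)
      m[, feats, drop = FALSE]))
    ytr <- rep(concepts, times = length(train_p))
    model <- gnb_train(xtr, ytr, feature_indices = feats)
    post <- predict(model, avg[[p]][, feats, drop = FALSE], log = TRUE)
    rownames(post) <- concepts
    posts[[p]] <- post
    acc[p, ] <- vapply(seq_along(concepts), function(i)
      rank_accuracy(post[i, ], concepts[i]), numeric(1L))
  }
  new_decode_result("between_participant", colMeans(acc), np, posts)
}

#' @param dsA,dsB two cohorts aligned on grid and concepts.
#' @param feature_voxels voxel indices used as features (typically the
#'   factor-location voxels); if `NULL`, the top-k cross-participant stable
#'   voxels of the training cohort are used per direction.
#' @rdname within_participant_cv
#' @export
cross_language_classify <- function(dsA, dsB, feature_voxels = NULL,
                                    k = 120L) {
  stopifnot(inherits(dsA, "activation_dataset"),
            inherits(dsB, "activation_dataset"))
  if (!identical(dsA$concepts$labels, dsB$concepts$labels))
    stop("cohorts must share the concept set")
  if (dim(dsA$data)[4L] != dim(dsB$data)[4L])
    stop("voxel sets not aligned between cohorts")
  direction <- function(train_ds, test_ds) {
    concepts <- train_ds$concepts$labels
    feats <- feature_voxels
    if (is.null(feats))
      feats <- select_top_k(voxel_stability_between(train_ds), k)
    avg_tr <- average_presentations(train_ds)
    xtr <- do.call(rbind, lapply(avg_tr, function(m)
      m[, feats, drop = FALSE]))
    ytr <- rep(concepts, times = length(avg_tr))
    model <- gnb_train(xtr, ytr, feature_indices = feats)
    avg_te <- average_presentations(test_ds)
    posts <- lapply(avg_te, function(m) {
      post <- predict(model, m[, feats, drop = FALSE], log = TRUE)
      rownames(post) <- concepts
      post
    })
    acc <- t(vapply(posts, function(post)
      vapply(seq_along(concepts), function(i)
        rank_accuracy(post[i, ], concepts[i]), numeric(1L)),
      numeric(length(concepts))))
    colnames(acc) <- concepts
    list(per_concept = colMeans(acc), posts = posts)
  }
  ab <- direction(dsA, dsB)
  ba <- direction(dsB, dsA)
  per_concept <- (ab$per_concept + ba$per_concept) / 2
  new_decode_result("cross_language", per_concept,
                    length(ab$posts) + length(ba$posts),
                    c(ab$posts, ba$posts))
}

new_decode_result <- function(scheme, per_concept, folds, posteriors) {
  structure(list(scheme = scheme, per_concept = per_concept,
                 mean = mean(per_concept), folds = folds,
                 posteriors = posteriors),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result (%s): mean rank accuracy %.3f over %d folds, %d concepts\n",
              x$scheme, x$mean, x$folds, length(x$per_concept)))
  invisible(x)
}

#' @export
summary.decode_result <- function(object, ...) {
  cat(sprintf("%s decoding, %d folds\n", object$scheme, object$folds))
  cat(sprintf("mean rank accuracy: %.3f (chance 0.5)\n", object$mean))
  cat(sprintf("range over concepts: %.3f - %.3f\n",
              min(object$per_concept), max(object$per_concept)))
  invisible(object)
}

#' Permutation test for decoding accuracy
#'
#' Builds the null distribution by permuting the test-set concept labels
#' while keeping the trained model's posteriors fixed, recomputing the mean
#' rank accuracy each iteration. The empirical p-value is
#' `(1 + #{null >= observed}) / (1 + n_iter)`; accuracy cutoffs are reported
#' for alpha in {.05, .01, .001}.
#'
#' @param result a `decode_result`, or a list of posterior matrices whose
#'   rownames are the true labels.
#' @param n_iter permutation iterations (default 10000).
#' @param seed RNG seed.
#' @return List with `observed`, `p_value`, `cutoffs`, `n_iter`, `seed` and
#'   the `null` distribution of mean accuracies.
#' @export
permutation_test <- function(result, n_iter = 10000L, seed = 1L) {
  posts <- if (inherits(result, "decode_result")) result$posteriors
           else result
  stopifnot(n_iter >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  # per matrix: trial x class rank-accuracy lookup, accuracy of assigning
  # class j as the true label of trial i
  lookup <- lapply(posts, function(post) {
    n <- ncol(post)
    r <- t(apply(post, 1L, function(p) rank(-p, ties.method = "average")))
    (n - r) / (n - 1)
  })
  observed <- mean(vapply(lookup, function(m)
    mean(m[cbind(seq_len(nrow(m)), match(rownames(m), colnames(m)))]),
    numeric(1L)))
  null <- vapply(seq_len(n_iter), function(it) {
    mean(vapply(lookup, function(m) {
      perm <- sample.int(nrow(m))
      mean(m[cbind(seq_len(nrow(m)),
                   match(rownames(m), colnames(m))[perm])])
    }, numeric(1L)))
  }, numeric(1L))
  alphas <- c(0.05, 0.01, 0.001)
  cutoffs <- stats::quantile(null, probs = 1 - alphas, names = FALSE,
                             type = 1L)
  list(observed = observed,
       p_value = (1 + sum(null >= observed)) / (1 + n_iter),
       cutoffs = stats::setNames(cutoffs, paste0("alpha_", alphas)),
       n_iter = n_iter, seed = seed, null = null)
}
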