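test_that("gnb_train computes class means and pooled variance, flooring zeros", {
  # degenerate: zero within-class variance gets floored, means survive
  m0 <- gnb_train(matrix(c(0, 0, 2, 2), ncol = 1L), c("a", "a", "b", "b"))
  expect_equal(unname(m0$class_means[, 1L]), c(0, 2))
  expect_gt(m0$feature_variances[1L], 0)

  # 3-class toy with unequal spread: hand-computed pooled variance
  x <- matrix(c(0, 2,   10, 14,   -3, -7), ncol = 1L)
  y <- rep(c("a", "b", "c"), each = 2L)
  m <- gnb_train(x, y)
  ss <- (0 - 1)^2 + (2 - 1)^2 + (10 - 12)^2 + (14 - 12)^2 + (-3 + 5)^2 +
    (-7 + 5)^2
  expect_equal(unname(m$feature_variances[1L]), ss / (6 - 3))
  expect_equal(sum(m$priors), 1)
  expect_error(gnb_train(x[0, , drop = FALSE], character(0)))
})

test_that("posteriors are normalized, symmetric and match brute-force Bayes", {
  m <- gnb_train(matrix(c(-1, -1, 1, 1), ncol = 1L), c("a", "a", "b", "b"))
  expect_equal(unname(predict(m, 0)), c(0.5, 0.5))

  set.seed(10)
  for (i in 1:50) {
    nc <- sample(2:5, 1L); nf <- sample(1:4, 1L); n_per <- sample(2:4, 1L)
    x <- matrix(stats::rnorm(nc * n_per * nf), ncol = nf)
    y <- rep(paste0("k", seq_len(nc)), each = n_per)
    model <- gnb_train(x, y, pooled_variance = sample(c(TRUE, FALSE), 1L))
    # test points near the data keep the oracle's density products
    # representable in double precision
    xt <- x[sample(nrow(x), 1L), ] + stats::rnorm(nf, 0, 0.5)
    p <- predict(model, xt)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(p), unname(brute_force_posterior(model, xt)),
                 tolerance = 1e-10)
  }

  expect_error(predict(m, c(0, 1)), "dimension mismatch")
})

test_that("rank accuracy follows the (N - r)/(N - 1) average-rank formula", {
  post <- stats::setNames(c(0.5, 0.3, 0.2), c("a", "b", "c"))
  expect_equal(rank_accuracy(post, "a"), 1)
  expect_equal(rank_accuracy(post, "c"), 0)
  tied <- stats::setNames(rep(1 / 28, 28L), paste0("c", 1:28))
  expect_equal(rank_accuracy(tied, "c7"), 0.5)
  expect_error(rank_accuracy(post, "z"), "absent")
  expect_error(rank_accuracy(post["a"], "a"), "at least 2")

  # expectation of a uniformly random ranking is 1/2
  set.seed(77)
  accs <- vapply(1:10000, function(i) {
    rank_accuracy(stats::setNames(sample(28L), paste0("c", 1:28)), "c1")
  }, numeric(1L))
  expect_lt(abs(mean(accs) - 0.5), 0.01)
})

test_that("accuracy is invariant to consistent feature-wise affine rescaling", {
  sim <- simulate_cohorts(tiny_spec(seed = 51L))
  ds <- sim$cohorts[[1L]]
  avg <- average_presentations(ds)
  feats <- 1:20
  xtr <- rbind(avg[[1L]][, feats], avg[[2L]][, feats])
  ytr <- rep(ds$concepts$labels, 2L)
  xte <- avg[[3L]][, feats]
  a <- stats::runif(length(feats), 0.5, 3)
  b <- stats::rnorm(length(feats))
  rescale <- function(m) sweep(sweep(m, 2L, a, `*`), 2L, b, `+`)
  acc <- function(xtr, xte) {
    model <- gnb_train(xtr, ytr)
    post <- predict(model, xte, log = TRUE)
    vapply(seq_len(nrow(xte)), function(i)
      rank_accuracy(post[i, ], ds$concepts$labels[i]), numeric(1L))
  }
  expect_equal(acc(xtr, xte), acc(rescale(xtr), rescale(xte)),
               tolerance = 1e-8)
})

test_that("within-participant CV has choose(n, 2) folds and is leakage-free", {
  ds <- handmade_dataset(n_participants = 1L, n_blocks = 4L,
                         n_concepts = 5L, n_voxels = 10L, noise_sd = 0.5)
  res <- within_participant_cv(ds, 1L, k = 6L)
  expect_equal(res$folds, choose(4L, 2L))

  # noiseless planted data: perfect decoding
  clean <- handmade_dataset(n_participants = 1L, n_blocks = 4L,
                            n_concepts = 5L, n_voxels = 10L, noise_sd = 0)
  expect_equal(within_participant_cv(clean, 1L, k = 6L)$mean, 1)

  # metamorphic: corrupting held-out blocks cannot change training-block
  # stability (feature selection never sees test data)
  sim <- simulate_cohorts(tiny_spec(seed = 61L))
  ds2 <- sim$cohorts[[1L]]
  train_b <- c(1L, 2L)
  before <- voxel_stability_within(ds2, 1L, blocks = train_b)
  corrupted <- ds2
  corrupted$data[1L, 3L, , ] <- ztrial(matrix(
    stats::rnorm(prod(dim(ds2$data)[3:4])), dim(ds2$data)[3L]))
  after <- voxel_stability_within(corrupted, 1L, blocks = train_b)
  expect_identical(before$scores, after$scores)
  expect_error(within_participant_cv(ds2, 1L, test_blocks = 4L), "blocks")
})

test_that("between-participant CV leaves one participant out per fold", {
  sim <- simulate_cohorts(tiny_spec(seed = 71L, noise_sd = 0.5))
  ds <- sim$cohorts[[1L]]
  res <- between_participant_cv(ds, k = 30L)
  expect_equal(res$folds, dim(ds$data)[1L])
  expect_gt(res$mean, 0.5)
  expect_lte(res$mean, 1)
  # clone participants, no noise: perfect generalization
  clean <- simulate_cohorts(tiny_spec(seed = 72L, noise_sd = 0,
                                      participant_sd = 0))
  expect_equal(between_participant_cv(clean$cohorts[[1L]], k = 30L)$mean, 1)
  expect_error(between_participant_cv(subset_participants(ds, 1:2)),
               "at least 3")
})

test_that("cross-language decoding generalizes planted structure and is chance on shuffled labels", {
  sim <- simulate_cohorts(tiny_spec(seed = 81L, noise_sd = 0.5))
  a <- sim$cohorts[[1L]]; b <- sim$cohorts[[2L]]
  res <- cross_language_classify(a, b, k = 30L)
  expect_equal(res$folds, dim(a$data)[1L] + dim(b$data)[1L])
  expect_gt(res$mean, 0.7)
  # identical cohorts decode perfectly
  expect_equal(cross_language_classify(a, a, k = 30L)$mean, 1,
               tolerance = 1e-12)
  # shuffling test labels collapses accuracy to chance
  set.seed(5)
  shuf <- b
  perm <- sample(dim(b$data)[3L])
  shuf$data <- shuf$data[, , perm, , drop = FALSE]
  dimnames(shuf$data)[[3L]] <- dimnames(b$data)[[3L]]
  res_null <- cross_language_classify(a, shuf, k = 30L)
  expect_lt(abs(res_null$mean - 0.5), 0.1)
})

test_that("permutation test calibrates p-values and bounds them below by 1/(n+1)", {
  sim <- simulate_cohorts(tiny_spec(seed = 91L, noise_sd = 0.3))
  res <- within_participant_cv(sim$cohorts[[1L]], 1L, k = 20L)
  pt <- permutation_test(res, n_iter = 999L, seed = 2L)
  expect_equal(pt$observed, res$mean, tolerance = 1e-12)
  expect_gte(pt$p_value, 1 / 1000)
  expect_true(all(diff(pt$cutoffs) >= 0))   # stricter alpha, higher cutoff
  if (pt$observed == 1) expect_equal(pt$p_value, 1 / 1000)

  # null data: p-values roughly uniform across independent null datasets
  ps <- vapply(1:30, function(s) {
    nds <- null_cohort(tiny_spec(seed = 1000L + s))
    resn <- within_participant_cv(nds, 1L, k = 20L)
    permutation_test(resn, n_iter = 199L, seed = s)$p_value
  }, numeric(1L))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
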