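planted_two_factor_data <- function(n = 40L, p = 12L, seed = 1L) {
  set.seed(seed)
  S <- scale(qr.Q(qr(matrix(stats::rnorm(n * 2L), n))))
  L <- matrix(0, p, 2L)
  L[1:6, 1L] <- stats::runif(6L, 0.7, 0.95)
  L[7:12, 2L] <- stats::runif(6L, 0.7, 0.95)
  u <- sqrt(1 - rowSums(L^2))
  X <- S %*% t(L) + matrix(stats::rnorm(n * p), n) %*% diag(u)
  list(X = X, S = S, L = L)
}

test_that("principal-axis factoring recovers a planted 2-factor model", {
  pl <- planted_two_factor_data(n = 500L, seed = 2L)
  sol <- principal_axis_fa(pl$X, 2L)
  m <- match_factors(sol$factor_scores, pl$S)
  expect_true(all(m$pairs$abs_r >= 0.9))
  # scores standardized, loadings bounded, variance shares ordered
  expect_equal(unname(colMeans(sol$factor_scores)), c(0, 0),
               tolerance = 1e-6)
  expect_equal(unname(apply(sol$factor_scores, 2L, stats::sd)), c(1, 1),
               tolerance = 1e-6)
  expect_true(all(abs(sol$loadings) <= 1 + 1e-8))
  expect_true(all(diff(sol$variance_explained) <= 1e-12))

  # exact (noiseless) low-rank data with simple-structure loadings:
  # near-perfect score recovery (dense loadings would leave the solution
  # identified only up to rotation)
  set.seed(3)
  S <- scale(qr.Q(qr(matrix(stats::rnorm(60L * 2L), 60L))))
  L <- matrix(0, 12L, 2L)
  L[1:6, 1L] <- stats::runif(6L, 0.5, 1)
  L[7:12, 2L] <- stats::runif(6L, 0.5, 1)
  sol0 <- suppressWarnings(principal_axis_fa(S %*% t(L), 2L))
  m0 <- match_factors(sol0$factor_scores, S)
  # planted columns are orthogonal before standardization, so recovery is
  # near-perfect but not exact
  expect_true(all(m0$pairs$abs_r >= 0.998))
})

test_that("rank-1 data loads on a single factor capturing the common variance", {
  set.seed(4)
  s <- stats::rnorm(50L)
  X <- s %*% t(stats::runif(8L, 0.5, 1)) +
    matrix(stats::rnorm(400L, 0, 1e-3), 50L)
  sol <- principal_axis_fa(X, 1L)
  expect_gt(sol$variance_explained[1L], 0.95)
  expect_gt(abs(stats::cor(sol$factor_scores[, 1L], s)), 0.999)
})

test_that("varimax rotation preserves communalities and the reproduced matrix", {
  pl <- planted_two_factor_data(n = 120L, seed = 5L)
  rotated <- principal_axis_fa(pl$X, 2L, rotate = "varimax")
  plain <- principal_axis_fa(pl$X, 2L, rotate = "none")
  expect_equal(rowSums(rotated$loadings^2), rowSums(plain$loadings^2),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(rotated$loadings %*% t(rotated$loadings),
               plain$loadings %*% t(plain$loadings), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(stats::rnorm(40L), 10L)
  X[, 2L] <- 3
  expect_error(principal_axis_fa(X, 2L), "constant variable")
  expect_error(principal_axis_fa(matrix(stats::rnorm(8L), 2L), 2L),
               "observations")
})

test_that("second level concatenates participant scores and seeks consensus", {
  # fabricated first-level solutions: 16 participants x 7 factors -> 112 vectors
  set.seed(6)
  labs <- paste0("c", 1:28)
  fls <- lapply(1:16, function(p) {
    sc <- scale(matrix(stats::rnorm(28L * 7L), 28L))
    dimnames(sc) <- list(labs, paste0("F", 1:7))
    structure(list(factor_scores = sc, loadings = matrix(0, 2L, 7L)),
              class = "fa_solution")
  })
  sol <- second_level(fls, 6L)
  expect_equal(sol$meta$n_input_vectors, 112L)
  expect_equal(nrow(sol$factor_scores), 28L)

  # clone participants, noiseless: group factors reproduce the individual's
  pl <- planted_two_factor_data(n = 28L, seed = 7L)
  one <- principal_axis_fa(pl$X, 2L)
  rownames(one$factor_scores) <- labs
  clones <- list(one, one, one)
  grp <- suppressWarnings(second_level(clones, 2L))
  m <- match_factors(grp, one)
  expect_true(all(m$pairs$abs_r >= 0.999))

  # concatenation order leaves the solution unchanged (up to tolerance);
  # checked on structured input where factors are well separated
  set.seed(12)
  latent <- scale(matrix(stats::rnorm(28L * 3L), 28L))
  fls_struct <- lapply(1:8, function(p) {
    sc <- scale(latent[, c(1:3, sample(3L))] +
                  matrix(stats::rnorm(28L * 6L, 0, 0.3), 28L))
    dimnames(sc) <- list(labs, paste0("F", 1:6))
    structure(list(factor_scores = sc), class = "fa_solution")
  })
  sol_a <- second_level(fls_struct, 3L)
  sol_b <- second_level(fls_struct[c(5:8, 1:4)], 3L)
  expect_equal(abs(stats::cor(sol_a$factor_scores, sol_b$factor_scores)) |>
                 apply(1L, max), rep(1, 3L), tolerance = 1e-6,
               ignore_attr = TRUE)

  bad <- fls
  rownames(bad[[2L]]$factor_scores) <- rev(labs)
  expect_error(second_level(bad), "disagree")
})

test_that("factor locations keep only suprathreshold clusters of minimum size", {
  grid <- voxel_grid(c(8L, 8L, 4L))
  loadings <- rep(0, n_voxels(grid))
  coords <- voxel_coords(grid)
  # a 3x5x1 block at loading 0.9: one cluster, centroid at the block center
  blk <- which(coords[, 1L] %in% 2:4 & coords[, 2L] %in% 1:5 &
                 coords[, 3L] == 2L)
  loadings[blk] <- 0.9
  loc <- factor_locations(loadings, grid, min_cluster = 15L)
  expect_length(loc$clusters, 1L)
  expect_equal(loc$centroids_ijk[1L, ], c(3, 3, 2), ignore_attr = TRUE)
  expect_setequal(loc$clusters[[1L]], blk)

  # a 14-voxel blob is rejected under min_cluster = 15
  small <- rep(0, n_voxels(grid))
  small[which(coords[, 1L] %in% 0:1 & coords[, 2L] %in% 0:6 &
                coords[, 3L] == 0L)] <- 0.8   # 2 x 7 x 1 = 14 voxels
  expect_warning(loc2 <- factor_locations(small, grid, min_cluster = 15L),
                 "no suprathreshold cluster")
  expect_length(loc2$clusters, 0L)
  # ... but survives the figure-style min_cluster = 10
  loc3 <- factor_locations(small, grid, min_cluster = 10L)
  expect_length(loc3$clusters, 1L)

  # sub-threshold loadings never enter a cluster
  mixed <- rep(0.39, n_voxels(grid))
  mixed[blk] <- 0.41
  loc4 <- factor_locations(mixed, grid, min_cluster = 15L)
  expect_setequal(loc4$clusters[[1L]], blk)
})

test_that("flood fill agrees with an igraph oracle, including single-voxel bridges", {
  skip_if_not_installed("igraph")
  # two blobs joined by one face-adjacent voxel form a single 6-connected
  # component
  coords <- rbind(as.matrix(expand.grid(0:2, 0:2, 0L)),
                  c(3L, 1L, 0L),
                  as.matrix(expand.grid(4:6, 0:2, 0L)))
  comp <- connected_components(coords, 6L)
  expect_equal(length(unique(comp)), 1L)
  # removing the bridge splits it
  comp2 <- connected_components(coords[-10L, ], 6L)
  expect_equal(length(unique(comp2)), 2L)

  set.seed(8)
  for (i in 1:10) {
    conn <- sample(c(6L, 18L, 26L), 1L)
    n <- sample(30:80, 1L)
    pts <- unique(cbind(sample(0:11, n, TRUE), sample(0:11, n, TRUE),
                        sample(0:5, n, TRUE)))
    expect_true(same_partition(connected_components(pts, conn),
                               igraph_components(pts, conn)))
  }
})

test_that("factor matching recovers permutations and flags unmatched factors", {
  set.seed(9)
  A <- scale(matrix(stats::rnorm(28L * 5L), 28L))
  dimnames(A) <- list(paste0("c", 1:28), paste0("F", 1:5))
  perm <- c(4L, 1L, 5L, 3L, 2L)
  flip <- c(1, -1, 1, -1, -1)
  B <- A[, perm] %*% diag(flip)
  dimnames(B) <- list(rownames(A), paste0("G", 1:5))
  m <- match_factors(A, B)
  expect_true(all(m$pairs$abs_r >= 1 - 1e-12))
  recovered <- m$pairs$factor_b[match(paste0("F", perm), m$pairs$factor_a)]
  expect_identical(recovered, paste0("G", 1:5))

  # rectangular case: extra factors are reported unmatched
  m2 <- match_factors(A[, 1:3], B)
  expect_length(m2$unmatched, 2L)
  expect_equal(nrow(m2$pairs), 3L)

  # independent random solutions match weakly compared to a planted link
  C <- scale(matrix(stats::rnorm(28L * 5L), 28L))
  dimnames(C) <- dimnames(A)
  m3 <- match_factors(A, C)
  expect_lt(mean(m3$pairs$abs_r), 0.6)
})

test_that("factor-score/rating correlations behave at the extremes", {
  set.seed(10)
  sc <- scale(matrix(stats::rnorm(28L * 2L), 28L))
  dimnames(sc) <- list(paste0("c", 1:28), c("F1", "F2"))
  sol <- structure(list(factor_scores = sc), class = "fa_solution")
  rt <- ratings_table(pmin(pmax(4 + sc, 1), 7) |>
                        `colnames<-`(c("d1", "d2")))
  res <- score_rating_correlation(sol, rt)
  expect_gt(res$r["F1", "d1"], 0.99)
  expect_lt(res$p["F1", "d1"], 1e-10)
  # reversed scale flips the sign
  rev_rt <- ratings_table((8 - rt$values))
  expect_lt(score_rating_correlation(sol, rev_rt)$r["F1", "d1"], -0.99)
  # constant column flagged undefined (one warning per affected pair)
  const <- rt$values; const[, 2L] <- 4
  w <- capture_warnings(res2 <- score_rating_correlation(sol,
                                                         ratings_table(const)))
  expect_match(w, "constant column", all = TRUE)
  expect_length(w, 2L)
  expect_true(is.na(res2$r["F1", "d2"]))
  expect_true(is.na(res2$r["F2", "d2"]))
})
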