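#' Generative specification for synthetic two-cohort data
#'
#' Defines the study conditions the generator emulates: two language cohorts
#' (9 and 7 participants), 28 concepts presented 6 times each, and activation
#' maps whose signal is a low-rank product of concept factor scores and
#' spatially clustered voxel loadings. `K_shared` dimensions use identical
#' scores and loadings in both cohorts; `K_specific` dimensions (the
#' word-length analogue) use cohort-specific score vectors whose cross-cohort
#' correlation is about `specific_rho`.
#'
#' @param grid_shape 3-vector of voxel counts (default 10 x 10 x 6).
#' @param voxel_size_mm physical voxel spacing in mm per axis (default
#'   3.125 x 3.125 x 6, echo-planar in-plane resolution with 5 mm slices and
#'   a 1 mm gap); sets the grid affine.
#' @param K_shared number of shared semantic dimensions.
#' @param K_specific number of cohort-specific dimensions.
#' @param n_participants named integer vector, participants per cohort.
#' @param n_presentations presentation blocks per participant.
#' @param n_concepts number of stimulus concepts.
#' @param cluster_size voxels per planted loading cluster.
#' @param salience cohort x dimension positive weight matrix (default all 1).
#' @param noise_sd SD of presentation-level Gaussian noise added per voxel,
#'   on the scale of the standardized factor scores (in-cluster signal SD is
#'   roughly the mean loading, ~0.8).
#' @param participant_sd SD of per-participant dimension weights around 1.
#' @param specific_rho target cross-cohort correlation of the specific
#'   dimension's score vectors.
#' @param seed RNG seed; a fixed seed reproduces the datasets exactly.
#' @return A list of class `generative_spec`.
#' @export
generative_spec <- function(grid_shape = c(10L, 10L, 6L),
                            voxel_size_mm = c(3.125, 3.125, 6),
                            K_shared = 4L, K_specific = 1L,
                            n_participants = c(english = 9L, mandarin = 7L),
                            n_presentations = 6L, n_concepts = 28L,
                            cluster_size = 40L, salience = NULL,
                            noise_sd = 2, participant_sd = 0.3,
                            specific_rho = 0.2, seed = 1L) {
  K <- K_shared + K_specific
  if (is.null(salience))
    salience <- matrix(1, nrow = 2L, ncol = K)
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = voxel_size_mm,
               K_shared = as.integer(K_shared),
               K_specific = as.integer(K_specific),
               n_participants = n_participants,
               n_presentations = as.integer(n_presentations),
               n_concepts = as.integer(n_concepts),
               cluster_size = as.integer(cluster_size),
               salience = salience, noise_sd = noise_sd,
               participant_sd = participant_sd,
               specific_rho = specific_rho, seed = as.integer(seed))
  if (any(unlist(spec[c("K_shared", "n_presentations", "n_concepts",
                        "cluster_size")]) < 0) ||
      any(n_participants <= 0))
    stop("all counts must be positive")
  if (any(salience <= 0)) stop("salience weights must be positive")
  if (K * spec$cluster_size > prod(spec$grid_shape))
    stop("cluster_size x total dimensions exceeds voxel count")
  class(spec) <- "generative_spec"
  spec
}

spec_grid <- function(spec) {
  aff <- diag(c(spec$voxel_size_mm, 1))
  voxel_grid(spec$grid_shape, affine = aff)
}

largest_divisor_leq <- function(n, cap) {
  for (d in seq(min(n, cap), 1L)) if (n %% d == 0L) return(d)
  1L
}

# Disjoint axis-aligned blocks of cluster_size voxels on the grid.
plant_clusters <- function(shape, K, cluster_size) {
  dx <- largest_divisor_leq(cluster_size, shape[1L])
  rest <- cluster_size / dx
  dy <- largest_divisor_leq(rest, shape[2L])
  dz <- rest / dy
  if (dz > shape[3L]) stop("cluster_size does not fit the grid as a block")
  slots_x <- shape[1L] %/% dx
  slots_y <- shape[2L] %/% dy
  slots_z <- shape[3L] %/% dz
  if (slots_x * slots_y * slots_z < K)
    stop("not enough room for ", K, " disjoint clusters")
  clusters <- vector("list", K)
  k <- 0L
  for (sz in seq_len(slots_z)) for (sy in seq_len(slots_y))
    for (sx in seq_len(slots_x)) {
      if (k >= K) break
      k <- k + 1L
      ix <- (sx - 1L) * dx + seq_len(dx)
      iy <- (sy - 1L) * dy + seq_len(dy)
      iz <- (sz - 1L) * dz + seq_len(dz)
      g <- as.matrix(expand.grid(i = ix, j = iy, k = iz))
      clusters[[k]] <- (g[, 3L] - 1L) * shape[1L] * shape[2L] +
        (g[, 2L] - 1L) * shape[1L] + g[, 1L]
    }
  clusters
}

standardize_cols <- function(m) {
  m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  m
}

synthetic_concepts <- function(n) {
  if (n == 28L) return(default_concepts())
  labels <- sprintf("concept%02d", seq_len(n))
  categories <- stats::setNames(
    sprintf("cat%d", (seq_len(n) - 1L) %/% 4L + 1L), labels)
  concept_set(labels, categories,
              stats::setNames(5 + (seq_len(n) %% 7L), labels))
}

#' Generate a synthetic two-cohort activation dataset with known truth
#'
#' Activation of participant p, presentation r, concept c, voxel v is
#' `sum_k w[p,k] * salience[cohort,k] * S[c,k] * L[v,k] + noise`, then
#' z-scored across voxels within each trial. Shared dimensions reuse the same
#' standardized scores `S` and clustered loadings `L` in both cohorts; each
#' specific dimension keeps the loading cluster but draws cohort-specific
#' scores correlated at `specific_rho` across cohorts.
#'
#' @param spec a [generative_spec()].
#' @return A list with elements `cohorts` (named list of two
#'   [activation_dataset()]s) and `truth` (planted scores, loadings, cluster
#'   memberships, centroids and participant weights).
#' @export
simulate_cohorts <- function(spec = generative_spec()) {
  stopifnot(inherits(spec, "generative_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  K <- spec$K_shared + spec$K_specific
  nv <- prod(spec$grid_shape)
  nc <- spec$n_concepts
  grid <- spec_grid(spec)
  cs <- synthetic_concepts(nc)
  cohort_names <- names(spec$n_participants)
  if (is.null(cohort_names)) cohort_names <- c("A", "B")

  # planted scores: orthonormal columns (QR of Gaussian), standardized
  S_shared <- if (spec$K_shared > 0L) {
    q <- qr.Q(qr(matrix(stats::rnorm(nc * spec$K_shared), nc)))
    standardize_cols(q)
  } else matrix(0, nc, 0L)
  rownames(S_shared) <- cs$labels

  S_specific <- lapply(seq_len(2L), function(g) {
    matrix(0, nc, spec$K_specific,
           dimnames = list(cs$labels, NULL))
  })
  if (spec$K_specific > 0L) {
    for (k in seq_len(spec$K_specific)) {
      a <- as.vector(standardize_cols(matrix(stats::rnorm(nc), nc)))
      e <- as.vector(standardize_cols(matrix(stats::rnorm(nc), nc)))
      b <- spec$specific_rho * a + sqrt(1 - spec$specific_rho^2) * e
      S_specific[[1L]][, k] <- a
      S_specific[[2L]][, k] <- as.vector(standardize_cols(matrix(b, nc)))
    }
  }

  clusters <- plant_clusters(spec$grid_shape, K, spec$cluster_size)
  L <- matrix(0, nv, K)
  for (k in seq_len(K))
    L[clusters[[k]], k] <- stats::runif(spec$cluster_size, 0.6, 1)
  coords <- voxel_coords(grid)
  centroids <- t(vapply(clusters, function(cl)
    colMeans(coords[cl, , drop = FALSE]), numeric(3L)))

  weights <- vector("list", 2L)
  cohorts <- vector("list", 2L)
  for (g in seq_len(2L)) {
    np <- spec$n_participants[[g]]
    w <- matrix(pmax(stats::rnorm(np * K, 1, spec$participant_sd), 0.2), np, K)
    weights[[g]] <- w
    S <- cbind(S_shared, S_specific[[g]])
    sal <- spec$salience[g, ]
    dat <- array(NA_real_, dim = c(np, spec$n_presentations, nc, nv),
                 dimnames = list(NULL, NULL, cs$labels, NULL))
    for (p in seq_len(np)) {
      signal <- S %*% (t(L) * (w[p, ] * sal))   # concept x voxel
      for (r in seq_len(spec$n_presentations)) {
        trial <- signal + matrix(stats::rnorm(nc * nv, 0, spec$noise_sd),
                                 nc, nv)
        dat[p, r, , ] <- ztrial(trial)
      }
    }
    ids <- sprintf("%s%02d", substr(cohort_names[g], 1L, 1L), seq_len(np))
    cohorts[[g]] <- activation_dataset(dat, ids, cohort_names[g], grid, cs,
                                       check = FALSE)
  }
  names(cohorts) <- cohort_names
  names(weights) <- cohort_names
  names(S_specific) <- cohort_names

  truth <- list(scores_shared = S_shared, scores_specific = S_specific,
                loadings = L, clusters = clusters, centroids = centroids,
                participant_weights = weights)
  list(cohorts = cohorts, truth = truth)
}

#' Pure-noise cohort with no planted structure
#'
#' Used to verify false-positive calibration: decoding on a null cohort must
#' hover at chance (0.5) and stability maps at 0.
#'
#' @param spec a [generative_spec()]; only the sizes and seed are used.
#' @param cohort which cohort's size to draw (index into `n_participants`).
#' @return An [activation_dataset()] of z-scored Gaussian noise.
#' @export
null_cohort <- function(spec = generative_spec(), cohort = 1L) {
  stopifnot(inherits(spec, "generative_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  nv <- prod(spec$grid_shape)
  nc <- spec$n_concepts
  np <- spec$n_participants[[cohort]]
  grid <- spec_grid(spec)
  cs <- synthetic_concepts(nc)
  dat <- array(stats::rnorm(np * spec$n_presentations * nc * nv),
               dim = c(np, spec$n_presentations, nc, nv),
               dimnames = list(NULL, NULL, cs$labels, NULL))
  for (p in seq_len(np)) for (r in seq_len(spec$n_presentations))
    dat[p, r, , ] <- ztrial(dat[p, r, , ])
  ids <- sprintf("n%02d", seq_len(np))
  activation_dataset(dat, ids, "null", grid, cs, check = FALSE)
}

#' Synthetic behavioral ratings derived from planted dimensions
#'
#' Maps each planted shared dimension's standardized factor scores onto a
#' bounded 1-7 rating scale with rater noise, emulating an independent group
#' rating each concept's saliency on each dimension.
#'
#' @param truth the `truth` element of [simulate_cohorts()].
#' @param noise_sd SD of rater noise on the 1-7 scale.
#' @param seed RNG seed.
#' @return A [ratings_table()] with one column per shared dimension.
#' @export
synthetic_ratings <- function(truth, noise_sd = 0.5, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  S <- truth$scores_shared
  vals <- 4 + 1.2 * S + matrix(stats::rnorm(length(S), 0, noise_sd),
                               nrow(S), ncol(S))
  vals <- pmin(pmax(vals, 1), 7)
  colnames(vals) <- sprintf("dim%d", seq_len(ncol(vals)))
  ratings_table(vals, rater_group = "synthetic")
}
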