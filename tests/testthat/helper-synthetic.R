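# Small generative specs used across tests (kept tiny so suites run fast).

tiny_spec <- function(seed = 1L, noise_sd = 0.5, ...) {
  generative_spec(grid_shape = c(6L, 5L, 4L), cluster_size = 15L,
                  K_shared = 2L, K_specific = 1L,
                  n_participants = c(a = 4L, b = 3L),
                  n_presentations = 4L, n_concepts = 12L,
                  noise_sd = noise_sd, seed = seed, ...)
}

# deterministic dataset built by hand: known per-trial patterns, z-scored
handmade_dataset <- function(n_participants = 2L, n_blocks = 6L,
                             n_concepts = 4L, n_voxels = 8L, noise_sd = 0,
                             seed = 42L) {
  set.seed(seed)
  cs <- concept_set(paste0("c", seq_len(n_concepts)),
                    stats::setNames(rep("cat", n_concepts),
                                    paste0("c", seq_len(n_concepts))))
  base <- matrix(stats::rnorm(n_concepts * n_voxels), n_concepts)
  dat <- array(NA_real_, c(n_participants, n_blocks, n_concepts, n_voxels),
               dimnames = list(NULL, NULL, cs$labels, NULL))
  for (p in seq_len(n_participants)) for (b in seq_len(n_blocks))
    dat[p, b, , ] <- ztrial(base + matrix(stats::rnorm(length(base), 0,
                                                       noise_sd),
                                          n_concepts))
  activation_dataset(dat, paste0("p", seq_len(n_participants)), "test",
                     voxel_grid(c(n_voxels, 1L, 1L)), cs, check = FALSE)
}

# brute-force Gaussian Bayes posterior: direct density computation
brute_force_posterior <- function(model, x) {
  dens <- vapply(model$classes, function(cl) {
    v <- if (model$pooled_variance) model$feature_variances
         else model$feature_variances[match(cl, model$classes), ]
    prod(stats::dnorm(x, model$class_means[cl, ], sqrt(v))) *
      model$priors[[cl]]
  }, numeric(1L))
  dens / sum(dens)
}

# independent connected-components oracle built on igraph
igraph_components <- function(coords, connectivity = 6L) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  lim <- switch(as.character(connectivity), "6" = 1L, "18" = 2L, "26" = 3L)
  edges <- integer(0)
  for (a in seq_len(n)) {
    d <- abs(sweep(coords, 2L, coords[a, ]))
    nb <- which(apply(d, 1L, max) <= 1L & rowSums(d) >= 1L & rowSums(d) <= lim)
    for (b in nb[nb > a]) edges <- c(edges, a, b)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# do two component labelings define the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(match(a, unique(a))),
              as.integer(match(b, unique(b))))
}
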