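#' Connected components of voxel coordinates
#'
#' Breadth-first flood fill over a set of 3-d integer coordinates, under
#' face (6), edge (18) or corner (26) connectivity.
#'
#' @param coords n x 3 integer matrix of voxel indices (any origin).
#' @param connectivity 6, 18 or 26.
#' @return Integer vector of length n assigning a component id to each row.
#' @export
connected_components <- function(coords, connectivity = 6L) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  offs <- neighbor_offsets(connectivity)
  lo <- apply(coords, 2L, min)
  dims <- apply(coords, 2L, max) - lo + 1L
  key <- function(m) (m[, 3L] - lo[3L]) * dims[1L] * dims[2L] +
    (m[, 2L] - lo[2L]) * dims[1L] + (m[, 1L] - lo[1L]) + 1L
  pos <- integer(prod(dims))
  pos[key(coords)] <- seq_len(n)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- sweep(offs, 2L, coords[v, ], `+`)
      inside <- nb[, 1L] >= lo[1L] & nb[, 1L] < lo[1L] + dims[1L] &
        nb[, 2L] >= lo[2L] & nb[, 2L] < lo[2L] + dims[2L] &
        nb[, 3L] >= lo[3L] & nb[, 3L] < lo[3L] + dims[3L]
      cand <- pos[key(nb[inside, , drop = FALSE])]
      cand <- cand[cand != 0L]
      cand <- cand[comp[cand] == 0L]
      if (length(cand)) {
        comp[cand] <- cid
        queue <- c(queue, cand)
      }
    }
  }
  comp
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1L, "18" = d >= 1L & d <= 2L, "26" = d >= 1L,
                 stop("connectivity must be 6, 18 or 26"))
  unname(g[keep, , drop = FALSE])
}

#' Factor locations: suprathreshold contiguous clusters and their spheres
#'
#' A factor's brain location is the set of voxels whose loading reaches the
#' threshold (default 0.4) and that form contiguous clusters of at least
#' `min_cluster` voxels (default 15; figure-style reporting sometimes uses
#' 10). Spheres of `sphere_radius` mm are centered on cluster centroids to
#' absorb minor inter-participant variation in voxel position.
#'
#' @param loadings numeric vector of one factor's loadings over
#'   `voxel_indices`.
#' @param grid the [voxel_grid()] the voxels live on.
#' @param voxel_indices dataset voxel indices the loadings refer to
#'   (default: all grid voxels in order).
#' @param threshold minimum loading (default 0.4, signed).
#' @param min_cluster minimum cluster size in voxels (default 15).
#' @param connectivity 6 (faces, default), 18 or 26.
#' @param sphere_radius sphere radius in mm (default 6).
#' @param factor label stored on the result.
#' @return An object of class `factor_location`: `clusters` (list of dataset
#'   voxel index vectors), `centroids_ijk` (0-based grid), `centroids_mm`,
#'   plus the parameters. Empty, with a warning, if no cluster survives.
#' @export
factor_locations <- function(loadings, grid, voxel_indices = NULL,
                             threshold = 0.4, min_cluster = 15L,
                             connectivity = 6L, sphere_radius = 6,
                             factor = NA) {
  if (is.null(voxel_indices)) voxel_indices <- seq_len(n_voxels(grid))
  if (length(loadings) != length(voxel_indices))
    stop("loadings must align with voxel_indices")
  supra <- which(loadings >= threshold)
  coords_all <- voxel_coords(grid)
  clusters <- list()
  centroids <- NULL
  if (length(supra)) {
    vox <- voxel_indices[supra]
    coords <- coords_all[vox, , drop = FALSE]
    comp <- connected_components(coords, connectivity)
    for (cidx in seq_len(max(comp))) {
      members <- which(comp == cidx)
      if (length(members) < min_cluster) next
      clusters[[length(clusters) + 1L]] <- vox[members]
      centroids <- rbind(centroids,
                         colMeans(coords[members, , drop = FALSE]))
    }
  }
  if (!length(clusters)) {
    warning("no suprathreshold cluster of >= ", min_cluster, " voxels")
    centroids <- matrix(numeric(0), 0L, 3L)
  }
  structure(list(factor = factor, clusters = clusters,
                 centroids_ijk = centroids,
                 centroids_mm = voxel_mm(grid, centroids),
                 sphere_radius = sphere_radius, threshold = threshold,
                 min_cluster = min_cluster, connectivity = connectivity),
            class = "factor_location")
}

#' @export
print.factor_location <- function(x, ...) {
  cat(sprintf("factor_location (factor %s): %d cluster(s) of sizes %s\n",
              as.character(x$factor), length(x$clusters),
              paste(vapply(x$clusters, length, 1L), collapse = ", ")))
  invisible(x)
}

#' Voxels inside the location spheres
#'
#' Union of all in-mask voxels within `sphere_radius` mm of any cluster
#' centroid, across one or several factor locations.
#'
#' @param locations a `factor_location` or list of them.
#' @param grid the [voxel_grid()].
#' @return Sorted integer vector of dataset voxel indices.
#' @export
sphere_voxels <- function(locations, grid) {
  if (inherits(locations, "factor_location")) locations <- list(locations)
  mm <- voxel_mm(grid, voxel_coords(grid))
  keep <- rep(FALSE, nrow(mm))
  for (loc in locations) {
    if (!nrow(loc$centroids_mm)) next
    for (i in seq_len(nrow(loc$centroids_mm))) {
      d2 <- colSums((t(mm) - loc$centroids_mm[i, ])^2)
      keep <- keep | d2 <= loc$sphere_radius^2
    }
  }
  which(keep)
}
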