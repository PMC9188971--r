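#' Voxel grid geometry
#'
#' Container for the common grid all participants share: integer shape, a 4x4
#' affine mapping 0-based voxel indices to mm coordinates, and a logical mask
#' marking analyzable (gray-matter) voxels. The voxel dimension of every
#' dataset on the grid equals `sum(mask)`; masked voxels are enumerated in
#' column-major (R array) order.
#'
#' @param shape integer vector of length 3, voxel counts per axis.
#' @param affine 4x4 invertible matrix; defaults to identity (mm == index).
#' @param mask logical array of dim `shape`; defaults to all `TRUE`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, affine = NULL, mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("shape must be 3 positive integers")
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  if (!identical(dim(mask), shape)) stop("mask dim must equal shape")
  mask <- array(as.logical(mask), dim = shape)
  structure(list(shape = shape, affine = affine, mask = mask),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %s grid, %d voxels in mask\n",
              paste(x$shape, collapse = "x"), n_voxels(x)))
  invisible(x)
}

#' Number of in-mask voxels
#' @param grid a [voxel_grid()].
#' @return Integer count.
#' @export
n_voxels <- function(grid) sum(grid$mask)

#' 0-based grid indices of the in-mask voxels
#'
#' @param grid a [voxel_grid()].
#' @return `n_voxels(grid)` x 3 integer matrix of 0-based (i, j, k) indices,
#'   row v giving the grid position of dataset voxel v.
#' @export
voxel_coords <- function(grid) {
  idx <- which(grid$mask, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  idx <- idx[order(which(grid$mask)), , drop = FALSE]
  colnames(idx) <- c("i", "j", "k")
  idx - 1L
}

#' Map 0-based voxel indices to mm coordinates through the affine
#' @param grid a [voxel_grid()].
#' @param ijk n x 3 matrix of 0-based indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_mm <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  if (nrow(ijk) == 0L) return(ijk)
  h <- cbind(ijk, 1)
  mm <- h %*% t(grid$affine)
  mm[, 1:3, drop = FALSE]
}
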