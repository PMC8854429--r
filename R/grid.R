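#' Voxel grid geometry
#'
#' A `voxel_grid` describes a regular 3D sampling lattice: the number of
#' voxels per axis, the voxel edge lengths in millimetres, and a 4x4 affine
#' mapping 0-based voxel indices to world coordinates in mm at voxel
#' centres. All volumes entering one tract analysis must share an
#' identical grid (dimensions and affine).
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0). Ignored when `affine` is supplied (then derived from it).
#' @param affine optional 4x4 matrix mapping 0-based voxel index to world
#'   mm. Defaults to `diag(voxel_size)` with zero origin.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, voxel_size = c(2, 2, 2), affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L)
  if (any(dims < 1L)) stop("grid dims must all be >= 1")
  if (is.null(affine)) {
    voxel_size <- as.numeric(voxel_size)
    stopifnot(length(voxel_size) == 3L)
    if (any(voxel_size <= 0)) stop("voxel_size must be positive")
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- unname(as.matrix(affine))
    stopifnot(all(dim(affine) == c(4L, 4L)))
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) stop("affine must be invertible")
  structure(
    list(dims = dims, voxel_size = voxel_size, affine = affine),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
    x$dims[1], x$dims[2], x$dims[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

#' Convert voxel indices to world coordinates
#'
#' Voxel indices are 0-based; world coordinates are mm at voxel centres.
#'
#' @param grid a [voxel_grid()].
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
index_to_world <- function(grid, ijk) {
  ijk <- rbind_coerce(ijk)
  h <- cbind(ijk, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' Convert world coordinates to voxel indices
#'
#' Inverse of [index_to_world()]; returns fractional (not rounded)
#' 0-based indices.
#'
#' @inheritParams index_to_world
#' @param xyz n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @export
world_to_index <- function(grid, xyz) {
  xyz <- rbind_coerce(xyz)
  h <- cbind(xyz, 1) %*% t(solve(grid$affine))
  h[, 1:3, drop = FALSE]
}

rbind_coerce <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == 3L)
  x
}

#' @rdname voxel_grid
#' @param a,b two `voxel_grid` objects.
#' @param tol numeric tolerance on affine entries.
#' @export
grids_identical <- function(a, b, tol = 1e-4) {
  all(a$dims == b$dims) && max(abs(a$affine - b$affine)) <= tol
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!grids_identical(grid_of(a), grid_of(b)))
    stop("grid mismatch: ", what, " must share an identical voxel grid")
  invisible(TRUE)
}

grid_of <- function(x) {
  if (inherits(x, "voxel_grid")) x else x$grid
}

#' World coordinates of all voxel centres
#'
#' @param grid a [voxel_grid()].
#' @return an `prod(dims)` x 3 matrix, rows in R array (column-major) order.
#' @export
voxel_centres <- function(grid) {
  d <- grid$dims
  ijk <- as.matrix(expand.grid(
    i = 0:(d[1] - 1L), j = 0:(d[2] - 1L), k = 0:(d[3] - 1L)
  ))
  index_to_world(grid, ijk)
}

#' Scalar, vector and mask volumes
#'
#' Light containers pairing a data array with its [voxel_grid()].
#' `scalar_volume` holds one value per voxel (visitation probabilities,
#' uncertainty fields, TSA maps); `vector_volume` holds a 3-vector per
#' voxel (mean streamline orientations; the zero vector means no
#' orientation is defined at that voxel); `roi_mask` holds logical
#' membership flags for a named region of interest.
#'
#' @param values numeric array with `dim == grid$dims`.
#' @param grid a [voxel_grid()].
#' @param probability if `TRUE`, enforce values in \[0, 1\].
#' @return classed list with elements `grid` and `values` (or `vectors`,
#'   `mask`).
#' @export
scalar_volume <- function(values, grid, probability = FALSE) {
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$dims))
    stop("values dimensions do not match grid dims")
  if (probability) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("probability volume values must lie in [0, 1]")
    values[] <- pmin(pmax(values, 0), 1)
  }
  structure(list(grid = grid, values = values), class = "scalar_volume")
}

#' @rdname scalar_volume
#' @param vectors numeric 4D array `c(grid$dims, 3)`; nonzero vectors must
#'   have unit norm (tolerance 1e-6).
#' @export
vector_volume <- function(vectors, grid) {
  vectors <- as.array(vectors)
  if (!identical(as.integer(dim(vectors)), c(grid$dims, 3L)))
    stop("vectors must be a 4D array with last dimension 3 matching the grid")
  m <- matrix(vectors, ncol = 3)
  nrm <- sqrt(rowSums(m^2))
  bad <- nrm > 1e-12 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop(sum(bad), " orientation vectors are neither zero nor unit-norm")
  structure(list(grid = grid, vectors = vectors), class = "vector_volume")
}

#' @rdname scalar_volume
#' @param mask logical array with `dim == grid$dims`; at least one voxel
#'   must be a member.
#' @param label name of the region.
#' @export
roi_mask <- function(mask, grid, label = "roi") {
  mask <- array(as.logical(mask), dim = grid$dims)
  if (!any(mask)) stop("ROI mask '", label, "' has no member voxels")
  structure(list(grid = grid, mask = mask, label = label), class = "roi_mask")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume>"); print(x$grid)
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.vector_volume <- function(x, ...) {
  nz <- sum(rowSums(matrix(x$vectors, ncol = 3)^2) > 0)
  cat("<vector_volume>"); print(x$grid)
  cat(sprintf("  %d voxels with a defined orientation\n", nz))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels\n", x$label, sum(x$mask)))
  invisible(x)
}
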