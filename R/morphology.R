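#' Voxel neighbourhood offsets
#'
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces + edges
#'   + corners).
#' @return an n x 3 integer matrix of index offsets (excluding the origin).
#' @export
neighbour_offsets <- function(connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
    "6"  = ord == 1L,
    "18" = ord >= 1L & ord <= 2L,
    "26" = ord >= 1L
  )
  unname(off[keep, , drop = FALSE])
}

# Linear-index neighbour expansion on a dims grid: returns the unique
# in-bounds neighbours of the given linear indices (1-based).
expand_neighbours <- function(lin, dims, offsets) {
  if (length(lin) == 0L) return(integer(0))
  ijk <- arrayInd(lin, dims)
  n <- nrow(ijk)
  m <- nrow(offsets)
  cand <- ijk[rep.int(seq_len(n), m), , drop = FALSE] +
    offsets[rep(seq_len(m), each = n), , drop = FALSE]
  ok <- cand[, 1] >= 1L & cand[, 1] <= dims[1] &
        cand[, 2] >= 1L & cand[, 2] <= dims[2] &
        cand[, 3] >= 1L & cand[, 3] <= dims[3]
  cand <- cand[ok, , drop = FALSE]
  unique(cand[, 1] + dims[1] * (cand[, 2] - 1L) +
         dims[1] * dims[2] * (cand[, 3] - 1L))
}

#' Morphological dilation of a voxel mask
#'
#' Iterative dilation with the structuring element implied by
#' `connectivity` (default 26: a 3x3x3 cube neighbourhood per iteration).
#'
#' @param mask logical 3D array, or an [roi_mask()].
#' @param voxels number of dilation iterations.
#' @param connectivity structuring-element connectivity (6/18/26).
#' @return same type as the input.
#' @export
dilate_mask <- function(mask, voxels = 3, connectivity = 26) {
  is_roi <- inherits(mask, "roi_mask")
  arr <- if (is_roi) mask$mask else mask
  dims <- dim(arr)
  offsets <- neighbour_offsets(connectivity)
  current <- which(arr)
  frontier <- current
  inmask <- arr
  for (it in seq_len(voxels)) {
    nb <- expand_neighbours(frontier, dims, offsets)
    nb <- nb[!inmask[nb]]
    if (length(nb) == 0L) break
    inmask[nb] <- TRUE
    frontier <- nb
  }
  if (is_roi) roi_mask(inmask, mask$grid, label = mask$label) else inmask
}

# Separable Gaussian filtering of a 3D array, kernel truncated at 4 sigma,
# zero-padded at the borders; kernel weights are renormalised to sum 1 so
# an all-ones field maps to <= 1 (exactly 1 away from borders).
gaussian_filter_3d <- function(arr, fwhm, voxel_size) {
  if (length(fwhm) == 1L) fwhm <- rep(fwhm, 3L)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  out <- arr
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, axis)
  }
  out
}

# Shift-and-add 1D convolution along one axis with zero padding.
convolve_axis <- function(arr, kernel, axis) {
  dims <- dim(arr)
  r <- (length(kernel) - 1L) %/% 2L
  acc <- array(0, dims)
  n <- dims[axis]
  for (t in -r:r) {
    w <- kernel[t + r + 1L]
    src <- seq_len(n) + t
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    dst_idx <- which(ok)
    src_idx <- src[ok]
    idx_dst <- switch(axis,
      list(dst_idx, TRUE, TRUE), list(TRUE, dst_idx, TRUE),
      list(TRUE, TRUE, dst_idx))
    idx_src <- switch(axis,
      list(src_idx, TRUE, TRUE), list(TRUE, src_idx, TRUE),
      list(TRUE, TRUE, src_idx))
    acc <- acc + w * shift_fill(arr, idx_src, idx_dst, dims)
  }
  acc
}

shift_fill <- function(arr, idx_src, idx_dst, dims) {
  out <- array(0, dims)
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Gaussian smoothing of a scalar volume
#'
#' Smooths with a Gaussian kernel parameterised by its full-width at
#' half-maximum in mm. When a mask is given, masked smoothing is used:
#' voxels outside the mask contribute neither signal nor normalisation,
#' so constant fields are preserved inside the mask and no signal bleeds
#' across its boundary.
#'
#' @param vol a [scalar_volume()].
#' @param fwhm full-width at half-maximum in mm (scalar or per-axis);
#'   0 is the identity.
#' @param mask optional logical array or [roi_mask()] restricting the
#'   smoothing support.
#' @return a [scalar_volume()].
#' @export
smooth_volume <- function(vol, fwhm, mask = NULL) {
  if (all(fwhm <= 0)) return(vol)
  grid <- vol$grid
  if (is.null(mask)) {
    sm <- gaussian_filter_3d(vol$values, fwhm, grid$voxel_size)
    return(scalar_volume(sm, grid))
  }
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  v <- vol$values
  v[!m] <- 0
  num <- gaussian_filter_3d(v, fwhm, grid$voxel_size)
  den <- gaussian_filter_3d(array(as.numeric(m), dim = grid$dims),
                            fwhm, grid$voxel_size)
  out <- array(0, grid$dims)
  ok <- m & den > 0
  out[ok] <- num[ok] / den[ok]
  scalar_volume(out, grid)
}
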