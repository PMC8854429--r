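#' Tract-orientation signal regressor
#'
#' Builds the per-gradient regressor `exp(-b * delta * (r_i . v)^2)` for
#' a voxel with mean tract orientation v. The dot product is squared, so
#' the regressor is antipodally symmetric (flipping v changes nothing).
#'
#' @param v_bar unit 3-vector (mean streamline orientation).
#' @param gradients a `gradient_table`.
#' @param diffusivity diffusivity delta in mm^2/s (> 0).
#' @return numeric vector of length M (one value per gradient).
#' @export
tsa_regressor <- function(v_bar, gradients, diffusivity) {
  v_bar <- as.numeric(v_bar)
  nrm <- sqrt(sum(v_bar^2))
  if (nrm < 1e-12) stop("undefined orientation: v_bar is the zero vector")
  if (abs(nrm - 1) > 1e-6) stop("v_bar must have unit norm")
  if (diffusivity <= 0) stop("diffusivity must be > 0")
  proj <- as.numeric(gradients$bvecs %*% v_bar)
  exp(-gradients$bval * diffusivity * proj^2)
}

#' Fit tract-specific anisotropy at one voxel
#'
#' Ordinary least squares of the normalised signal `y = signal / s0` on
#' the orientation regressor plus an intercept. The slope is the
#' tract-specific anisotropy (TSA): the fraction of the normalised
#' diffusion-weighted signal explained by the tract's mean orientation.
#' No non-negativity constraint is applied; negative estimates are
#' retained and flow into the statistics.
#'
#' @param signal numeric M-vector of DWI intensities.
#' @param s0 non-diffusion-weighted signal (> 0).
#' @param regressor M-vector from [tsa_regressor()].
#' @return named numeric vector `c(beta =, intercept =)`.
#' @export
fit_tsa_voxel <- function(signal, s0, regressor) {
  if (s0 <= 0) stop("s0 must be > 0")
  if (length(signal) != length(regressor))
    stop("signal and regressor lengths differ")
  x <- regressor
  sxx <- sum(x^2) - length(x) * mean(x)^2
  if (sxx < 1e-12)
    stop("collinear fit: regressor is constant across gradients")
  y <- signal / s0
  beta <- (sum(x * y) - length(x) * mean(x) * mean(y)) / sxx
  c(beta = beta, intercept = mean(y) - beta * mean(x))
}

# vectorised simple OLS: columns of Y (M x n) regressed on matching
# columns of X; returns list(beta, intercept, ok)
fit_tsa_columns <- function(Y, X) {
  m <- nrow(X)
  xbar <- colMeans(X)
  ybar <- colMeans(Y)
  sxx <- colSums(X^2) - m * xbar^2
  sxy <- colSums(X * Y) - m * xbar * ybar
  ok <- sxx >= 1e-12
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  list(beta = beta, intercept = ifelse(ok, ybar - beta * xbar, NA_real_),
       ok = ok)
}

#' Fit tract-specific anisotropy for one participant
#'
#' Applies the voxel-wise orientation regression at every support voxel
#' using that voxel's mean orientation and diffusivity. Voxels with no
#' orientation, non-positive s0, or a constant regressor are flagged
#' unfitted rather than raising errors.
#'
#' @param dwi participant DWI data: a 4D array `c(dims, M)`, or an
#'   M x n matrix whose columns correspond to `support` voxel indices.
#' @param b0 [scalar_volume()] of non-diffusion-weighted signal.
#' @param orientation [vector_volume()] of mean tract orientations.
#' @param support logical array or linear voxel indices of the tract
#'   support.
#' @param gradients a `gradient_table`.
#' @param diffusivity a [scalar_volume()] diffusivity map, or a single
#'   scalar (mm^2/s; 1e-3 is typical white matter).
#' @param participant_id identifier stored with the result.
#' @return a `tsa_volume`: list with `grid`, `beta` and `intercept`
#'   arrays (NA where unfitted), logical `fitted` array, and
#'   `participant_id`.
#' @export
fit_tsa_participant <- function(dwi, b0, orientation, support, gradients,
                                diffusivity = 1e-3,
                                participant_id = "participant") {
  grid <- orientation$grid
  check_same_grid(b0, orientation)
  support_idx <- if (is.logical(support) || is.array(support)) {
    which(as.logical(support))
  } else as.integer(support)
  m <- nrow(gradients$bvecs)
  if (is.matrix(dwi)) {
    if (nrow(dwi) != m || ncol(dwi) != length(support_idx))
      stop("dwi matrix must be M x n_support")
    Y <- dwi
  } else {
    dm <- dim(dwi)
    if (length(dm) != 4L || !identical(as.integer(dm[1:3]), grid$dims) ||
        dm[4] != m)
      stop("grid mismatch: dwi must be c(grid dims, M)")
    flat <- matrix(dwi, ncol = dm[4])
    Y <- t(flat[support_idx, , drop = FALSE])
  }
  vec <- matrix(orientation$vectors, ncol = 3)[support_idx, , drop = FALSE]
  has_orient <- rowSums(vec^2) > 0
  s0 <- b0$values[support_idx]
  dvals <- if (inherits(diffusivity, "scalar_volume")) {
    diffusivity$values[support_idx]
  } else rep(diffusivity, length(support_idx))
  usable <- has_orient & s0 > 0 & dvals > 0
  beta <- array(NA_real_, grid$dims)
  intercept <- array(NA_real_, grid$dims)
  fitted <- array(FALSE, grid$dims)
  if (any(usable)) {
    ui <- which(usable)
    proj <- gradients$bvecs %*% t(vec[ui, , drop = FALSE])
    X <- exp(-gradients$bval * sweep(proj^2, 2, dvals[ui], `*`))
    Yn <- sweep(Y[, ui, drop = FALSE], 2, s0[ui], `/`)
    fit <- fit_tsa_columns(Yn, X)
    vox <- support_idx[ui]
    beta[vox] <- fit$beta
    intercept[vox] <- fit$intercept
    fitted[vox] <- fit$ok
    beta[vox[!fit$ok]] <- NA_real_
  }
  structure(
    list(grid = grid, beta = beta, intercept = intercept, fitted = fitted,
         participant_id = participant_id),
    class = "tsa_volume"
  )
}

#' @export
print.tsa_volume <- function(x, ...) {
  cat(sprintf("<tsa_volume> '%s': %d fitted voxels\n",
              x$participant_id, sum(x$fitted)))
  if (any(x$fitted))
    cat(sprintf("  beta in [%.4g, %.4g]\n",
                min(x$beta[x$fitted]), max(x$beta[x$fitted])))
  invisible(x)
}

#' Fit TSA maps for a whole cohort
#'
#' Convenience wrapper running [fit_tsa_participant()] over every
#' participant of a [make_dwi_signal()] dataset, with optional masked
#' smoothing of each map.
#'
#' @param dwi_data a `dwi_dataset`.
#' @param orientation [vector_volume()] of mean tract orientations.
#' @param smoothing_fwhm Gaussian FWHM in mm applied to each
#'   participant's beta map over its fitted support (default 1.5;
#'   0 disables).
#' @param diffusivity as in [fit_tsa_participant()]; defaults to the
#'   generating spec's diffusivity.
#' @return list of `tsa_volume` objects, one per participant.
#' @export
fit_tsa_cohort <- function(dwi_data, orientation, smoothing_fwhm = 1.5,
                           diffusivity = NULL) {
  if (is.null(diffusivity)) diffusivity <- dwi_data$spec$diffusivity
  ids <- names(dwi_data$signals)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (k in seq_along(ids)) {
    tsa <- fit_tsa_participant(dwi_data$signals[[k]], dwi_data$b0,
                               orientation, dwi_data$support_idx,
                               dwi_data$gradients, diffusivity,
                               participant_id = ids[k])
    if (smoothing_fwhm > 0) tsa <- smooth_tsa(tsa, smoothing_fwhm)
    out[[k]] <- tsa
  }
  out
}

#' Smooth a TSA map
#'
#' Masked Gaussian smoothing of the beta map over the fitted voxels:
#' unfitted voxels contribute neither signal nor kernel normalisation,
#' so constants are preserved and no mass bleeds outside the tract
#' support. `fwhm = 0` is the identity.
#'
#' @param tsa a `tsa_volume`.
#' @param fwhm full-width at half-maximum in mm (default 1.5).
#' @return a `tsa_volume` with smoothed `beta`.
#' @export
smooth_tsa <- function(tsa, fwhm = 1.5) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0 || !any(tsa$fitted)) return(tsa)
  grid <- tsa$grid
  b <- tsa$beta
  b[!tsa$fitted] <- 0
  vol <- smooth_volume(scalar_volume(b, grid), fwhm, mask = tsa$fitted)
  out <- array(NA_real_, grid$dims)
  out[tsa$fitted] <- vol$values[tsa$fitted]
  tsa$beta <- out
  tsa
}
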