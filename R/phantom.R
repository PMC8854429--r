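#' Ground-truth curves for phantom tracts
#'
#' Helpers producing finely sampled 3D polylines (in world mm) used as
#' ground-truth tract cores by the phantom generator. `curve_line` is a
#' straight segment; `curve_arc` is a circular arc through the two
#' endpoints with a given apex offset ("bulge") perpendicular to the
#' chord.
#'
#' @param from,to endpoints in world mm (length-3 vectors).
#' @param step resampling step along the curve in mm.
#' @return an n x 3 matrix of points at `step` mm spacing.
#' @export
curve_line <- function(from, to, step = 0.5) {
  resample_polyline(rbind(from, to), step)
}

#' @rdname curve_line
#' @param bulge apex offset in mm, applied at the chord midpoint along
#'   `normal`.
#' @param normal unit direction of the bulge (defaults to the axis most
#'   orthogonal to the chord).
#' @export
curve_arc <- function(from, to, bulge, normal = NULL, step = 0.5) {
  from <- as.numeric(from); to <- as.numeric(to)
  chord <- to - from
  if (is.null(normal)) {
    ax <- diag(3)[, which.min(abs(chord))]
    normal <- ax - chord * sum(ax * chord) / sum(chord^2)
  }
  normal <- normal / sqrt(sum(normal^2))
  apex <- (from + to) / 2 + bulge * normal
  # circle through three points, sampled in their common plane
  e1 <- chord / sqrt(sum(chord^2))
  e2 <- normal
  p <- function(x) c(sum((x - from) * e1), sum((x - from) * e2))
  a <- p(from); b <- p(apex); d <- p(to)
  centre2 <- circumcentre_2d(a, b, d)
  r <- sqrt(sum((a - centre2)^2))
  th <- function(q) atan2(q[2] - centre2[2], q[1] - centre2[1])
  t0 <- th(a); t1 <- th(b); t2 <- th(d)
  # sweep from t0 to t2 passing through t1
  sweep <- (t2 - t0) %% (2 * pi)
  mid <- (t1 - t0) %% (2 * pi)
  if (mid > sweep) sweep <- sweep - 2 * pi
  n <- max(8L, ceiling(abs(sweep) * r / step))
  ang <- t0 + sweep * seq(0, 1, length.out = n + 1L)
  pts2 <- cbind(centre2[1] + r * cos(ang), centre2[2] + r * sin(ang))
  pts <- sweep(pts2[, 1] %o% e1 + pts2[, 2] %o% e2, 2,
               -from, check.margin = FALSE)
  resample_polyline(pts, step)
}

circumcentre_2d <- function(a, b, c) {
  m <- rbind(2 * (b - a), 2 * (c - a))
  rhs <- c(sum(b^2) - sum(a^2), sum(c^2) - sum(a^2))
  as.numeric(solve(m, rhs))
}

# resample a polyline at uniform arc-length spacing
resample_polyline <- function(points, step = 0.5) {
  points <- as.matrix(points)
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- seq(0, total, by = step)
  if (at[length(at)] < total) at <- c(at, total)
  t(vapply(at, function(u) {
    i <- findInterval(u, s, rightmost.closed = TRUE)
    i <- min(i, nrow(points) - 1L)
    w <- if (seg[i] > 0) (u - s[i]) / seg[i] else 0
    points[i, ] * (1 - w) + points[i + 1L, ] * w
  }, numeric(3)))
}

curve_tangents <- function(points) {
  n <- nrow(points)
  tg <- rbind(
    points[2, ] - points[1, ],
    points[seq(3, n), , drop = FALSE] - points[seq(1, n - 2), , drop = FALSE],
    points[n, ] - points[n - 1, ]
  )
  tg / sqrt(rowSums(tg^2))
}

#' Phantom specification
#'
#' Describes a synthetic tract phantom: a ground-truth core curve inside
#' a voxel grid, a Gaussian visitation-probability tube of radial scale
#' `tube_sigma` around it, optional competing alternative routes with
#' relative amplitude below 1, and spherical seed/target ROIs at the
#' curve endpoints.
#'
#' @param grid a [voxel_grid()].
#' @param curve n x 3 matrix of world-mm points (see [curve_line()]).
#' @param tube_sigma radial Gaussian decay of visitation probability, mm.
#' @param alt_curves optional list of `list(points =, amplitude =)` with
#'   amplitude in (0, 1).
#' @param roi_radius radius in mm of the terminal ROI balls.
#' @param seed integer seed controlling all phantom randomness.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid, curve, tube_sigma = 4, alt_curves = list(),
                         roi_radius = 4, seed = 1L) {
  curve <- as.matrix(curve)
  stopifnot(ncol(curve) == 3L, nrow(curve) >= 2L)
  if (tube_sigma <= 0) stop("tube_sigma must be > 0")
  for (ac in alt_curves) {
    if (is.null(ac$points) || is.null(ac$amplitude))
      stop("each alt_curve needs 'points' and 'amplitude'")
    if (ac$amplitude <= 0 || ac$amplitude >= 1)
      stop("alt_curve amplitudes must lie in (0, 1)")
  }
  check_curve_inside(grid, curve, roi_radius)
  structure(
    list(grid = grid, curve = curve, tube_sigma = tube_sigma,
         alt_curves = alt_curves, roi_radius = roi_radius,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

check_curve_inside <- function(grid, curve, margin_mm) {
  idx <- world_to_index(grid, curve)
  margin_vox <- margin_mm / grid$voxel_size
  lo <- sweep(idx, 2, margin_vox, `-`)
  hi <- sweep(idx, 2, grid$dims - 1 - margin_vox, `-`)
  ends <- c(1L, nrow(curve))
  if (any(lo[ends, ] < 0) || any(hi[ends, ] > 0))
    stop("curve endpoints must lie inside the grid with >= roi_radius margin")
  if (any(idx < 0) || any(sweep(idx, 2, grid$dims - 1, `-`) > 0))
    stop("curve leaves the voxel grid")
  invisible(TRUE)
}

# deterministic part of the phantom: population probability field,
# orientation field, and terminal ROIs
phantom_field <- function(spec) {
  grid <- spec$grid
  ctr <- voxel_centres(grid)
  curves <- c(list(list(points = spec$curve, amplitude = 1)), spec$alt_curves)
  best_p <- rep(0, nrow(ctr))
  best_tan <- matrix(0, nrow(ctr), 3)
  best_d <- rep(Inf, nrow(ctr))
  for (cv in curves) {
    pts <- as.matrix(cv$points)
    tg <- curve_tangents(pts)
    d2 <- rep(Inf, nrow(ctr))
    ni <- rep(1L, nrow(ctr))
    for (i in seq_len(nrow(pts))) {
      dd <- (ctr[, 1] - pts[i, 1])^2 + (ctr[, 2] - pts[i, 2])^2 +
            (ctr[, 3] - pts[i, 3])^2
      upd <- dd < d2
      d2[upd] <- dd[upd]
      ni[upd] <- i
    }
    p <- cv$amplitude * exp(-d2 / (2 * spec$tube_sigma^2))
    take <- p > best_p
    best_p[take] <- p[take]
    closer <- d2 < best_d^2
    best_tan[closer, ] <- tg[ni[closer], , drop = FALSE]
    best_d[closer] <- sqrt(d2[closer])
  }
  vec <- best_tan
  vec[best_p <= 1e-3, ] <- 0
  ends <- spec$curve[c(1L, nrow(spec$curve)), , drop = FALSE]
  ball <- function(centre) {
    d <- sqrt((ctr[, 1] - centre[1])^2 + (ctr[, 2] - centre[2])^2 +
              (ctr[, 3] - centre[3])^2)
    roi_mask(array(d <= spec$roi_radius, grid$dims), grid)
  }
  roi_a <- ball(ends[1, ]); roi_a$label <- "roi_a"
  roi_b <- ball(ends[2, ]); roi_b$label <- "roi_b"
  list(
    p = array(best_p, grid$dims),
    orientation = vector_volume(array(vec, c(grid$dims, 3L)), grid),
    roi_a = roi_a, roi_b = roi_b
  )
}

#' Generate a directed visitation-probability pair from a phantom
#'
#' Produces the two directed visitation maps (seed-to-target and
#' target-to-seed), the mean streamline-orientation volume, and the two
#' terminal ROI masks for a phantom tract. Each directed map is the
#' Gaussian tube `exp(-r^2 / (2 tube_sigma^2))` around the nearest curve,
#' scaled by direction-specific multiplicative log-normal jitter
#' (clipped to 1); alternative curves contribute with their stated
#' relative amplitude. The orientation volume holds the unit tangent of
#' the nearest curve wherever the noiseless probability exceeds 1e-3.
#'
#' @param spec a [phantom_spec()].
#' @param jitter_sd log-scale sd of the direction-specific multiplicative
#'   jitter (0 disables it).
#' @return list with elements `ab`, `ba` ([scalar_volume()] probability
#'   maps), `orientation` ([vector_volume()]), `roi_a`, `roi_b`
#'   ([roi_mask()]), and `p_noiseless` (the jitter-free field).
#' @export
make_probability_pair <- function(spec, jitter_sd = 0.1) {
  fld <- phantom_field(spec)
  set.seed(spec$seed)
  jitter <- function() {
    if (jitter_sd <= 0) return(fld$p)
    array(pmin(1, fld$p * exp(stats::rnorm(length(fld$p), 0, jitter_sd))),
          spec$grid$dims)
  }
  list(
    ab = scalar_volume(jitter(), spec$grid, probability = TRUE),
    ba = scalar_volume(jitter(), spec$grid, probability = TRUE),
    orientation = fld$orientation,
    roi_a = fld$roi_a, roi_b = fld$roi_b,
    p_noiseless = scalar_volume(fld$p, spec$grid, probability = TRUE)
  )
}

#' @rdname make_probability_pair
#' @param n_participants number of participants; each receives the
#'   population field scaled by participant-level log-normal jitter
#'   (sd `participant_sd`), then direction-specific jitter per map.
#' @param participant_sd log-scale sd of the participant-level jitter.
#' @return `make_participant_pairs`: list with `pairs` (per participant,
#'   a list of `ab`/`ba` probability volumes), plus the shared
#'   `orientation`, `roi_a`, `roi_b`, `p_noiseless`.
#' @export
make_participant_pairs <- function(spec, n_participants, jitter_sd = 0.1,
                                   participant_sd = 0.05) {
  fld <- phantom_field(spec)
  set.seed(spec$seed)
  nv <- length(fld$p)
  pairs <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    base <- if (participant_sd > 0) {
      fld$p * exp(stats::rnorm(nv, 0, participant_sd))
    } else fld$p
    draw <- function() {
      v <- if (jitter_sd > 0) base * exp(stats::rnorm(nv, 0, jitter_sd)) else base
      scalar_volume(array(pmin(1, v), spec$grid$dims), spec$grid,
                    probability = TRUE)
    }
    pairs[[p]] <- list(ab = draw(), ba = draw())
  }
  list(pairs = pairs, orientation = fld$orientation,
       roi_a = fld$roi_a, roi_b = fld$roi_b,
       p_noiseless = scalar_volume(fld$p, spec$grid, probability = TRUE))
}

#' Generate a synthetic cohort table
#'
#' Ages are uniform over `age_range`; sex (1 = male, 2 = female) is
#' assigned so the female count matches `female_fraction` as closely as
#' integer counts allow, in shuffled order. Deterministic given `seed`.
#'
#' @param n number of participants (>= 2).
#' @param age_range length-2 numeric, years.
#' @param female_fraction fraction of participants coded sex = 2.
#' @param seed integer seed.
#' @return a `cohort_table`.
#' @export
make_cohort <- function(n, age_range = c(18, 80), female_fraction = 86 / 130,
                        seed = 1L) {
  if (n < 2) stop("cohort needs n >= 2")
  set.seed(seed)
  ages <- stats::runif(n, age_range[1], age_range[2])
  n_f <- round(n * female_fraction)
  n_f <- min(max(n_f, 0L), n)
  sex <- sample(c(rep(2L, n_f), rep(1L, n - n_f)))
  cohort_table(data.frame(
    participant_id = sprintf("sub-%03d", seq_len(n)),
    age = ages, sex = sex, stringsAsFactors = FALSE
  ))
}

#' Diffusion-signal generation specification
#'
#' Defines the forward model for synthetic DWI signals: at voxel j with
#' mean tract orientation v_j, the normalised signal at gradient r_i is
#' `beta_j * exp(-b * delta * (r_i . v_j)^2) + c_j` plus noise, where
#' beta_j is the voxel's true anisotropy fraction after adding the
#' cohort covariate effects (age slope, sex effect, age-by-sex
#' interaction) inside the designated effect region.
#'
#' @param gradients a `gradient_table`.
#' @param beta_true [scalar_volume()] of true anisotropy fractions in
#'   \[0, 1\].
#' @param intercept_true [scalar_volume()] of baseline fractions;
#'   `beta_true + intercept_true` must not exceed 1 anywhere (before
#'   covariate effects).
#' @param cohort a `cohort_table`.
#' @param diffusivity scalar diffusivity delta in mm^2/s.
#' @param noise_sd noise level relative to the b0 signal (>= 0).
#' @param age_slope,sex_effect,interaction_effect additive effects on
#'   beta_true per year of age, per sex code, and per year x code.
#' @param effect_region logical array or [roi_mask()] where the effects
#'   apply (default: wherever `beta_true > 0`).
#' @param s0 non-diffusion-weighted signal level (constant).
#' @param noise_model `"gaussian"` (additive, default) or `"rician"`.
#' @param seed integer seed; participant p uses sub-seed
#'   `seed + 7919 * p`.
#' @return a `signal_spec`.
#' @export
signal_spec <- function(gradients, beta_true, intercept_true, cohort,
                        diffusivity = 1e-3, noise_sd = 0,
                        age_slope = 0, sex_effect = 0,
                        interaction_effect = 0, effect_region = NULL,
                        s0 = 1000, noise_model = c("gaussian", "rician"),
                        seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(gradients, "gradient_table"),
            inherits(beta_true, "scalar_volume"),
            inherits(intercept_true, "scalar_volume"))
  check_same_grid(beta_true, intercept_true)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (diffusivity <= 0) stop("diffusivity must be > 0")
  tot <- beta_true$values + intercept_true$values
  if (any(tot > 1 + 1e-9))
    stop("beta_true + intercept_true exceeds 1 at ",
         sum(tot > 1 + 1e-9), " voxels")
  if (is.null(effect_region)) {
    effect_region <- beta_true$values > 0
  } else if (inherits(effect_region, "roi_mask")) {
    effect_region <- effect_region$mask
  }
  structure(
    list(gradients = gradients, beta_true = beta_true,
         intercept_true = intercept_true, cohort = cohort,
         diffusivity = diffusivity, noise_sd = noise_sd,
         age_slope = age_slope, sex_effect = sex_effect,
         interaction_effect = interaction_effect,
         effect_region = effect_region, s0 = s0,
         noise_model = noise_model, seed = as.integer(seed)),
    class = "signal_spec"
  )
}

# true per-voxel beta for one participant (covariate effects added
# inside the effect region); errors if any value leaves [0, 1]
participant_beta <- function(spec, row) {
  b <- spec$beta_true$values
  eff <- spec$age_slope * row$age + spec$sex_effect * row$sex +
    spec$interaction_effect * row$age * row$sex
  b[spec$effect_region] <- b[spec$effect_region] + eff
  bad <- which(b < -1e-9 | b > 1 + 1e-9)
  if (length(bad))
    stop("covariate effects push beta outside [0, 1] for participant ",
         row$participant_id, " at voxel(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  b
}

#' Generate synthetic DWI signals for a cohort
#'
#' Evaluates the forward signal model of a [signal_spec()] at every
#' support voxel for every participant. Signals are returned as
#' gradient-by-voxel matrices (one per participant) to keep a full
#' cohort in memory; [write_volume()] plus [matrix_to_volume4d()] can
#' expand any participant to a 4D NIfTI.
#'
#' @param spec a [signal_spec()].
#' @param orientation [vector_volume()] of mean tract orientations;
#'   must be nonzero wherever `beta_true > 0`.
#' @param support optional logical array or linear voxel indices
#'   restricting generation (default: voxels with nonzero orientation).
#' @param participants optional integer indices into the cohort
#'   (default: all).
#' @return a `dwi_dataset`: list with `signals` (per participant, an
#'   M x n_support matrix of DWI intensities), `support_idx`,
#'   `b0` ([scalar_volume()] at level `s0`), `gradients`, `spec`.
#' @export
make_dwi_signal <- function(spec, orientation, support = NULL,
                            participants = NULL) {
  check_same_grid(spec$beta_true, orientation)
  grid <- orientation$grid
  vec <- matrix(orientation$vectors, ncol = 3)
  has_orient <- rowSums(vec^2) > 0
  if (any(spec$beta_true$values > 0 & !has_orient))
    stop("orientation must be nonzero wherever beta_true > 0")
  support_idx <- if (is.null(support)) {
    which(has_orient)
  } else if (is.logical(support) || is.array(support)) {
    which(as.logical(support))
  } else {
    as.integer(support)
  }
  if (is.null(participants)) participants <- seq_len(nrow(spec$cohort))
  signals <- vector("list", length(participants))
  names(signals) <- spec$cohort$participant_id[participants]
  for (k in seq_along(participants)) {
    p <- participants[k]
    signals[[k]] <- participant_signal_matrix(spec, orientation,
                                              support_idx, p)
  }
  b0 <- scalar_volume(array(spec$s0, grid$dims), grid)
  structure(
    list(signals = signals, support_idx = support_idx, b0 = b0,
         gradients = spec$gradients, participants = participants,
         spec = spec),
    class = "dwi_dataset"
  )
}

# forward model for one participant at the given support voxels:
# M x n matrix of DWI intensities
participant_signal_matrix <- function(spec, orientation, support_idx,
                                      p_index) {
  row <- spec$cohort[p_index, ]
  beta <- participant_beta(spec, row)[support_idx]
  cj <- spec$intercept_true$values[support_idx]
  X <- regressor_matrix(orientation, support_idx, spec$gradients,
                        spec$diffusivity)
  mu <- spec$s0 * sweep(X, 2, beta, `*`)
  mu <- sweep(mu, 2, spec$s0 * cj, `+`)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 7919L * p_index)
    sdv <- spec$noise_sd * spec$s0
    if (spec$noise_model == "gaussian") {
      mu <- mu + stats::rnorm(length(mu), 0, sdv)
    } else {
      mu <- sqrt((mu + stats::rnorm(length(mu), 0, sdv))^2 +
                 stats::rnorm(length(mu), 0, sdv)^2)
    }
  }
  mu[mu < 0] <- 0
  mu
}

# regressor exp(-b * delta * (r_i . v_j)^2) for all support voxels:
# M x n matrix
regressor_matrix <- function(orientation, support_idx, gradients,
                             diffusivity) {
  vec <- matrix(orientation$vectors, ncol = 3)[support_idx, , drop = FALSE]
  proj <- gradients$bvecs %*% t(vec)    # M x n
  exp(-gradients$bval * diffusivity * proj^2)
}

#' Expand a gradient-by-voxel signal matrix to a 4D array
#'
#' @param mat M x n matrix (gradients by support voxels).
#' @param support_idx linear voxel indices of the columns.
#' @param grid the [voxel_grid()].
#' @return a 4D array `c(grid$dims, M)`.
#' @export
matrix_to_volume4d <- function(mat, support_idx, grid) {
  out <- array(0, c(grid$dims, nrow(mat)))
  nv <- n_voxels(grid)
  for (i in seq_len(nrow(mat))) {
    plane <- numeric(nv)
    plane[support_idx] <- mat[i, ]
    out[, , , i] <- array(plane, grid$dims)
  }
  out
}
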