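#' Voxel-wise covariate model of TSA
#'
#' At every voxel fitted in all participants (listwise exclusion),
#' ordinary least squares of TSA on an intercept, Age, Sex (coded 1/2 as
#' read from the cohort, not re-centred) and the literal product
#' Age x Sex. Per-coefficient t-statistics are estimate / standard
#' error with nu = n - 4 residual degrees of freedom; residuals are
#' retained for smoothness estimation. Voxels with zero residual
#' variance are flagged degenerate (t undefined).
#'
#' @param tsa_stack list of `tsa_volume` objects, one per participant,
#'   in cohort row order.
#' @param cohort a `cohort_table` (same order and length as
#'   `tsa_stack`).
#' @return `contrast_maps`: list with `grid`, `t` (named list of 3D
#'   arrays for `age`, `sex`, `interaction`; NA off-support), `coef`,
#'   `nu`, `voxel_idx`, `residuals` (n x n_voxel matrix), `sigma2`,
#'   `degenerate` (logical per voxel column).
#' @export
voxelwise_glm <- function(tsa_stack, cohort) {
  n <- length(tsa_stack)
  if (n < 6L) stop("voxelwise GLM needs at least 6 participants")
  if (nrow(cohort) != n)
    stop("cohort rows and TSA maps differ in number")
  grid <- tsa_stack[[1]]$grid
  fitted_all <- tsa_stack[[1]]$fitted
  for (tsa in tsa_stack[-1]) {
    check_same_grid(tsa, tsa_stack[[1]])
    fitted_all <- fitted_all & tsa$fitted
  }
  voxel_idx <- which(fitted_all)
  if (!length(voxel_idx)) stop("no voxel is fitted in all participants")
  Y <- vapply(tsa_stack, function(tsa) tsa$beta[voxel_idx],
              numeric(length(voxel_idx)))
  Y <- t(Y)                                   # n x nvox
  X <- cbind(intercept = 1, age = cohort$age, sex = as.numeric(cohort$sex),
             interaction = cohort$age * as.numeric(cohort$sex))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient design: column(s) ", paste(bad, collapse = ", "),
         " are collinear (single-sex cohort?)")
  }
  xtx_inv <- chol2inv(qr.R(qx))
  coef <- qr.coef(qx, Y)                      # 4 x nvox
  resid <- Y - X %*% coef
  nu <- n - ncol(X)
  sigma2 <- colSums(resid^2) / nu
  degenerate <- sigma2 <= 1e-24
  tmaps <- list()
  for (k in 2:4) {
    se <- sqrt(sigma2 * xtx_inv[k, k])
    tv <- ifelse(degenerate, NA_real_, coef[k, ] / se)
    arr <- array(NA_real_, grid$dims)
    arr[voxel_idx] <- tv
    tmaps[[colnames(X)[k]]] <- arr
  }
  structure(
    list(grid = grid, t = tmaps, coef = coef, nu = nu,
         voxel_idx = voxel_idx, residuals = resid, sigma2 = sigma2,
         degenerate = degenerate),
    class = "contrast_maps"
  )
}

#' @export
print.contrast_maps <- function(x, ...) {
  cat(sprintf("<contrast_maps> %d voxels, nu = %d (%d degenerate)\n",
              length(x$voxel_idx), x$nu, sum(x$degenerate)))
  invisible(x)
}

#' Weighted per-distance summary of a t-map
#'
#' Computes weighted statistics `t'(j) = t(j) * p_tract(j)^lambda` for
#' every voxel of each distance stratum and summarises each stratum
#' twice: the positive tail reports the unweighted t of the voxel
#' maximising t', the negative tail that of the voxel minimising t'.
#' Strata without any modelled voxel are skipped (with one collective
#' warning).
#'
#' @param contrast_maps result of [voxelwise_glm()].
#' @param p_tract tract probability [scalar_volume()] (P_ab-tract).
#' @param distance_map result of [flood_fill_distances()].
#' @param lambda_decay weighting exponent lambda >= 0 (default 1).
#' @return `distance_profile`: data.frame with columns `distance`,
#'   `contrast`, `t_pos`, `t_neg`, `vox_pos`, `vox_neg`; attribute
#'   `field_length` holds the number of summarised strata.
#' @export
weighted_distance_summary <- function(contrast_maps, p_tract, distance_map,
                                      lambda_decay = 1) {
  if (lambda_decay < 0) stop("lambda_decay must be >= 0")
  darr <- distance_map$d
  voxel_idx <- contrast_maps$voxel_idx
  dvox <- darr[voxel_idx]
  w <- p_tract$values[voxel_idx]^lambda_decay
  all_d <- seq_len(distance_map$max_d)
  have <- sort(unique(dvox[dvox > 0L]))
  skipped <- setdiff(all_d, have)
  if (length(skipped))
    warning(length(skipped), " distance stratum/strata without modelled ",
            "voxels were skipped")
  rows <- list()
  for (cn in names(contrast_maps$t)) {
    tv <- contrast_maps$t[[cn]][voxel_idx]
    for (dd in have) {
      sel <- which(dvox == dd & !is.na(tv))
      if (!length(sel)) next
      tw <- tv[sel] * w[sel]
      ip <- sel[which.max(tw)]
      im <- sel[which.min(tw)]
      rows[[length(rows) + 1L]] <- data.frame(
        distance = dd, contrast = cn,
        t_pos = tv[ip], t_neg = tv[im],
        vox_pos = voxel_idx[ip], vox_neg = voxel_idx[im],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "field_length") <- length(have)
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Per-stratum residual field along the tract
#'
#' Extracts, for each distance stratum, the GLM residual vector at the
#' stratum's maximal-`p_tract` voxel (the core voxel), yielding the
#' n-participants x Q-strata residual field whose smoothness calibrates
#' the random-field threshold.
#'
#' @inheritParams weighted_distance_summary
#' @return n x Q numeric matrix.
#' @export
stratum_residuals <- function(contrast_maps, p_tract, distance_map) {
  darr <- distance_map$d
  voxel_idx <- contrast_maps$voxel_idx
  dvox <- darr[voxel_idx]
  pv <- p_tract$values[voxel_idx]
  have <- sort(unique(dvox[dvox > 0L]))
  cols <- vapply(have, function(dd) {
    sel <- which(dvox == dd)
    sel[which.max(pv[sel])]
  }, integer(1))
  contrast_maps$residuals[, cols, drop = FALSE]
}

#' Estimate residual smoothness as a FWHM
#'
#' The standard random-field-theory smoothness estimator applied along
#' the distance axis: residual fields are standardised per stratum
#' (unit sum of squares over participants), differentiated along the
#' distance axis (central differences), and the per-node resel density
#' `sqrt(sum_i grad_i^2 / (4 log 2))` averaged; the FWHM is its
#' reciprocal, in stratum units (inter-stratum spacing = 1). Constant
#' residual fields have zero gradient and return the `Inf` sentinel
#' (infinitely smooth); fewer than 2 strata are undefined (`NA`).
#'
#' @param residual_field n x Q matrix (participants by strata), e.g.
#'   from [stratum_residuals()].
#' @return FWHM in stratum units (possibly `Inf` or `NA`).
#' @export
estimate_residual_fwhm <- function(residual_field) {
  R <- as.matrix(residual_field)
  q <- ncol(R)
  if (q < 2L) return(NA_real_)
  ssq <- colSums(R^2)
  ok <- ssq > 1e-24
  R[, ok] <- sweep(R[, ok, drop = FALSE], 2, sqrt(ssq[ok]), `/`)
  g <- matrix(0, nrow(R), q)
  if (q >= 3L)
    g[, 2:(q - 1L)] <- (R[, 3:q, drop = FALSE] -
                        R[, 1:(q - 2L), drop = FALSE]) / 2
  g[, 1L] <- R[, 2L] - R[, 1L]
  g[, q] <- R[, q] - R[, q - 1L]
  v <- colSums(g^2)
  v <- v[ok & is.finite(v)]
  if (!length(v)) return(NA_real_)
  resels_per_node <- sqrt(v / (4 * log(2)))
  mean_rpn <- mean(resels_per_node)
  if (mean_rpn <= 0) return(Inf)
  1 / mean_rpn
}

# expected Euler characteristic of the excursion set of a smooth 1D
# t- or Gaussian field above u: the survival approximation for the
# field maximum
rft_ec_expect <- function(u, resels, nu, model = c("t", "gaussian")) {
  model <- match.arg(model)
  if (model == "t") {
    ec0 <- stats::pt(u, df = nu, lower.tail = FALSE)
    ec1 <- sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / nu)^(-(nu - 1) / 2)
  } else {
    ec0 <- stats::pnorm(u, lower.tail = FALSE)
    ec1 <- sqrt(4 * log(2)) / (2 * pi) * exp(-u^2 / 2)
  }
  ec0 + resels * ec1
}

#' Survival probability of the maximum of a smooth 1D field
#'
#' Expected-Euler-characteristic approximation to
#' `P(max field > u)` for a stationary 1D t- or Gaussian field of the
#' given smoothness and length.
#'
#' @param u threshold.
#' @param fwhm field smoothness (FWHM, stratum units; `Inf` = flat).
#' @param field_length number of strata Q (the field spans Q - 1
#'   inter-node intervals).
#' @param nu degrees of freedom (t model).
#' @param model `"t"` (default) or `"gaussian"`.
#' @return approximate survival probability.
#' @export
rft_max_survival <- function(u, fwhm, field_length, nu,
                             model = c("t", "gaussian")) {
  model <- match.arg(model)
  resels <- if (is.finite(fwhm) && fwhm > 0) (field_length - 1) / fwhm else 0
  rft_ec_expect(u, resels, nu, model)
}

#' Critical t-value for a smooth 1D random field
#'
#' Inverts the expected-Euler-characteristic survival approximation:
#' returns t* with `P(max field > t*) = alpha` for a 1D field of the
#' given smoothness and length. As the resel count approaches 0 the
#' threshold approaches the point-wise one-sided critical value.
#'
#' @inheritParams rft_max_survival
#' @param alpha level in (0, 1) (default 0.05).
#' @return the critical value t*.
#' @export
rft_critical_t <- function(fwhm, field_length, nu, alpha = 0.05,
                           model = c("t", "gaussian")) {
  model <- match.arg(model)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.na(fwhm) && fwhm <= 0) stop("fwhm must be > 0")
  f <- function(u) rft_max_survival(u, fwhm, field_length, nu, model) - alpha
  stats::uniroot(f, lower = 0, upper = 100, extendInt = "downX",
                 tol = 1e-10)$root
}

#' Cluster-wise inference on a distance profile
#'
#' For each contrast and each tail, finds maximal runs of consecutive
#' strata whose summarised t exceeds the critical value (positive tail:
#' `t_d > t*`; negative tail: `t_d < -t*`), discards runs shorter than
#' `min_extent`, and assigns each surviving run a cluster p-value from
#' the expected-extent exponential approximation for supra-threshold
#' runs in a stationary 1D field:
#' `p = 1 - exp(-E[N] * exp(-extent / E[S]))`, where E\[N\] is the
#' expected number of upcrossings at t* and E\[S\] the expected run
#' extent.
#'
#' @param profile a `distance_profile`.
#' @param t_star critical value from [rft_critical_t()].
#' @param min_extent minimum cluster size in strata (default 3).
#' @param fwhm field smoothness used for the extent model.
#' @param nu degrees of freedom.
#' @param model `"t"` or `"gaussian"`.
#' @return data.frame with one row per retained cluster: `contrast`,
#'   `sign`, `start`, `end`, `extent`, `peak_t`, `p`, `sum_t`,
#'   `r2_peak`.
#' @export
cluster_inference <- function(profile, t_star, min_extent = 3, fwhm, nu,
                              model = c("t", "gaussian")) {
  model <- match.arg(model)
  field_length <- attr(profile, "field_length")
  resels <- if (is.finite(fwhm) && fwhm > 0) (field_length - 1) / fwhm else 0
  if (model == "t") {
    p0 <- stats::pt(t_star, df = nu, lower.tail = FALSE)
    ec1 <- resels * sqrt(4 * log(2)) / (2 * pi) *
      (1 + t_star^2 / nu)^(-(nu - 1) / 2)
  } else {
    p0 <- stats::pnorm(t_star, lower.tail = FALSE)
    ec1 <- resels * sqrt(4 * log(2)) / (2 * pi) * exp(-t_star^2 / 2)
  }
  e_n <- max(ec1, 1e-12)
  e_s <- max(field_length * p0 / e_n, 1e-12)   # expected extent, nodes
  cluster_p <- function(extent) {
    1 - exp(-e_n * exp(-extent / e_s))
  }
  rows <- list()
  for (cn in unique(profile$contrast)) {
    sub <- profile[profile$contrast == cn, , drop = FALSE]
    sub <- sub[order(sub$distance), , drop = FALSE]
    for (sgn in c("positive", "negative")) {
      tvals <- if (sgn == "positive") sub$t_pos else sub$t_neg
      above <- if (sgn == "positive") tvals > t_star else tvals < -t_star
      above[is.na(above)] <- FALSE
      runs <- find_runs(sub$distance, above)
      for (r in runs) {
        extent <- length(r)
        if (extent < min_extent) next
        tt <- tvals[r]
        peak <- if (sgn == "positive") max(tt) else min(tt)
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = cn, sign = sgn,
          start = sub$distance[r[1]], end = sub$distance[r[extent]],
          extent = extent, peak_t = peak, p = cluster_p(extent),
          sum_t = sum(tt), r2_peak = peak^2 / (peak^2 + nu),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contrast = character(0), sign = character(0),
                      start = integer(0), end = integer(0),
                      extent = integer(0), peak_t = numeric(0),
                      p = numeric(0), sum_t = numeric(0),
                      r2_peak = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# maximal runs of TRUE over positions that are consecutive in distance
find_runs <- function(distance, flag) {
  runs <- list()
  cur <- integer(0)
  for (i in seq_along(flag)) {
    if (flag[i]) {
      if (length(cur) && distance[i] == distance[cur[length(cur)]] + 1L) {
        cur <- c(cur, i)
      } else {
        if (length(cur)) runs[[length(runs) + 1L]] <- cur
        cur <- i
      }
    } else {
      if (length(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}

#' Two-stage non-negative FDR across tracts
#'
#' The two-stage step-up procedure: stage one runs the linear step-up
#' at q / (1 + q) to estimate the number of true null hypotheses m0;
#' stage two applies the step-up with the threshold inflated by m / m0.
#' Adjusted p-values are monotone non-decreasing in the raw p-values
#' and a discovery survives when its adjusted p is at most q.
#'
#' @param pvals numeric vector of cluster p-values in \[0, 1\].
#' @param q FDR rate (default 0.05).
#' @return list with `adjusted`, `survives`, `m0`.
#' @export
fdr_across_tracts <- function(pvals, q = 0.05) {
  if (!length(pvals))
    return(list(adjusted = numeric(0), survives = logical(0), m0 = 0L))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  alpha_prime <- q / (1 + q)
  bh <- stats::p.adjust(pvals, method = "BH")
  r1 <- sum(bh <= alpha_prime)
  m0 <- m - r1
  adjusted <- if (r1 == 0L || r1 == m) {
    pmin(bh * (1 + q), 1)
  } else {
    pmin(bh * (m0 / m) * (1 + q), 1)
  }
  list(adjusted = adjusted, survives = adjusted <= q, m0 = m0)
}

#' Signed sums of significant t-values
#'
#' Sums the summarised t statistics over the strata of surviving
#' clusters, separately for positive and negative clusters, per tract
#' and contrast; zero when no cluster of that sign survives.
#'
#' @param clusters data.frame of clusters (with `tract`, `contrast`,
#'   `sign`, `sum_t`, `survives` columns).
#' @return data.frame with `tract`, `contrast`, `positive_sum`,
#'   `negative_sum`.
#' @export
signed_sums <- function(clusters) {
  if (!nrow(clusters)) {
    return(data.frame(tract = character(0), contrast = character(0),
                      positive_sum = numeric(0), negative_sum = numeric(0),
                      stringsAsFactors = FALSE))
  }
  keys <- unique(clusters[, c("tract", "contrast")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- clusters$tract == keys$tract[i] &
      clusters$contrast == keys$contrast[i] & clusters$survives
    data.frame(
      tract = keys$tract[i], contrast = keys$contrast[i],
      positive_sum = sum(clusters$sum_t[sel & clusters$sign == "positive"]),
      negative_sum = sum(clusters$sum_t[sel & clusters$sign == "negative"]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Tract-wise statistics for one or more tracts
#'
#' Runs the full statistical stage: the voxel-wise covariate model per
#' tract, weighted per-distance summarisation, residual-smoothness
#' estimation (averaged across tracts), the random-field critical value
#' at `alpha_level`, cluster-wise inference with the minimum extent
#' rule, two-stage FDR across all clusters of all tracts, and signed
#' sums of significant t-values.
#'
#' @param tracts named list; each element is a list with `tsa` (list of
#'   `tsa_volume` per participant) and `tract` (an accepted
#'   `tract_estimate`).
#' @param cohort a `cohort_table`.
#' @param lambda_decay weighting exponent (default 1).
#' @param alpha_level random-field level (default 0.05).
#' @param min_extent minimum cluster size in strata (default 3).
#' @param q FDR rate across tracts (default 0.05).
#' @param model `"t"` (default) or `"gaussian"` field model.
#' @return a `tract_stat_result`: list with `profiles` (per tract),
#'   `clusters` (pooled data.frame with FDR-adjusted p and survives
#'   flags), `sums`, `fwhm` (per tract), `mean_fwhm`, `t_star`, `nu`,
#'   and the parameters.
#' @export
tract_stats <- function(tracts, cohort, lambda_decay = 1,
                        alpha_level = 0.05, min_extent = 3, q = 0.05,
                        model = c("t", "gaussian")) {
  model <- match.arg(model)
  if (is.null(names(tracts)))
    names(tracts) <- sprintf("tract_%02d", seq_along(tracts))
  accepted <- vapply(tracts, function(x) x$tract$status == "accepted",
                     logical(1))
  tracts <- tracts[accepted]
  if (!length(tracts))
    stop("no accepted tracts to analyse")
  profiles <- list(); fwhms <- numeric(0); nu <- NA_integer_
  lens <- integer(0); cms <- list()
  for (nm in names(tracts)) {
    tr <- tracts[[nm]]
    cm <- voxelwise_glm(tr$tsa, cohort)
    nu <- cm$nu
    prof <- weighted_distance_summary(cm, tr$tract$p_tract,
                                      tr$tract$distance_map, lambda_decay)
    res <- stratum_residuals(cm, tr$tract$p_tract, tr$tract$distance_map)
    fw <- estimate_residual_fwhm(res)
    profiles[[nm]] <- prof
    fwhms[nm] <- fw
    lens[nm] <- attr(prof, "field_length")
    cms[[nm]] <- cm
  }
  finite_fw <- fwhms[is.finite(fwhms)]
  mean_fwhm <- if (length(finite_fw)) mean(finite_fw) else Inf
  t_star <- rft_critical_t(mean_fwhm, field_length = max(lens), nu = nu,
                           alpha = alpha_level, model = model)
  all_clusters <- list()
  for (nm in names(tracts)) {
    cl <- cluster_inference(profiles[[nm]], t_star, min_extent,
                            mean_fwhm, nu, model)
    if (nrow(cl)) {
      cl <- cbind(tract = nm, cl, stringsAsFactors = FALSE)
      all_clusters[[nm]] <- cl
    }
  }
  clusters <- if (length(all_clusters)) {
    do.call(rbind, all_clusters)
  } else {
    data.frame(tract = character(0), contrast = character(0),
               sign = character(0), start = integer(0), end = integer(0),
               extent = integer(0), peak_t = numeric(0), p = numeric(0),
               sum_t = numeric(0), r2_peak = numeric(0),
               stringsAsFactors = FALSE)
  }
  fdr <- fdr_across_tracts(clusters$p, q)
  clusters$p_adjusted <- fdr$adjusted
  clusters$survives <- fdr$survives
  rownames(clusters) <- NULL
  structure(
    list(profiles = profiles, clusters = clusters,
         sums = signed_sums(clusters), fwhm = fwhms,
         mean_fwhm = mean_fwhm, t_star = t_star, nu = nu,
         params = list(lambda_decay = lambda_decay,
                       alpha_level = alpha_level, min_extent = min_extent,
                       q = q, model = model)),
    class = "tract_stat_result"
  )
}

#' @export
print.tract_stat_result <- function(x, ...) {
  cat(sprintf(
    "<tract_stat_result> %d tract(s), nu = %d, FWHM = %.3g, t* = %.4g\n",
    length(x$profiles), x$nu, x$mean_fwhm, x$t_star))
  ns <- sum(x$clusters$survives)
  cat(sprintf("  %d cluster(s), %d surviving FDR at q = %g\n",
              nrow(x$clusters), ns, x$params$q))
  invisible(x)
}
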