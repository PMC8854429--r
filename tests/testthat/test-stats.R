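# minimal synthetic TSA stack: n participants, values at `idx` voxels of a
# small grid, from a function(participant row) -> numeric(length(idx))
make_tsa_stack <- function(cohort, grid, idx, value_fn) {
  lapply(seq_len(nrow(cohort)), function(i) {
    beta <- array(NA_real_, grid$dims)
    fitted <- array(FALSE, grid$dims)
    beta[idx] <- value_fn(cohort[i, ])
    fitted[idx] <- TRUE
    structure(list(grid = grid, beta = beta, intercept = beta * 0,
                   fitted = fitted,
                   participant_id = cohort$participant_id[i]),
              class = "tsa_volume")
  })
}

test_that("voxel-wise GLM t-statistics match the lm() oracle", {
  set.seed(31)
  grid <- voxel_grid(c(4, 4, 1), c(2, 2, 2))
  idx <- 1:12
  cohort <- make_cohort(10, seed = 8)
  vals <- matrix(rnorm(10 * length(idx)), 10)
  stack <- make_tsa_stack(cohort, grid, idx, local({
    i <- 0
    function(row) { i <<- i + 1; vals[i, ] }
  }))
  cm <- voxelwise_glm(stack, cohort)
  expect_equal(cm$nu, 6)
  for (j in seq_along(idx)) {
    fit <- stats::lm(vals[, j] ~ age * sex,
                     data = transform(cohort, sex = as.numeric(sex)))
    tt <- summary(fit)$coefficients[, "t value"]
    expect_equal(cm$t$age[idx[j]], unname(tt["age"]), tolerance = 1e-8)
    expect_equal(cm$t$sex[idx[j]], unname(tt["sex"]), tolerance = 1e-8)
    expect_equal(cm$t$interaction[idx[j]], unname(tt["age:sex"]),
                 tolerance = 1e-8)
  }
})

test_that("degenerate and rank-deficient designs are reported", {
  grid <- voxel_grid(c(2, 2, 1), c(2, 2, 2))
  cohort <- make_cohort(8, seed = 2)
  stack <- make_tsa_stack(cohort, grid, 1:4, function(row) rep(1, 4))
  cm <- voxelwise_glm(stack, cohort)           # identical TSA everywhere
  expect_true(all(cm$degenerate))
  expect_true(all(is.na(cm$t$age[1:4])))
  single_sex <- cohort
  single_sex$sex <- 1L
  expect_error(voxelwise_glm(stack, single_sex), "collinear")
  expect_error(voxelwise_glm(stack[1:5], cohort[1:5, ]), "at least 6")
})

test_that("distance summarisation weights t by p_tract^lambda per tail", {
  grid <- voxel_grid(c(2, 1, 1), c(2, 2, 2))
  dm <- structure(list(grid = grid, d = array(c(1L, 1L), c(2, 1, 1)),
                       max_d = 1L), class = "distance_map")
  cm <- structure(list(
    grid = grid, t = list(age = array(c(3, 2), c(2, 1, 1))),
    voxel_idx = 1:2,
    residuals = matrix(0, 4, 2)), class = "contrast_maps")
  pt <- scalar_volume(array(c(0.5, 1), c(2, 1, 1)), grid)
  # weighting flips the argmax: t' = (1.5, 2.0) -> reported unweighted t 2.0
  prof <- weighted_distance_summary(cm, pt, dm, lambda_decay = 1)
  expect_equal(prof$t_pos, 2)
  # lambda = 0: weights are 1, the plain maximum wins
  prof0 <- weighted_distance_summary(cm, pt, dm, lambda_decay = 0)
  expect_equal(prof0$t_pos, 3)
  expect_equal(prof0$t_neg, 2)
  # single-voxel stratum reports its own t for both tails
  dm1 <- structure(list(grid = grid, d = array(c(1L, 0L), c(2, 1, 1)),
                        max_d = 1L), class = "distance_map")
  prof1 <- weighted_distance_summary(cm, pt, dm1, lambda_decay = 1)
  expect_equal(prof1$t_pos, 3)
  expect_equal(prof1$t_neg, 3)
})

test_that("residual smoothness estimation is calibrated and handles edge cases", {
  smooth_fields <- function(n, Q, fwhm) {
    sig <- fwhm / (2 * sqrt(2 * log(2)))
    r <- ceiling(4 * sig); k <- dnorm(-r:r, sd = sig)
    W <- matrix(0, Q + 2 * r, Q)
    for (j in 1:Q) W[j:(j + 2 * r), j] <- k
    (matrix(rnorm(n * (Q + 2 * r)), n) %*% W) / sqrt(sum(k^2))
  }
  set.seed(55)
  # known smoothness FWHM = 5 strata, field length 100: within 15%
  est <- replicate(60, estimate_residual_fwhm(smooth_fields(20, 100, 5)))
  expect_lt(abs(mean(est) - 5) / 5, 0.15)
  # white-noise floor is stable across seeds within 10%
  floor1 <- mean(replicate(40, estimate_residual_fwhm(
    matrix(rnorm(20 * 100), 20))))
  floor2 <- mean(replicate(40, estimate_residual_fwhm(
    matrix(rnorm(20 * 100), 20))))
  expect_lt(abs(floor1 - floor2) / floor1, 0.1)
  # constant residuals: zero gradient, infinite smoothness sentinel
  expect_identical(estimate_residual_fwhm(matrix(1, 5, 10)), Inf)
  # fewer than 2 strata: undefined
  expect_true(is.na(estimate_residual_fwhm(matrix(rnorm(5), 5, 1))))
})

test_that("the critical value has the right limits and monotonicity", {
  # resel count -> 0: point-wise one-sided Gaussian quantile
  expect_equal(rft_critical_t(1e12, 100, 1e7, 0.05, model = "gaussian"),
               qnorm(0.95), tolerance = 1e-4)
  expect_equal(rft_critical_t(Inf, 100, 126, 0.05, model = "t"),
               qt(0.95, 126), tolerance = 1e-6)
  # strictly decreasing in fwhm at fixed length
  ts <- vapply(c(2, 5, 10, 20, 50), rft_critical_t, numeric(1),
               field_length = 100, nu = 126, alpha = 0.05)
  expect_true(all(diff(ts) < 0))
  # survival at the returned threshold equals alpha
  tstar <- rft_critical_t(10, 100, 126, 0.05)
  expect_equal(rft_max_survival(tstar, 10, 100, 126), 0.05,
               tolerance = 1e-8)
})

test_that("cluster inference applies the minimum-extent rule and extent monotonicity", {
  mkprof <- function(tvals) {
    out <- data.frame(distance = seq_along(tvals), contrast = "age",
                      t_pos = tvals, t_neg = -rev(tvals))
    attr(out, "field_length") <- length(tvals)
    class(out) <- c("distance_profile", "data.frame")
    out
  }
  quiet <- mkprof(rep(1, 20))
  expect_equal(nrow(cluster_inference(quiet, 3.5, 3, fwhm = 5, nu = 126)), 0)
  # a run of exactly 2 supra-threshold strata is discarded
  two <- mkprof(c(rep(1, 8), 4, 4, rep(1, 10)))
  expect_equal(nrow(cluster_inference(two, 3.5, 3, fwhm = 5, nu = 126)), 0)
  # extent monotonicity at equal peak: longer bump, smaller p
  bump <- function(k) mkprof(c(rep(1, 4), rep(4, k), rep(1, 16 - k)))
  cl3 <- cluster_inference(bump(3), 3.5, 3, fwhm = 5, nu = 126)
  cl10 <- cluster_inference(bump(10), 3.5, 3, fwhm = 5, nu = 126)
  pos3 <- cl3[cl3$sign == "positive", ]
  pos10 <- cl10[cl10$sign == "positive", ]
  expect_equal(pos3$extent, 3)
  expect_equal(pos10$extent, 10)
  expect_lt(pos10$p, pos3$p)
  # both tails are found with their signs
  both <- mkprof(c(rep(4, 3), rep(1, 17)))
  cl <- cluster_inference(both, 3.5, 3, fwhm = 5, nu = 126)
  expect_setequal(cl$sign, c("positive", "negative"))
  expect_true(all(cl$p >= 0 & cl$p <= 1))
})

test_that("two-stage FDR matches a step-by-step reference and its bounds", {
  # independent step-by-step reference of the two-stage step-up procedure
  ref_tsbky <- function(p, q) {
    m <- length(p)
    qp <- q / (1 + q)
    step_up <- function(p, level) {
      o <- order(p); r <- 0
      for (k in m:1) if (p[o[k]] <= k * level / m) { r <- k; break }
      r
    }
    r1 <- step_up(p, qp)
    if (r1 == 0) return(rep(FALSE, m))
    if (r1 == m) return(rep(TRUE, m))
    m0 <- m - r1
    r2 <- step_up(p, qp * m / m0)
    o <- order(p)
    rej <- rep(FALSE, m); rej[o[seq_len(r2)]] <- TRUE
    rej
  }
  expect_true(fdr_across_tracts(0.04, q = 0.05)$survives)
  expect_false(fdr_across_tracts(0.06, q = 0.05)$survives)
  expect_true(all(fdr_across_tracts(rep(0.001, 10))$survives))
  set.seed(12)
  for (i in 1:10) {
    p <- c(runif(12), rbeta(8, 0.2, 6))
    out <- fdr_across_tracts(p, q = 0.05)
    expect_identical(out$survives, ref_tsbky(p, 0.05))
    # adjusted p monotone non-decreasing in raw p
    expect_true(all(diff(out$adjusted[order(p)]) >= -1e-12))
    # never more discoveries than plain BH when the null estimate is m
    plain <- stats::p.adjust(p, "BH") <= 0.05
    if (out$m0 == length(p)) expect_lte(sum(out$survives), sum(plain))
  }
})

test_that("signed sums aggregate surviving clusters per tail", {
  cl <- data.frame(
    tract = "t1", contrast = "age",
    sign = c("positive", "negative", "positive"),
    sum_t = c(10, -8, 5), survives = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  s <- signed_sums(cl)
  expect_equal(s$positive_sum, 10)   # the non-surviving cluster is excluded
  expect_equal(s$negative_sum, -8)
  empty <- signed_sums(cl[0, ])
  expect_equal(nrow(empty), 0)
  none <- cl; none$survives <- FALSE
  s0 <- signed_sums(none)
  expect_equal(s0$positive_sum, 0)
  expect_equal(s0$negative_sum, 0)
})

test_that("an injected age effect is localised; a null cohort stays quiet", {
  spec <- straight_phantom_spec(seed = 101L)
  ph <- make_participant_pairs(spec, 4)
  tr <- estimate_tract(ph$pairs, ph$roi_a, ph$roi_b)
  cohort <- make_cohort(24, seed = 400)
  # effect region: middle strata of the tract
  dmax <- tr$distance_map$max_d
  band <- tr$distance_map$d >= floor(dmax / 3) &
    tr$distance_map$d <= floor(2 * dmax / 3)
  gt <- make_gradient_scheme(64)
  ss <- phantom_signal_spec(ph, cohort, gradients = gt, beta = 0.4,
                            intercept = 0.2, noise_sd = 0.02,
                            age_slope = 0.004, effect_region = band,
                            seed = 500L)
  vec <- matrix(ph$orientation$vectors, ncol = 3)
  support <- which(array(rowSums(vec^2) > 0, spec$grid$dims) & tr$members)
  dwi <- make_dwi_signal(ss, ph$orientation, support = support)
  tsa <- fit_tsa_cohort(dwi, ph$orientation, smoothing_fwhm = 1.5)
  st <- tract_stats(list(main = list(tsa = tsa, tract = tr)), cohort)
  surv <- st$clusters[st$clusters$survives, ]
  expect_true(any(surv$contrast == "age" & surv$sign == "positive"))
  age_cl <- surv[surv$contrast == "age" & surv$sign == "positive", ]
  # the surviving cluster overlaps the injected stratum band
  expect_true(any(age_cl$start <= floor(2 * dmax / 3) &
                  age_cl$end >= floor(dmax / 3)))
  # same data without the effect: no surviving age cluster
  ss0 <- phantom_signal_spec(ph, cohort, gradients = gt, beta = 0.4,
                             intercept = 0.2, noise_sd = 0.02,
                             seed = 500L)
  dwi0 <- make_dwi_signal(ss0, ph$orientation, support = support)
  tsa0 <- fit_tsa_cohort(dwi0, ph$orientation, smoothing_fwhm = 1.5)
  st0 <- tract_stats(list(main = list(tsa = tsa0, tract = tr)), cohort)
  expect_false(any(st0$clusters$survives[st0$clusters$contrast == "age"]))
})
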