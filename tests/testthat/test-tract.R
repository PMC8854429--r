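make_grid <- function(dims, voxel = 2) voxel_grid(dims, rep(voxel, 3))

test_that("directed normalisation divides by the target count and clips at 1", {
  grid <- make_grid(c(3, 1, 1))
  counts <- scalar_volume(array(c(10, 5, 0), c(3, 1, 1)), grid)
  p <- normalize_directed(counts, 10)
  expect_equal(as.numeric(p$values), c(1, 0.5, 0))
  expect_false(attr(p, "unconnectable"))

  # a way-point voxel visited by more streamlines than reach the target
  # has ratio 2.0 before clipping
  over <- scalar_volume(array(20, c(1, 1, 1)), make_grid(c(1, 1, 1)))
  expect_equal(20 / 10, 2)   # pre-clip ratio
  expect_equal(as.numeric(normalize_directed(over, 10)$values), 1)

  z <- normalize_directed(counts, 0)
  expect_true(attr(z, "unconnectable"))
  expect_true(all(z$values == 0))
})

test_that("bidirectional averaging takes min, mean, then renormalises to max 1", {
  grid <- make_grid(c(4, 1, 1))
  mk <- function(v) scalar_volume(array(v, c(4, 1, 1)), grid)
  # one participant, identical directions: renormalised copy
  p1 <- bidirectional_population_average(
    list(list(ab = mk(c(0.2, 0.4, 0.1, 0)), ba = mk(c(0.2, 0.4, 0.1, 0)))),
    smoothing_fwhm = 0)
  expect_equal(as.numeric(p1$values), c(0.5, 1, 0.25, 0))
  # one direction all-zero kills the tract
  p0 <- bidirectional_population_average(
    list(list(ab = mk(c(0.2, 0.4, 0.1, 0)), ba = mk(rep(0, 4)))),
    smoothing_fwhm = 0)
  expect_true(all(p0$values == 0))
  # two participants average before renormalisation: (0.2 + 0.6)/2 = 0.4
  p2 <- bidirectional_population_average(
    list(list(ab = mk(c(0.2, 1, 0, 0)), ba = mk(c(0.2, 1, 0, 0))),
         list(ab = mk(c(0.6, 1, 0, 0)), ba = mk(c(0.6, 1, 0, 0)))),
    smoothing_fwhm = 0)
  expect_equal(as.numeric(p2$values)[1], 0.4 / 1)
  # grid mismatch is a consistency error
  other <- scalar_volume(array(0, c(2, 1, 1)), make_grid(c(2, 1, 1)))
  expect_error(bidirectional_population_average(
    list(list(ab = mk(rep(0.1, 4)), ba = other))), "grid mismatch")
})

test_that("thresholding is inclusive and keeps dilated ROIs", {
  grid <- make_grid(c(9, 9, 9))
  roi_a <- roi_mask(array(seq_len(729) == 1, c(9, 9, 9)), grid, "a")
  roi_b <- roi_mask(array(seq_len(729) == 729, c(9, 9, 9)), grid, "b")
  # uniform 0.05 below alpha = 0.07: members are only the dilated ROIs
  p <- scalar_volume(array(0.05, c(9, 9, 9)), grid)
  m <- threshold_with_dilated_rois(p, roi_a, roi_b, alpha = 0.07,
                                   dilation_voxels = 3)
  expect_identical(unclass(m)[seq_len(729)],
                   as.vector(attr(m, "roi_a_dilated") | attr(m, "roi_b_dilated")))
  expect_equal(sum(attr(m, "roi_a_dilated")), 4^3)  # corner ROI dilated 3x
  # uniform 0.5: everything is a member
  p5 <- scalar_volume(array(0.5, c(9, 9, 9)), grid)
  expect_true(all(threshold_with_dilated_rois(p5, roi_a, roi_b)))
  # exact equality with alpha is retained
  pe <- scalar_volume(array(0.07, c(9, 9, 9)), grid)
  expect_true(all(threshold_with_dilated_rois(pe, roi_a, roi_b, alpha = 0.07)))
})

test_that("raising alpha monotonically shrinks the member set", {
  spec <- straight_phantom_spec(seed = 5L)
  ph <- make_probability_pair(spec)
  p_ab <- bidirectional_population_average(list(ph[c("ab", "ba")]))
  prev <- NULL
  for (a in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    m <- threshold_with_dilated_rois(p_ab, ph$roi_a, ph$roi_b, alpha = a)
    if (!is.null(prev)) expect_true(all(prev | !m))  # m subset of prev
    prev <- m
  }
})

test_that("flood fill labels a corridor linearly and leaves islands unassigned", {
  grid <- make_grid(c(10, 1, 1))
  members <- array(TRUE, c(10, 1, 1))
  seed <- roi_mask(array(c(TRUE, rep(FALSE, 9)), c(10, 1, 1)), grid)
  dm <- flood_fill_distances(members, seed, grid)
  expect_equal(as.integer(dm$d), c(0L, 1:9))
  expect_equal(dm$max_d, 9L)
  # a member voxel disconnected from the seed stays unassigned
  members2 <- array(c(TRUE, TRUE, FALSE, TRUE, TRUE, rep(FALSE, 5)),
                    c(10, 1, 1))
  dm2 <- flood_fill_distances(members2, seed, grid)
  expect_equal(as.integer(dm2$d), c(0L, 1L, rep(0L, 8)))
})

test_that("flood fill matches an independent voxel-by-voxel BFS oracle", {
  set.seed(99)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:4) {
      dims <- c(7, 7, 7)
      grid <- make_grid(dims)
      members <- array(runif(prod(dims)) < 0.6, dims)
      members[1, 1, 1] <- TRUE
      seed <- array(FALSE, dims); seed[1, 1, 1] <- TRUE
      dm <- flood_fill_distances(members, seed, grid, connectivity = conn)
      expect_identical(dm$d, bfs_oracle(members, seed, conn))
    }
  }
})

test_that("the core polyline tracks a straight tube and reaches the target", {
  spec <- straight_phantom_spec(seed = 6L)
  ph <- make_participant_pairs(spec, 4)
  tr <- estimate_tract(ph$pairs, ph$roi_a, ph$roi_b)
  expect_equal(tr$status, "accepted")
  expect_true(nrow(tr$trajectory$vertices) >= 10)
  # every vertex within one voxel diagonal of the ground-truth line
  d_to_line <- sqrt(rowSums(
    (tr$trajectory$vertices[, 2:3, drop = FALSE] -
       matrix(31, nrow(tr$trajectory$vertices), 2))^2))
  expect_lt(max(d_to_line), sqrt(3) * 2 + 1e-9)
})

test_that("an off-path decoy beyond the segment bound is skipped without a flag", {
  grid <- make_grid(c(20, 9, 9))
  # corridor along x at y = z = 5 (1-based), distances 1..19 from seed x=1
  p <- array(0, c(20, 9, 9))
  p[, 5, 5] <- 0.8
  roi_a <- roi_mask(array(slice.index(p, 1) == 1 & p > 0, dim(p)), grid, "a")
  roi_b <- roi_mask(array(slice.index(p, 1) == 20 & p > 0, dim(p)), grid, "b")
  # decoy 4 mm off-path in y at column 10, connected to the corridor by a
  # low-probability stepping stone so it lands in the same stratum
  p[9, 6, 5] <- 0.2
  p[10, 7, 5] <- 0.95
  members <- p >= 0.07
  dm <- flood_fill_distances(members, roi_a$mask, grid)
  expect_equal(dm$d[10, 7, 5], dm$d[10, 5, 5])  # same stratum
  traj <- build_core_polyline(scalar_volume(p, grid), dm, roi_b$mask)
  expect_equal(traj$status, "accepted")
  expect_false(any(traj$flags))
  # segment from the previous on-path vertex to the decoy centre is
  # sqrt(2^2 + 4^2) > 4 mm, so despite its higher probability the decoy
  # is skipped and the on-path runner-up chosen: all vertices stay on
  # the corridor (world y = 8 mm)
  expect_true(all(traj$vertices[, 2] == 8))
})

test_that("breaking the corridor before the target yields rejection", {
  grid <- make_grid(c(20, 9, 9))
  p <- array(0, c(20, 9, 9))
  p[, 5, 5] <- 0.8
  p[12, 5, 5] <- 0     # broken corridor
  roi_a <- roi_mask(array(slice.index(p, 1) == 1 & p > 0, dim(p)), grid)
  roi_b <- roi_mask(array(slice.index(p, 1) == 20 & p > 0, dim(p)), grid)
  members <- p >= 0.07
  dm <- flood_fill_distances(members, roi_a$mask, grid)
  traj <- build_core_polyline(scalar_volume(p, grid), dm, roi_b$mask)
  expect_equal(traj$status, "rejected")
})

test_that("vertex orientations are segment-vector sums, normalised", {
  line <- list(vertices = rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  om <- vertex_orientations(line)
  expect_equal(om, rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)))
  bend <- list(vertices = rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0)))
  om2 <- vertex_orientations(bend)
  expect_equal(om2[2, ], c(1, 1, 0) / sqrt(2))  # 45-degree bisector
  two <- list(vertices = rbind(c(0, 0, 0), c(0, 3, 0)))
  expect_equal(vertex_orientations(two), rbind(c(0, 1, 0), c(0, 1, 0)))
  dup <- list(vertices = rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(vertex_orientations(dup), "degenerate")
})

test_that("the uncertainty field obeys its closed form and 8 mm support", {
  grid <- make_grid(c(21, 21, 21), voxel = 1)
  traj <- structure(list(
    vertices = rbind(c(6, 10, 10), c(10, 10, 10), c(14, 10, 10)),
    flags = c(FALSE, FALSE, FALSE), status = "accepted",
    omega = NULL), class = "core_trajectory")
  traj$omega <- vertex_orientations(traj)
  phi <- uncertainty_field(traj, grid, sigma_axial = 10, sigma_radial = 4,
                           radius = 8)
  expect_equal(phi$values[11, 11, 11], 1)           # voxel centre at a vertex
  expect_equal(phi$values[11, 15, 11], exp(-0.5), tolerance = 1e-9)
  # pure radial offset of 4 mm = sigma_r
  far <- phi$values[11, 20, 11]                     # 9 mm from nearest vertex
  expect_equal(far, 0)
  # axial falloff uses sigma_a: 4 mm beyond the end vertex along omega
  expect_equal(phi$values[19, 11, 11], exp(-16 / 200), tolerance = 1e-9)
})

test_that("the uncertainty field is invariant under 90-degree rotation", {
  grid <- make_grid(c(17, 17, 17), voxel = 2)
  traj <- structure(list(
    vertices = rbind(c(6, 16, 16), c(10, 16, 16), c(14, 18, 16)),
    status = "accepted", omega = NULL), class = "core_trajectory")
  traj$omega <- vertex_orientations(traj)
  phi <- uncertainty_field(traj, grid)
  # rotate vertices by 90 degrees about the grid centre z-axis
  ctr <- c(16, 16, 16)
  rot <- function(p) c(ctr[1] - (p[2] - ctr[2]), ctr[2] + (p[1] - ctr[1]), p[3])
  traj2 <- traj
  traj2$vertices <- t(apply(traj$vertices, 1, rot))
  traj2$omega <- vertex_orientations(traj2)
  phi2 <- uncertainty_field(traj2, grid)
  expect_equal(sort(phi2$values[phi2$values > 0]),
               sort(phi$values[phi$values > 0]), tolerance = 1e-9)
})

test_that("tract probability renormalises per distance stratum", {
  grid <- make_grid(c(3, 2, 1))
  dm <- structure(list(grid = grid,
                       d = array(c(1L, 1L, 2L, 2L, 3L, 0L), c(3, 2, 1)),
                       max_d = 3L), class = "distance_map")
  phi <- scalar_volume(array(1, c(3, 2, 1)), grid)
  p <- scalar_volume(array(c(0.2, 0.1, 0.3, 0.6, 0.5, 0.9), c(3, 2, 1)), grid)
  pt <- tract_probability(phi, p, dm)
  expect_equal(as.numeric(pt$values), c(1, 0.5, 0.5, 1, 1, 0))
  # an all-zero stratum stays zero
  p2 <- scalar_volume(array(c(0.2, 0.1, 0, 0, 0.5, 0.9), c(3, 2, 1)), grid)
  pt2 <- tract_probability(phi, p2, dm)
  expect_equal(as.numeric(pt2$values)[3:4], c(0, 0))
  # per-stratum maximum is exactly 1 for every nonempty stratum
  spec <- straight_phantom_spec(seed = 8L)
  ph <- make_participant_pairs(spec, 3)
  tr <- estimate_tract(ph$pairs, ph$roi_a, ph$roi_b)
  expect_equal(tr$status, "accepted")
  strata <- tr$distance_map$d[tr$distance_map$d > 0]
  vals <- tr$p_tract$values[tr$distance_map$d > 0]
  mx <- tapply(vals, strata, max)
  nonzero <- tapply(tr$p_ab$values[tr$distance_map$d > 0] *
                      tr$phi$values[tr$distance_map$d > 0], strata, max) > 0
  expect_true(all(abs(mx[nonzero] - 1) < 1e-12))
  # phi is zero outside the 8 mm vertex neighbourhood union
  ctrs <- voxel_centres(tr$p_ab$grid)
  dmin <- rep(Inf, nrow(ctrs))
  for (v in seq_len(nrow(tr$trajectory$vertices))) {
    dv <- sqrt(rowSums(sweep(ctrs, 2, tr$trajectory$vertices[v, ])^2))
    dmin <- pmin(dmin, dv)
  }
  expect_true(all(tr$phi$values[dmin > 8] == 0))
})

test_that("trajectories round-trip through JSON", {
  spec <- straight_phantom_spec(seed = 9L)
  ph <- make_participant_pairs(spec, 2)
  tr <- estimate_tract(ph$pairs, ph$roi_a, ph$roi_b)
  f <- withr::local_tempfile(fileext = ".json")
  write_trajectory(tr$trajectory, f)
  back <- read_trajectory(f)
  expect_equal(back$vertices, tr$trajectory$vertices)
  expect_equal(back$omega, tr$trajectory$omega, tolerance = 1e-12)
  expect_identical(back$status, tr$trajectory$status)
})
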