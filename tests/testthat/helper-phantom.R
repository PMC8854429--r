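# shared fixture builders: everything is generated in code at test time

# straight-tube phantom on an n^3 grid with 2 mm voxels
straight_phantom_spec <- function(n = 32, voxel = 2, tube_sigma = 4,
                                  roi_radius = 4, seed = 42L, ...) {
  grid <- voxel_grid(rep(n, 3), rep(voxel, 3))
  ext <- (n - 1) * voxel
  margin <- roi_radius + voxel
  mid <- ext / 2
  phantom_spec(grid,
               curve_line(c(margin, mid, mid), c(ext - margin, mid, mid)),
               tube_sigma = tube_sigma, roi_radius = roi_radius,
               seed = seed, ...)
}

arc_phantom_spec <- function(n = 32, voxel = 2, tube_sigma = 4,
                             roi_radius = 4, bulge = 10, seed = 42L) {
  grid <- voxel_grid(rep(n, 3), rep(voxel, 3))
  ext <- (n - 1) * voxel
  margin <- roi_radius + voxel
  mid <- ext / 2
  phantom_spec(grid,
               curve_arc(c(margin, mid, mid), c(ext - margin, mid, mid),
                         bulge = bulge, normal = c(0, 1, 0)),
               tube_sigma = tube_sigma, roi_radius = roi_radius,
               seed = seed)
}

# uniform beta / intercept fields over the phantom's oriented support
phantom_signal_spec <- function(phantom, cohort,
                                gradients = make_gradient_scheme(137),
                                beta = 0.5, intercept = 0.3,
                                noise_sd = 0, seed = 7L, ...) {
  grid <- phantom$orientation$grid
  vec <- matrix(phantom$orientation$vectors, ncol = 3)
  support <- array(rowSums(vec^2) > 0, grid$dims)
  bt <- array(0, grid$dims); bt[support] <- beta
  ct <- array(0, grid$dims); ct[support] <- intercept
  signal_spec(gradients, scalar_volume(bt, grid), scalar_volume(ct, grid),
              cohort, noise_sd = noise_sd, seed = seed, ...)
}

# voxel-by-voxel breadth-first search, deliberately naive: the oracle for
# the vectorised frontier-expansion flood fill
bfs_oracle <- function(members, seed, conn) {
  dims <- dim(members)
  off <- neighbour_offsets(conn)
  dist <- array(0L, dims)
  visited <- seed
  frontier <- which(seed)
  dcur <- 0L
  repeat {
    nxt <- integer(0)
    for (v in frontier) {
      ijk <- arrayInd(v, dims)
      nb <- sweep(off, 2, as.integer(ijk), `+`)
      ok <- rowSums(nb >= 1) == 3 & rowSums(sweep(nb, 2, dims, `<=`)) == 3
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1) +
        dims[1] * dims[2] * (nb[, 3] - 1)
      nxt <- c(nxt, lin[members[lin] & !visited[lin]])
    }
    nxt <- unique(nxt)
    if (!length(nxt)) break
    dcur <- dcur + 1L
    dist[nxt] <- dcur
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  dist
}

# tiny deterministic cohort with both sexes and a spread of ages
tiny_cohort <- function(n = 8) {
  cohort_table(data.frame(
    participant_id = sprintf("p%02d", seq_len(n)),
    age = seq(20, 75, length.out = n),
    sex = rep(c(1L, 2L), length.out = n)
  ))
}
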