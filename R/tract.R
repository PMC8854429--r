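#' Normalise a directed visitation-count map
#'
#' Divides per-voxel streamline visitation counts by the total number of
#' streamlines that reached the target from the seed. Way-point voxels
#' can be visited by more streamlines than reach the target, so ratios
#' above 1 are clipped to 1 to keep the probability contract (all
#' downstream uses — minima, averages, maxima — are order-preserving
#' under clipping). A zero total marks the pair unconnectable and yields
#' an all-zero map.
#'
#' @param counts [scalar_volume()] of visitation counts.
#' @param total_to_target total streamlines reaching the target.
#' @return a probability [scalar_volume()] with attribute
#'   `unconnectable` set when `total_to_target` is 0.
#' @export
normalize_directed <- function(counts, total_to_target) {
  if (total_to_target < 0) stop("total_to_target must be >= 0")
  if (total_to_target == 0) {
    out <- scalar_volume(array(0, counts$grid$dims), counts$grid,
                         probability = TRUE)
    attr(out, "unconnectable") <- TRUE
    return(out)
  }
  out <- scalar_volume(pmin(counts$values / total_to_target, 1),
                       counts$grid, probability = TRUE)
  attr(out, "unconnectable") <- FALSE
  out
}

#' Bidirectional population-average probability map
#'
#' For each participant, takes the per-voxel minimum of the two directed
#' probability maps; averages these minima over participants; smooths
#' with a Gaussian kernel; and renormalises by the global maximum so the
#' output peaks at 1 (an all-zero input stays all-zero).
#'
#' @param per_participant_pairs list of `list(ab =, ba =)` probability
#'   [scalar_volume()]s, one element per participant.
#' @param smoothing_fwhm Gaussian FWHM in mm (default 2, one voxel on a
#'   2 mm grid; 0 disables smoothing).
#' @return a probability [scalar_volume()] (the population map P_ab).
#' @export
bidirectional_population_average <- function(per_participant_pairs,
                                             smoothing_fwhm = 2) {
  stopifnot(length(per_participant_pairs) >= 1L)
  g <- per_participant_pairs[[1]]$ab$grid
  acc <- array(0, g$dims)
  for (pair in per_participant_pairs) {
    check_same_grid(pair$ab, pair$ba)
    check_same_grid(pair$ab$grid, g)
    acc <- acc + pmin(pair$ab$values, pair$ba$values)
  }
  acc <- acc / length(per_participant_pairs)
  if (smoothing_fwhm > 0)
    acc <- gaussian_filter_3d(acc, smoothing_fwhm, g$voxel_size)
  mx <- max(acc)
  if (mx > 0) acc <- acc / mx
  scalar_volume(acc, g, probability = TRUE)
}

#' Threshold the population map with dilated ROIs
#'
#' Retains voxels where `p_ab >= alpha` (inclusive) and unions in both
#' ROIs after morphological dilation, which keeps the low-probability
#' voxels proximal to the ROIs connected to the tract body.
#'
#' @param p_ab population probability [scalar_volume()].
#' @param roi_a,roi_b seed and target [roi_mask()]s.
#' @param alpha probability threshold in (0, 1); default 0.07.
#' @param dilation_voxels dilation iterations (default 3).
#' @param connectivity structuring-element connectivity for the dilation.
#' @return logical membership array (the voxel set T_ab).
#' @export
threshold_with_dilated_rois <- function(p_ab, roi_a, roi_b, alpha = 0.07,
                                        dilation_voxels = 3,
                                        connectivity = 26) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  check_same_grid(p_ab, roi_a); check_same_grid(p_ab, roi_b)
  da <- dilate_mask(roi_a, dilation_voxels, connectivity)
  db <- dilate_mask(roi_b, dilation_voxels, connectivity)
  members <- (p_ab$values >= alpha) | da$mask | db$mask
  attr(members, "roi_a_dilated") <- da$mask
  attr(members, "roi_b_dilated") <- db$mask
  members
}

#' Flood-fill distance labelling from a seed ROI
#'
#' Breadth-first labelling over the member voxel set: all member
#' neighbours of the seed ROI get distance 1, their unlabelled member
#' neighbours distance 2, and so on. Seed-ROI voxels carry no distance;
#' members unreachable from the seed stay unassigned (0).
#'
#' @param members logical membership array (from
#'   [threshold_with_dilated_rois()]).
#' @param seed_roi the seed [roi_mask()] (typically dilated).
#' @param connectivity neighbourhood used for the fill (6/18/26;
#'   default 26).
#' @param grid the [voxel_grid()] of the member set.
#' @return a `distance_map`: list with `grid`, `d` (integer array; 0 =
#'   unassigned), `max_d`.
#' @export
flood_fill_distances <- function(members, seed_roi, grid,
                                 connectivity = 26) {
  dims <- dim(members)
  seed <- if (inherits(seed_roi, "roi_mask")) seed_roi$mask else seed_roi
  offsets <- neighbour_offsets(connectivity)
  d <- array(0L, dims)
  visited <- seed        # seed voxels carry no distance but stop the fill
  frontier <- which(seed)
  depth <- 0L
  while (length(frontier)) {
    nb <- expand_neighbours(frontier, dims, offsets)
    nb <- nb[members[nb] & !visited[nb]]
    if (!length(nb)) break
    depth <- depth + 1L
    d[nb] <- depth
    visited[nb] <- TRUE
    frontier <- nb
  }
  structure(list(grid = grid, d = d, max_d = depth), class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %d labelled voxels, max distance %d\n",
              sum(x$d > 0), x$max_d))
  invisible(x)
}

#' Build the core trajectory polyline
#'
#' Walks the distance strata in order. At each distance d the candidate
#' voxels are visited in descending `p_ab` order (ties broken by lowest
#' linear index) and the first voxel whose centre satisfies both
#' geometric constraints — segment to the previous vertex shorter than
#' `max_segment`, turning angle at the previous vertex below
#' `max_angle` — is appended. If no candidate satisfies them, the
#' maximal-probability voxel is appended and a violation flag recorded.
#' The walk terminates with status `"accepted"` as soon as a new
#' vertex's voxel lies inside, or 26-adjacent to, the dilated target
#' ROI; if the strata are exhausted first, the trajectory has status
#' `"rejected"` (the thresholding broke all routes).
#'
#' @param p_ab population probability [scalar_volume()].
#' @param distance_map result of [flood_fill_distances()].
#' @param target_roi dilated target mask (logical array or
#'   [roi_mask()]).
#' @param max_segment maximum segment length in mm (default 4).
#' @param max_angle maximum turning angle in radians (default pi/3;
#'   0 = straight).
#' @return a `core_trajectory`: list with `vertices` (n x 3 mm matrix),
#'   `voxels` (linear indices), `distances`, `omega` (per-vertex unit
#'   orientation), `flags` (per-vertex constraint-violation markers) and
#'   `status` ("accepted"/"rejected").
#' @export
build_core_polyline <- function(p_ab, distance_map, target_roi,
                                max_segment = 4, max_angle = pi / 3) {
  if (distance_map$max_d < 1L) {
    return(structure(list(vertices = matrix(numeric(0), 0, 3),
                          voxels = integer(0), distances = integer(0),
                          omega = matrix(numeric(0), 0, 3),
                          flags = logical(0), status = "rejected"),
                     class = "core_trajectory"))
  }
  grid <- p_ab$grid
  tmask <- if (inherits(target_roi, "roi_mask")) target_roi$mask else target_roi
  # target encounter = vertex voxel inside or 26-adjacent to the target
  tnear <- dilate_mask(tmask, 1, 26)
  darr <- distance_map$d
  pv <- p_ab$values
  verts <- matrix(NA_real_, distance_map$max_d, 3)
  voxs <- integer(distance_map$max_d)
  dists <- integer(distance_map$max_d)
  flags <- logical(distance_map$max_d)
  n <- 0L
  status <- "rejected"
  prev <- NULL; prev_dir <- NULL
  for (dd in seq_len(distance_map$max_d)) {
    cand <- which(darr == dd)
    if (!length(cand)) next
    ord <- order(-pv[cand], cand)
    cand <- cand[ord]
    cpts <- index_to_world(grid, arrayInd(cand, grid$dims) - 1L)
    chosen <- NULL; flag <- FALSE
    if (is.null(prev)) {
      chosen <- 1L
    } else {
      for (ci in seq_along(cand)) {
        seg <- cpts[ci, ] - prev
        len <- sqrt(sum(seg^2))
        if (len <= 0 || len >= max_segment) next
        if (!is.null(prev_dir)) {
          cosang <- sum(seg * prev_dir) / len
          ang <- acos(pmin(pmax(cosang, -1), 1))
          if (ang >= max_angle) next
        }
        chosen <- ci
        break
      }
      if (is.null(chosen)) { chosen <- 1L; flag <- TRUE }
    }
    vx <- cand[chosen]
    pt <- cpts[chosen, ]
    n <- n + 1L
    verts[n, ] <- pt
    voxs[n] <- vx
    dists[n] <- dd
    flags[n] <- flag
    if (!is.null(prev)) {
      seg <- pt - prev
      len <- sqrt(sum(seg^2))
      if (len > 0) prev_dir <- seg / len
    }
    prev <- pt
    if (tnear[vx]) { status <- "accepted"; break }
  }
  traj <- structure(
    list(vertices = verts[seq_len(n), , drop = FALSE],
         voxels = voxs[seq_len(n)], distances = dists[seq_len(n)],
         omega = NULL, flags = flags[seq_len(n)], status = status),
    class = "core_trajectory"
  )
  if (n >= 2L) traj$omega <- vertex_orientations(traj)
  traj
}

#' @export
print.core_trajectory <- function(x, ...) {
  cat(sprintf("<core_trajectory> %s, %d vertices, %d constraint flag(s)\n",
              x$status, nrow(x$vertices), sum(x$flags)))
  invisible(x)
}

#' Per-vertex orientation vectors of a polyline
#'
#' The orientation at an interior vertex is the normalised sum of its
#' two adjacent segment vectors; at the endpoints the single segment is
#' used.
#'
#' @param trajectory a `core_trajectory` (or any list with a `vertices`
#'   matrix of >= 2 rows).
#' @return an n x 3 matrix of unit vectors.
#' @export
vertex_orientations <- function(trajectory) {
  v <- trajectory$vertices
  n <- nrow(v)
  if (n < 2L) stop("vertex orientations need at least 2 vertices")
  segs <- diff(v)
  if (any(rowSums(segs^2) < 1e-20))
    stop("degenerate segment: duplicate consecutive vertices")
  omega <- rbind(
    segs[1, ],
    if (n > 2L) segs[seq_len(n - 2L), , drop = FALSE] +
                segs[seq(2L, n - 1L), , drop = FALSE],
    segs[n - 1L, ]
  )
  omega / sqrt(rowSums(omega^2))
}

#' Anisotropic Gaussian uncertainty field around a trajectory
#'
#' For each vertex v with orientation omega_v, an anisotropic Gaussian
#' kernel is evaluated at every voxel centre i within `radius` mm of v:
#' the offset i - v is decomposed into its component along omega_v
#' (axial distance) and the perpendicular remainder (radial distance),
#' and `phi = exp(-d_a^2 / (2 sigma_a^2) - d_r^2 / (2 sigma_r^2))`.
#' The field value at a voxel is the maximum of phi over all vertices;
#' voxels beyond `radius` of every vertex are 0. Kernels are
#' peak-normalised (value 1 at the vertex); the final tract probability
#' renormalises per distance stratum anyway.
#'
#' @param trajectory an accepted `core_trajectory` with orientations.
#' @param grid the [voxel_grid()].
#' @param sigma_axial axial standard deviation in mm (default 10).
#' @param sigma_radial radial standard deviation in mm (default 4).
#' @param radius evaluation radius around each vertex in mm (default 8).
#' @return a [scalar_volume()] with values in \[0, 1\].
#' @export
uncertainty_field <- function(trajectory, grid, sigma_axial = 10,
                              sigma_radial = 4, radius = 8) {
  if (trajectory$status != "accepted")
    stop("uncertainty field requires an accepted trajectory")
  omega <- trajectory$omega
  if (is.null(omega)) omega <- vertex_orientations(trajectory)
  phi <- array(0, grid$dims)
  dims <- grid$dims
  margin_vox <- ceiling(radius / grid$voxel_size)
  for (v in seq_len(nrow(trajectory$vertices))) {
    vert <- trajectory$vertices[v, ]
    w <- omega[v, ]
    cidx <- world_to_index(grid, vert)[1, ]
    lo <- pmax(floor(cidx - margin_vox), 0)
    hi <- pmin(ceiling(cidx + margin_vox), dims - 1)
    if (any(lo > hi)) next
    ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                 k = lo[3]:hi[3]))
    pts <- index_to_world(grid, ijk)
    dx <- sweep(pts, 2, vert)
    dist2 <- rowSums(dx^2)
    inside <- dist2 <= radius^2
    if (!any(inside)) next
    da <- dx[inside, , drop = FALSE] %*% w
    dr2 <- dist2[inside] - da^2
    dr2[dr2 < 0] <- 0
    val <- exp(-da^2 / (2 * sigma_axial^2) - dr2 / (2 * sigma_radial^2))
    lin <- 1L + ijk[inside, 1] + dims[1] * ijk[inside, 2] +
      dims[1] * dims[2] * ijk[inside, 3]
    upd <- val > phi[lin]
    phi[lin[upd]] <- val[upd]
  }
  scalar_volume(phi, grid, probability = TRUE)
}

#' Final tract probability map
#'
#' Multiplies the uncertainty field by the population probability map
#' element-wise, then normalises the product within each discrete
#' distance stratum of the distance map to a maximum of 1 (all-zero
#' strata stay zero). Voxels without a distance label are zero.
#'
#' @param phi uncertainty [scalar_volume()] (from
#'   [uncertainty_field()]).
#' @param p_ab population probability [scalar_volume()].
#' @param distance_map result of [flood_fill_distances()].
#' @return a probability [scalar_volume()] (P_ab-tract).
#' @export
tract_probability <- function(phi, p_ab, distance_map) {
  check_same_grid(phi, p_ab)
  g <- phi$values * p_ab$values
  out <- array(0, phi$grid$dims)
  darr <- distance_map$d
  labelled <- which(darr > 0L)
  if (length(labelled)) {
    vals <- g[labelled]
    strata <- darr[labelled]
    mx <- tapply(vals, strata, max)
    mxv <- as.numeric(mx[as.character(strata)])
    ok <- mxv > 0
    out[labelled[ok]] <- vals[ok] / mxv[ok]
  }
  scalar_volume(out, phi$grid, probability = TRUE)
}

#' Estimate a tract from directed visitation maps
#'
#' Runs the full tract-determination stage: bidirectional population
#' averaging, thresholding with dilated ROIs, flood-fill distance
#' labelling, core-polyline construction, the anisotropic-Gaussian
#' uncertainty field, and the per-stratum-normalised tract probability
#' map. Rejection (the threshold broke all routes between the ROIs) is
#' reported in the result's `status`, not as an error.
#'
#' @param per_participant_pairs list of `list(ab =, ba =)` probability
#'   volumes (see [bidirectional_population_average()]).
#' @param roi_a,roi_b seed and target [roi_mask()]s.
#' @param alpha threshold on the population map (default 0.07).
#' @param dilation_voxels ROI dilation iterations (default 3).
#' @param sigma_axial,sigma_radial,radius uncertainty-field parameters
#'   in mm (defaults 10, 4, 8).
#' @param max_segment,max_angle polyline constraints (defaults 4 mm,
#'   pi/3).
#' @param smoothing_fwhm population-average smoothing FWHM in mm.
#' @param connectivity voxel neighbourhood (6/18/26) for dilation and
#'   the flood fill.
#' @return a `tract_estimate`: list with `p_ab`, `members`,
#'   `distance_map`, `trajectory`, `phi`, `p_tract`, `status` and the
#'   parameters used. For rejected tracts `phi` and `p_tract` are NULL.
#' @export
estimate_tract <- function(per_participant_pairs, roi_a, roi_b,
                           alpha = 0.07, dilation_voxels = 3,
                           sigma_axial = 10, sigma_radial = 4, radius = 8,
                           max_segment = 4, max_angle = pi / 3,
                           smoothing_fwhm = 2, connectivity = 26) {
  p_ab <- bidirectional_population_average(per_participant_pairs,
                                           smoothing_fwhm)
  members <- threshold_with_dilated_rois(p_ab, roi_a, roi_b, alpha,
                                         dilation_voxels, connectivity)
  seed_dil <- attr(members, "roi_a_dilated")
  target_dil <- attr(members, "roi_b_dilated")
  dm <- flood_fill_distances(members, seed_dil, p_ab$grid, connectivity)
  traj <- build_core_polyline(p_ab, dm, target_dil, max_segment, max_angle)
  phi <- NULL; p_tract <- NULL
  if (traj$status == "accepted") {
    phi <- uncertainty_field(traj, p_ab$grid, sigma_axial, sigma_radial,
                             radius)
    p_tract <- tract_probability(phi, p_ab, dm)
  }
  structure(
    list(p_ab = p_ab, members = members, distance_map = dm,
         trajectory = traj, phi = phi, p_tract = p_tract,
         status = traj$status,
         params = list(alpha = alpha, dilation_voxels = dilation_voxels,
                       sigma_axial = sigma_axial,
                       sigma_radial = sigma_radial, radius = radius,
                       max_segment = max_segment, max_angle = max_angle,
                       smoothing_fwhm = smoothing_fwhm,
                       connectivity = connectivity)),
    class = "tract_estimate"
  )
}

#' @export
print.tract_estimate <- function(x, ...) {
  cat(sprintf("<tract_estimate> status: %s\n", x$status))
  cat(sprintf("  member voxels: %d; distance strata: %d\n",
              sum(x$members), x$distance_map$max_d))
  print(x$trajectory)
  invisible(x)
}

#' Write a core trajectory to JSON
#'
#' Serialises the ordered mm vertices, per-vertex orientations, flags
#' and status; [read_trajectory()] restores them.
#'
#' @param trajectory a `core_trajectory`.
#' @param path output JSON path.
#' @export
write_trajectory <- function(trajectory, path) {
  obj <- list(
    status = trajectory$status,
    vertices = unname(apply(trajectory$vertices, 1, as.numeric,
                            simplify = FALSE)),
    omega = if (!is.null(trajectory$omega))
      unname(apply(trajectory$omega, 1, as.numeric, simplify = FALSE)),
    distances = trajectory$distances,
    flags = trajectory$flags
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat3 <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) return(unname(x))
    matrix(unlist(x), ncol = 3, byrow = TRUE)
  }
  structure(
    list(vertices = as_mat3(obj$vertices),
         voxels = NULL,
         distances = as.integer(obj$distances),
         omega = as_mat3(obj$omega),
         flags = as.logical(obj$flags),
         status = obj$status),
    class = "core_trajectory"
  )
}
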