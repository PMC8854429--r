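#' Deterministic single-shell gradient scheme
#'
#' Generates M gradient directions by the spherical Fibonacci lattice
#' (antipodally unique, approximately uniform), preceded by `n_b0`
#' zero-gradient volumes, at a single b-value.
#'
#' @param m number of diffusion-weighted directions.
#' @param bval b-value in s/mm^2 (default 1500).
#' @param n_b0 number of b = 0 volumes (default 1).
#' @return a `gradient_table`.
#' @export
make_gradient_scheme <- function(m, bval = 1500, n_b0 = 1) {
  i <- seq_len(m) - 1
  z <- (2 * i + 1) / m - 1
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  bvals <- c(rep(0, n_b0), rep(bval, m))
  gradient_table(bvecs, bvals)
}

#' @rdname make_gradient_scheme
#' @param gradients a `gradient_table`.
#' @param bvec_path,bval_path output text paths (FSL dialect: bvec is
#'   3 rows x M columns, bval one row; b = 0 columns are restored).
#' @export
write_gradient_table <- function(gradients, bvec_path, bval_path) {
  bvecs <- rbind(matrix(0, gradients$n_b0, 3), gradients$bvecs)
  bvals <- c(rep(0, gradients$n_b0),
             rep(gradients$bval, nrow(gradients$bvecs)))
  write(t(bvecs), bvec_path, ncolumns = nrow(bvecs), sep = " ")
  write(bvals, bval_path, ncolumns = length(bvals), sep = " ")
  invisible(bvec_path)
}

pipeline_defaults <- function() {
  list(
    seed = 1L, out_dir = "tractsa-run",
    grid_dim = 32L, voxel_size = 2,
    tube_sigma = 4, roi_radius = 4,
    curve = "line", arc_bulge = 10,
    jitter_sd = 0.1, participant_sd = 0.05,
    n_participants = 12L, age_range = c(18, 80),
    female_fraction = 86 / 130,
    n_gradients = 137L, n_b0 = 1L, bval = 1500, diffusivity = 1e-3,
    beta_level = 0.5, intercept_level = 0.3, s0 = 1000,
    noise_sd = 0.01, noise_model = "gaussian",
    age_slope = 0, sex_effect = 0, interaction_effect = 0,
    alpha = 0.07, dilation = 3L, connectivity = 26L,
    smoothing_fwhm = 2,
    sigma_axial = 10, sigma_radial = 4, radius = 8,
    max_segment = 4, max_angle = pi / 3,
    tsa_fwhm = 1.5,
    lambda = 1.0, alpha_level = 0.05, min_extent = 3L,
    fdr_q = 0.05, field_model = "t"
  )
}

#' Pipeline run configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Every tunable
#' parameter of the four stages has a default matching the module
#' interfaces (alpha = 0.07, dilation = 3, sigma_a = 10 mm, sigma_r =
#' 4 mm, radius = 8 mm, max segment = 4 mm, max angle = pi/3, TSA
#' smoothing FWHM = 1.5 mm, lambda = 1, min cluster extent = 3, FDR
#' q = 0.05, level alpha = 0.05). Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults (see
#'   `tractsa:::pipeline_defaults()`).
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) && is.null(names(over)))
    stop("configuration overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$grid_dim >= 8, cfg$voxel_size > 0, cfg$tube_sigma > 0,
            cfg$roi_radius > 0, cfg$n_participants >= 6,
            cfg$n_gradients >= 6, cfg$bval > 0, cfg$diffusivity > 0,
            cfg$noise_sd >= 0, cfg$s0 > 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$dilation >= 0,
            cfg$connectivity %in% c(6, 18, 26),
            cfg$sigma_axial > 0, cfg$sigma_radial > 0, cfg$radius > 0,
            cfg$max_segment > 0, cfg$max_angle > 0, cfg$max_angle <= pi,
            cfg$tsa_fwhm >= 0, cfg$lambda >= 0,
            cfg$alpha_level > 0, cfg$alpha_level < 1,
            cfg$min_extent >= 1, cfg$fdr_q > 0, cfg$fdr_q < 1,
            cfg$field_model %in% c("t", "gaussian"),
            cfg$curve %in% c("line", "arc"))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path a YAML file of `key: value` pairs.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# phantom geometry implied by a config
config_phantom_spec <- function(cfg) {
  d <- cfg$grid_dim
  grid <- voxel_grid(rep(d, 3), rep(cfg$voxel_size, 3))
  ext <- (d - 1) * cfg$voxel_size
  margin <- cfg$roi_radius + cfg$voxel_size
  from <- c(margin, ext / 2, ext / 2)
  to <- c(ext - margin, ext / 2, ext / 2)
  curve <- if (cfg$curve == "arc") {
    curve_arc(from, to, bulge = cfg$arc_bulge, normal = c(0, 1, 0))
  } else {
    curve_line(from, to)
  }
  phantom_spec(grid, curve, tube_sigma = cfg$tube_sigma,
               roi_radius = cfg$roi_radius, seed = cfg$seed)
}

config_signal_spec <- function(cfg, phantom, cohort) {
  grid <- phantom$orientation$grid
  vec <- matrix(phantom$orientation$vectors, ncol = 3)
  support <- array(rowSums(vec^2) > 0, grid$dims)
  beta_true <- array(0, grid$dims); beta_true[support] <- cfg$beta_level
  c_true <- array(0, grid$dims); c_true[support] <- cfg$intercept_level
  gt <- make_gradient_scheme(cfg$n_gradients, cfg$bval, cfg$n_b0)
  signal_spec(
    gradients = gt,
    beta_true = scalar_volume(beta_true, grid),
    intercept_true = scalar_volume(c_true, grid),
    cohort = cohort, diffusivity = cfg$diffusivity,
    noise_sd = cfg$noise_sd, age_slope = cfg$age_slope,
    sex_effect = cfg$sex_effect,
    interaction_effect = cfg$interaction_effect,
    s0 = cfg$s0, noise_model = cfg$noise_model,
    seed = cfg$seed + 104729L
  )
}

stage_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

config_digest <- function(cfg, stage) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(list(stage = stage, config = unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

stage_done <- function(cfg, out_dir, stage) {
  mf <- file.path(out_dir, paste0(stage, "_manifest.json"))
  if (!file.exists(mf)) return(FALSE)
  prev <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
  identical(prev$config_digest, as.character(config_digest(cfg, stage)))
}

write_stage_manifest <- function(cfg, out_dir, stage, outputs) {
  mf <- file.path(out_dir, paste0(stage, "_manifest.json"))
  paths <- file.path(out_dir, outputs)
  hashes <- as.list(tools::md5sum(paths[file.exists(paths)]))
  names(hashes) <- basename(names(hashes))
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed,
         config_digest = as.character(config_digest(cfg, stage)),
         config = unclass(cfg), outputs = hashes),
    mf, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(mf)
}

#' Run the phantom-to-statistics pipeline
#'
#' Orchestrates phantom generation, tract determination, TSA fitting
#' and tract statistics from a single configuration, writing each
#' stage's outputs and a manifest (parameters, seed, output hashes)
#' under `config$out_dir`. A stage whose manifest already matches the
#' configuration is skipped (`resume = TRUE`), making reruns
#' idempotent. A rejected tract is recorded with its reason and the
#' downstream stages are skipped for it.
#'
#' Per-participant DWI signal matrices are synthesised deterministically
#' from the manifest seed during the `tsa` stage rather than stored on
#' disk.
#'
#' @param config a [run_config()].
#' @param stages subset of `c("phantom", "tract", "tsa", "stats")` to
#'   execute (in pipeline order).
#' @param resume skip stages whose manifest already matches.
#' @return invisibly, a list with the stage results available in
#'   memory (`tract`, `stats`, paths of written outputs).
#' @export
run_pipeline <- function(config,
                         stages = c("phantom", "tract", "tsa", "stats"),
                         resume = TRUE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config_phantom_spec(config)
  result <- list()

  ## -- phantom ---------------------------------------------------------
  phantom <- make_participant_pairs(spec, config$n_participants,
                                    jitter_sd = config$jitter_sd,
                                    participant_sd = config$participant_sd)
  cohort <- make_cohort(config$n_participants, config$age_range,
                        config$female_fraction, seed = config$seed)
  sspec <- config_signal_spec(config, phantom, cohort)
  if ("phantom" %in% stages) {
    if (resume && stage_done(config, out_dir, "phantom")) {
      stage_log("phantom: outputs up to date, skipping")
    } else {
      stage_log("phantom: %d participants on a %d^3 grid",
                config$n_participants, config$grid_dim)
      outs <- c("orientation.nii.gz", "roi_a.nii.gz", "roi_b.nii.gz",
                "cohort.tsv", "gradients.bvec", "gradients.bval")
      write_volume(phantom$orientation, file.path(out_dir, "orientation.nii.gz"))
      write_volume(phantom$roi_a, file.path(out_dir, "roi_a.nii.gz"))
      write_volume(phantom$roi_b, file.path(out_dir, "roi_b.nii.gz"))
      write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
      write_gradient_table(sspec$gradients,
                           file.path(out_dir, "gradients.bvec"),
                           file.path(out_dir, "gradients.bval"))
      for (p in seq_len(config$n_participants)) {
        fa <- sprintf("visitation_%s_ab.nii.gz", cohort$participant_id[p])
        fb <- sprintf("visitation_%s_ba.nii.gz", cohort$participant_id[p])
        write_volume(phantom$pairs[[p]]$ab, file.path(out_dir, fa),
                     datatype = "float")
        write_volume(phantom$pairs[[p]]$ba, file.path(out_dir, fb),
                     datatype = "float")
        outs <- c(outs, fa, fb)
      }
      write_stage_manifest(config, out_dir, "phantom", outs)
    }
  }

  ## -- tract determination ---------------------------------------------
  tract <- NULL
  if (any(c("tract", "tsa", "stats") %in% stages)) {
    tract <- estimate_tract(
      phantom$pairs, phantom$roi_a, phantom$roi_b,
      alpha = config$alpha, dilation_voxels = config$dilation,
      sigma_axial = config$sigma_axial, sigma_radial = config$sigma_radial,
      radius = config$radius, max_segment = config$max_segment,
      max_angle = config$max_angle, smoothing_fwhm = config$smoothing_fwhm,
      connectivity = config$connectivity
    )
    result$tract <- tract
  }
  if ("tract" %in% stages) {
    if (resume && stage_done(config, out_dir, "tract")) {
      stage_log("tract: outputs up to date, skipping")
    } else {
      stage_log("tract: status %s, %d strata, %d constraint flag(s)",
                tract$status, tract$distance_map$max_d,
                sum(tract$trajectory$flags))
      outs <- c("p_ab.nii.gz", "distance_map.nii.gz", "trajectory.json")
      write_volume(tract$p_ab, file.path(out_dir, "p_ab.nii.gz"))
      write_volume(
        scalar_volume(array(as.numeric(tract$distance_map$d),
                            tract$p_ab$grid$dims), tract$p_ab$grid),
        file.path(out_dir, "distance_map.nii.gz"), datatype = "int16")
      write_trajectory(tract$trajectory, file.path(out_dir, "trajectory.json"))
      if (tract$status == "accepted") {
        write_volume(tract$phi, file.path(out_dir, "phi.nii.gz"))
        write_volume(tract$p_tract, file.path(out_dir, "p_tract.nii.gz"))
        outs <- c(outs, "phi.nii.gz", "p_tract.nii.gz")
      } else {
        stage_log("tract: rejected (thresholding broke all routes)")
      }
      write_stage_manifest(config, out_dir, "tract", outs)
    }
  }

  ## -- TSA -------------------------------------------------------------
  tsa_maps <- NULL
  if (any(c("tsa", "stats") %in% stages)) {
    if (tract$status != "accepted") {
      stage_log("tsa: no accepted tract, skipping TSA fitting")
    } else {
      dwi <- make_dwi_signal(sspec, phantom$orientation,
                             support = tract$members)
      tsa_maps <- fit_tsa_cohort(dwi, phantom$orientation,
                                 smoothing_fwhm = config$tsa_fwhm)
      result$tsa <- tsa_maps
    }
  }
  if ("tsa" %in% stages && !is.null(tsa_maps)) {
    if (resume && stage_done(config, out_dir, "tsa")) {
      stage_log("tsa: outputs up to date, skipping")
    } else {
      stage_log("tsa: fitted %d participants at %d support voxels",
                length(tsa_maps), sum(tract$members))
      outs <- character(0)
      for (nm in names(tsa_maps)) {
        f <- sprintf("tsa_%s.nii.gz", nm)
        b <- tsa_maps[[nm]]$beta
        b[!tsa_maps[[nm]]$fitted] <- 0
        write_volume(scalar_volume(b, tract$p_ab$grid),
                     file.path(out_dir, f), datatype = "float")
        outs <- c(outs, f)
      }
      write_stage_manifest(config, out_dir, "tsa", outs)
    }
  }

  ## -- statistics ------------------------------------------------------
  if ("stats" %in% stages) {
    if (is.null(tsa_maps)) {
      stage_log("stats: no accepted tracts")
      writeLines("no accepted tracts",
                 file.path(out_dir, "stats_no_accepted_tracts.txt"))
      write_stage_manifest(config, out_dir, "stats",
                           "stats_no_accepted_tracts.txt")
    } else if (resume && stage_done(config, out_dir, "stats")) {
      stage_log("stats: outputs up to date, skipping")
    } else {
      st <- tract_stats(
        list(tract_01 = list(tsa = tsa_maps, tract = tract)), cohort,
        lambda_decay = config$lambda, alpha_level = config$alpha_level,
        min_extent = config$min_extent, q = config$fdr_q,
        model = config$field_model
      )
      result$stats <- st
      stage_log("stats: t* = %.4g, %d cluster(s), %d surviving",
                st$t_star, nrow(st$clusters), sum(st$clusters$survives))
      prof <- do.call(rbind, lapply(names(st$profiles), function(nm) {
        cbind(tract = nm, as.data.frame(st$profiles[[nm]]),
              stringsAsFactors = FALSE)
      }))
      write_csv_canonical(prof, file.path(out_dir, "distance_profiles.csv"))
      write_csv_canonical(st$clusters, file.path(out_dir, "clusters.csv"))
      write_csv_canonical(st$sums, file.path(out_dir, "signed_sums.csv"))
      write_stage_manifest(config, out_dir, "stats",
                           c("distance_profiles.csv", "clusters.csv",
                             "signed_sums.csv"))
    }
  }
  invisible(result)
}

# deterministic CSV writer (fixed precision, no row names)
write_csv_canonical <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
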