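# Synthetic canopy generator: elliptical leaf patches with known
# orientation and chlorophyll fields, a reference cube of known dimensions,
# and multi-day water-stress trajectories. Every quantity the pipeline
# estimates exists here as ground truth, so each stage is testable without
# any real reconstruction.

#' Specification of a synthetic leaf patch
#'
#' An elliptical patch of given size, orientation and per-point chlorophyll
#' field. Points are sampled uniformly over the ellipse, optionally bent by
#' a parabolic fold across the blade, rotated to the target orientation and
#' perturbed by Gaussian noise along the surface normal (emulating
#' photogrammetric reconstruction roughness).
#'
#' @param label integer leaf id (> 0).
#' @param center leaf center in cm (calibrated frame).
#' @param long_axis_length,short_axis_length ellipse axes in cm.
#' @param zenith,azimuth leaf-plane orientation in degrees
#'   (zenith in `[0, 90]`, azimuth in `[0, 360)`).
#' @param curvature parabolic fold curvature across the blade in 1/cm
#'   (0 = flat).
#' @param orientation `"up"` or `"down"`: whether the blade inclines
#'   upward or downward (metadata for the signed zenith; the plane fit
#'   itself cannot distinguish the two).
#' @param chl_base chlorophyll at the leaf center (ug/mm2-equivalent
#'   units of the calibration curve).
#' @param chl_gradient length-2 within-leaf chlorophyll gradient along the
#'   leaf-local long and short axes (units per cm); the default small
#'   gradient gives the heterogeneous within-leaf fields seen in real
#'   leaves while keeping colors realizable.
#' @param point_density surface sampling density in points/cm2. 400 is a
#'   typical close-range photogrammetry density at this leaf scale.
#' @param noise_sigma Gaussian noise standard deviation along the surface
#'   normal, cm. 0.02 cm reflects the sub-millimeter roughness of good
#'   reconstructions.
#' @return an object of class `leaf_spec`.
#' @export
leaf_spec <- function(label, center = c(0, 0, 20),
                      long_axis_length = 4, short_axis_length = 2,
                      zenith = 30, azimuth = 90, curvature = 0,
                      orientation = c("up", "down"),
                      chl_base = 12, chl_gradient = c(0.5, 0.25),
                      point_density = 400, noise_sigma = 0.02) {
  orientation <- match.arg(orientation)
  stopifnot(label > 0, long_axis_length > 0, short_axis_length > 0,
            zenith >= 0, zenith <= 90, point_density > 0, noise_sigma >= 0,
            length(chl_gradient) == 2)
  structure(list(label = as.integer(label), center = as.numeric(center),
                 long_axis_length = long_axis_length,
                 short_axis_length = short_axis_length,
                 zenith = zenith, azimuth = azimuth %% 360,
                 curvature = curvature, orientation = orientation,
                 chl_base = chl_base, chl_gradient = as.numeric(chl_gradient),
                 point_density = point_density, noise_sigma = noise_sigma),
            class = "leaf_spec")
}

# Realize a target normalized-Red value in 8-bit RGB. Green is held at a
# leaf-like constant; for every candidate blue the best red is the rounded
# solution of R = t (G + B) / (1 - t), and the (R, B) pair minimizing the
# realized error is kept. Returns the color matrix plus the realized
# normalized Red and a flag for points whose target forced channel
# clamping.
.realize_colors <- function(target_rn, green = 110L) {
  t <- pmin(pmax(target_rn, 0.004), 0.996)
  forced <- target_rn <= 0 | target_rn >= 1
  bs <- 0:255
  n <- length(t)
  reds <- integer(n); blues <- integer(n); realized <- numeric(n)
  clamped <- logical(n)
  gb <- green + bs
  for (i in seq_len(n)) {
    rraw <- t[i] * gb / (1 - t[i])
    r <- pmin(255, pmax(0, round(rraw)))
    rn <- r / (r + gb)
    err <- abs(rn - t[i])
    j <- which.min(err)
    reds[i] <- r[j]; blues[i] <- bs[j]; realized[i] <- rn[j]
    clamped[i] <- rraw[j] < -0.5 || rraw[j] > 255.5
  }
  list(colors = cbind(reds, rep(as.integer(green), n), blues),
       realized_rn = realized, clipped = clamped | forced)
}

#' Generate a synthetic leaf point cloud with ground truth
#'
#' Samples the patch described by `spec`, computes the analytic surface
#' normal at every point, evaluates the affine chlorophyll field in leaf
#' coordinates, and colors the points so that their normalized Red value
#' inverts the calibration curve at the true chlorophyll
#' (`r_n = (chl - intercept) / slope`), up to 8-bit quantization — the
#' documented noise floor of chlorophyll round-trip checks.
#'
#' @param spec a [leaf_spec()].
#' @param curve a `calibration_curve` with nonzero slope.
#' @param seed integer seed; identical seeds give bit-identical clouds.
#' @return list with `cloud` (a calibrated [point_cloud()] with leaf
#'   labels) and `truth` (data frame: leaf-local `u`, `v`, per-point
#'   `zenith_true`, `azimuth_true` degrees from the analytic normal,
#'   `chlorophyll_true`, `target_rn`, `realized_rn`, `clipped`).
#' @export
make_leaf <- function(spec, curve, seed = 1L) {
  stopifnot(inherits(spec, "leaf_spec"), inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("curve slope must be nonzero to invert colors")
  a <- spec$long_axis_length / 2
  b <- spec$short_axis_length / 2
  n <- max(12L, round(spec$point_density * pi * a * b))
  dat <- withr::with_seed(seed, {
    rr <- sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    eps <- if (spec$noise_sigma > 0) stats::rnorm(n, 0, spec$noise_sigma)
           else numeric(n)
    list(u = a * rr * cos(th), v = b * rr * sin(th), eps = eps)
  })
  u <- dat$u; v <- dat$v
  w <- spec$curvature * v^2 / 2
  rot <- rot_z(spec$azimuth) %*% rot_y(spec$zenith)
  local_pts <- cbind(u, v, w)
  # analytic surface normal of (u, v, c v^2 / 2): (0, -c v, 1) normalized
  nl <- cbind(0, -spec$curvature * v, 1)
  nl <- nl / sqrt(rowSums(nl^2))
  nw <- nl %*% t(rot)
  flip <- nw[, 3] < 0 | (nw[, 3] == 0 & (nw[, 1] < 0 |
                                           (nw[, 1] == 0 & nw[, 2] < 0)))
  nw[flip, ] <- -nw[flip, ]
  pts <- local_pts %*% t(rot) + dat$eps * nw
  pts <- sweep(pts, 2, spec$center, `+`)
  zen_true <- rad2deg(acos(pmin(1, pmax(-1, nw[, 3]))))
  az_true <- rad2deg(atan2(nw[, 2], nw[, 1])) %% 360
  chl <- spec$chl_base + spec$chl_gradient[1] * u + spec$chl_gradient[2] * v
  target_rn <- (chl - curve$intercept) / curve$slope
  if (mean(target_rn <= 0 | target_rn >= 1) > 0.5) {
    stop_phyto(paste("chlorophyll field maps outside the realizable",
                     "normalized-Red range (0,1) for %.0f%% of points;",
                     "target r_n spans [%.3f, %.3f]"),
               100 * mean(target_rn <= 0 | target_rn >= 1),
               min(target_rn), max(target_rn),
               class = "unrealizable_color_error")
  }
  col <- .realize_colors(target_rn)
  cloud <- point_cloud(pts, col$colors,
                       leaf_labels = rep(spec$label, n),
                       frame = "calibrated")
  truth <- data.frame(label = spec$label, u = u, v = v,
                      zenith_true = zen_true, azimuth_true = az_true,
                      chlorophyll_true = chl, target_rn = target_rn,
                      realized_rn = col$realized_rn, clipped = col$clipped)
  list(cloud = cloud, truth = truth)
}

#' Generate a whole synthetic plant
#'
#' @param specs list of [leaf_spec()] (distinct labels).
#' @param curve a `calibration_curve`.
#' @param seed integer master seed; per-leaf streams are derived from it.
#' @return list with combined `cloud` and row-bound `truth`.
#' @export
make_plant <- function(specs, curve, seed = 1L) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                             length(specs)))
  parts <- Map(function(sp, s) make_leaf(sp, curve, s), specs, seeds)
  list(cloud = combine_clouds(lapply(parts, `[[`, "cloud")),
       truth = do.call(rbind, lapply(parts, `[[`, "truth")))
}

#' Generate a reference cube with ready-made measurements
#'
#' Uniform point samples on the six faces of a box of known edge lengths,
#' expressed in an arbitrary "model" unit (`1 / true_scale` of a cm), plus
#' the corner point pairs a user would pick: one pair per edge direction
#' with the known cm lengths, and the vertical edge as the up reference.
#' Feeding the measurement to [estimate_scale_calibration()] must recover
#' `true_scale`.
#'
#' @param edges known box edge lengths in cm (x, y, z); default the 13 x
#'   12 x 9 cm field cube.
#' @param density face sampling density in points per model-frame cm2.
#' @param seed integer seed.
#' @param true_scale cm per model unit of the generated cloud.
#' @return list with `cloud` (frame `"raw"`, gray colors) and
#'   `measurement` (a [cube_measurement()]).
#' @export
make_reference_cube <- function(edges = c(13, 12, 9), density = 4,
                                seed = 1L, true_scale = 1) {
  stopifnot(all(edges > 0), density > 0, true_scale > 0)
  ex <- edges[1]; ey <- edges[2]; ez <- edges[3]
  areas <- c(ey * ez, ey * ez, ex * ez, ex * ez, ex * ey, ex * ey)
  counts <- pmax(4L, round(density * areas))
  pts_cm <- withr::with_seed(seed, {
    do.call(rbind, lapply(1:6, function(f) {
      n <- counts[f]
      switch(f,
        cbind(0, stats::runif(n, 0, ey), stats::runif(n, 0, ez)),
        cbind(ex, stats::runif(n, 0, ey), stats::runif(n, 0, ez)),
        cbind(stats::runif(n, 0, ex), 0, stats::runif(n, 0, ez)),
        cbind(stats::runif(n, 0, ex), ey, stats::runif(n, 0, ez)),
        cbind(stats::runif(n, 0, ex), stats::runif(n, 0, ey), 0),
        cbind(stats::runif(n, 0, ex), stats::runif(n, 0, ey), ez))
    }))
  })
  pts_model <- pts_cm / true_scale
  cloud <- point_cloud(pts_model,
                       matrix(190L, nrow(pts_model), 3), frame = "raw")
  corner <- function(x, y, z) c(x, y, z) / true_scale
  pairs <- data.frame(
    ax = 0, ay = 0, az = 0,
    bx = c(corner(ex, 0, 0)[1], 0, 0),
    by = c(0, corner(0, ey, 0)[2], 0),
    bz = c(0, 0, corner(0, 0, ez)[3]),
    known_cm = edges)
  meas <- cube_measurement(pairs, up_edge = rbind(c(0, 0, 0),
                                                  corner(0, 0, ez)))
  list(cloud = cloud, measurement = meas)
}

#' Multi-day stress scenario
#'
#' Per-leaf per-day shifts of the leaf parameters relative to each leaf's
#' base [leaf_spec()]: chlorophyll mean delta, zenith delta (degrees) and
#' azimuth delta (degrees). Deltas are given at anchor days and
#' interpolated linearly in between (held constant outside the anchored
#' range).
#'
#' @param days number of observation days (>= 1).
#' @param anchors data frame with columns `day`, `leaf`, `chl_delta`,
#'   `zenith_delta`, `azimuth_delta`.
#' @return an object of class `stress_scenario`.
#' @export
stress_scenario <- function(days, anchors) {
  stopifnot(days >= 1)
  anchors <- as.data.frame(anchors)
  need <- c("day", "leaf", "chl_delta", "zenith_delta", "azimuth_delta")
  if (!all(need %in% names(anchors))) {
    stop("`anchors` needs columns ", paste(need, collapse = ", "))
  }
  structure(list(days = as.integer(days), anchors = anchors[, need]),
            class = "stress_scenario")
}

# Linear interpolation of a leaf's deltas over all days.
.interp_deltas <- function(anchors, days) {
  if (nrow(anchors) == 1) {
    out <- anchors[rep(1, days), c("chl_delta", "zenith_delta",
                                   "azimuth_delta")]
  } else {
    out <- data.frame(
      chl_delta = stats::approx(anchors$day, anchors$chl_delta,
                                xout = seq_len(days), rule = 2)$y,
      zenith_delta = stats::approx(anchors$day, anchors$zenith_delta,
                                   xout = seq_len(days), rule = 2)$y,
      azimuth_delta = stats::approx(anchors$day, anchors$azimuth_delta,
                                    xout = seq_len(days), rule = 2)$y)
  }
  out$day <- seq_len(days)
  out
}

#' The single-leaf water-stress preset
#'
#' A five-day scenario for one leaf whose day-1/3/5 target means follow
#' the within-leaf stress trajectory used throughout the package's
#' validation: chlorophyll 12.9 / 11.7 / 7.0 (dimensionless preset units),
#' zenith 23.7 / 33.1 / 33.9 degrees, azimuth 88.6 / 119.3 / 156.9
#' degrees; the intermediate days are interpolated.
#'
#' @return list with `specs` (one [leaf_spec()], base = day-1 values),
#'   `scenario` (a [stress_scenario()]), `targets` (data frame of the
#'   day-1/3/5 target means), and the default `curve` used to color it.
#' @export
water_stress_scenario <- function() {
  curve <- calibration_curve(slope = -40, intercept = 20)
  base <- leaf_spec(label = 1L, center = c(0, 0, 20),
                    long_axis_length = 4, short_axis_length = 2,
                    zenith = 23.7, azimuth = 88.6, curvature = 0.05,
                    chl_base = 12.9)
  targets <- data.frame(day = c(1, 3, 5),
                        chl_mean = c(12.9, 11.7, 7.0),
                        zenith = c(23.7, 33.1, 33.9),
                        azimuth = c(88.6, 119.3, 156.9))
  anchors <- data.frame(day = targets$day, leaf = 1L,
                        chl_delta = targets$chl_mean - base$chl_base,
                        zenith_delta = targets$zenith - base$zenith,
                        azimuth_delta = targets$azimuth - base$azimuth)
  list(specs = list(base), scenario = stress_scenario(5, anchors),
       targets = targets, curve = curve)
}

#' Generate a day-indexed stress time series
#'
#' One plant cloud per day, with each leaf's chlorophyll mean, zenith and
#' azimuth shifted by the scenario's (interpolated) deltas. Zenith shifts
#' leaving `[0, 90]` are clamped with a warning; azimuth wraps mod 360.
#'
#' @param specs list of base [leaf_spec()].
#' @param scenario a [stress_scenario()].
#' @param curve a `calibration_curve`.
#' @param seed integer master seed.
#' @return list with `clouds` (per-day [point_cloud()]), `truths` (per-day
#'   truth data frames) and `targets` (data frame of per-day per-leaf true
#'   parameter values: `day`, `leaf`, `chl_mean`, `zenith`, `azimuth`).
#' @export
make_stress_timeseries <- function(specs, scenario, curve, seed = 1L) {
  stopifnot(inherits(scenario, "stress_scenario"))
  days <- scenario$days
  day_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, days))
  labels <- vapply(specs, `[[`, 1L, "label")
  deltas <- lapply(labels, function(lab) {
    an <- scenario$anchors[scenario$anchors$leaf == lab, , drop = FALSE]
    if (nrow(an) == 0) {
      data.frame(chl_delta = 0, zenith_delta = 0, azimuth_delta = 0,
                 day = seq_len(days))
    } else {
      .interp_deltas(an, days)
    }
  })
  clouds <- vector("list", days)
  truths <- vector("list", days)
  targets <- list()
  for (d in seq_len(days)) {
    day_specs <- lapply(seq_along(specs), function(j) {
      sp <- specs[[j]]
      dl <- deltas[[j]][d, ]
      z <- sp$zenith + dl$zenith_delta
      if (z < 0 || z > 90) {
        warning(sprintf("day %d leaf %d: zenith %0.1f clamped into [0, 90]",
                        d, sp$label, z))
        z <- min(90, max(0, z))
      }
      sp$chl_base <- sp$chl_base + dl$chl_delta
      sp$zenith <- z
      sp$azimuth <- (sp$azimuth + dl$azimuth_delta) %% 360
      targets[[length(targets) + 1L]] <<-
        data.frame(day = d, leaf = sp$label, chl_mean = sp$chl_base,
                   zenith = sp$zenith, azimuth = sp$azimuth)
      sp
    })
    plant <- make_plant(day_specs, curve, day_seeds[d])
    clouds[[d]] <- plant$cloud
    truths[[d]] <- plant$truth
  }
  list(clouds = clouds, truths = truths, targets = do.call(rbind, targets))
}

#' Simulate calibration samples around a known curve
#'
#' Draws normalized Red values uniformly over a realistic leaf range and
#' chlorophyll values from the curve plus Gaussian noise sized so the
#' population R-squared equals `r_squared` — emulating the scatter of a
#' real leaf-disc calibration set.
#'
#' @param curve the generating `calibration_curve`.
#' @param n number of samples (default 30, a typical leaf-disc count).
#' @param r_squared population coefficient of determination (default
#'   0.81).
#' @param rn_range range of normalized Red values sampled.
#' @param seed integer seed.
#' @return a [calibration_samples()] data frame.
#' @export
make_calibration_samples <- function(curve, n = 30L, r_squared = 0.81,
                                     rn_range = c(0.15, 0.35), seed = 1L) {
  stopifnot(r_squared > 0, r_squared <= 1, n >= 3)
  width <- diff(rn_range)
  signal_var <- curve$slope^2 * width^2 / 12
  sigma <- sqrt(signal_var * (1 - r_squared) / r_squared)
  withr::with_seed(seed, {
    rn <- stats::runif(n, rn_range[1], rn_range[2])
    chl <- pmax(0, predict(curve, rn) + stats::rnorm(n, 0, sigma))
    calibration_samples(rn, chl)
  })
}

#' Write a full simulation to disk
#'
#' Materializes a stress scenario as the file set the pipeline consumes:
#' `dayN.ply` (labeled colored clouds), `truthN.csv`, `labels.json`
#' (per-leaf orientation flags), `cube.ply` + `cube_measurement.csv`, and
#' `calibration_samples.csv`.
#'
#' @param outdir output directory (created if needed).
#' @param specs,scenario,curve,seed as in [make_stress_timeseries()];
#'   defaults to the [water_stress_scenario()] preset.
#' @return invisibly, the list of written paths.
#' @export
simulate_to_dir <- function(outdir, specs = NULL, scenario = NULL,
                            curve = NULL, seed = 1L) {
  if (is.null(specs) || is.null(scenario)) {
    preset <- water_stress_scenario()
    if (is.null(specs)) specs <- preset$specs
    if (is.null(scenario)) scenario <- preset$scenario
    if (is.null(curve)) curve <- preset$curve
  }
  if (is.null(curve)) curve <- calibration_curve(-40, 20)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_stress_timeseries(specs, scenario, curve, seed)
  paths <- character()
  for (d in seq_along(sim$clouds)) {
    p <- file.path(outdir, sprintf("day%d.ply", d))
    write_ply(sim$clouds[[d]], p, format = "binary_little_endian")
    utils::write.csv(sim$truths[[d]],
                     file.path(outdir, sprintf("truth%d.csv", d)),
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  ori <- stats::setNames(
    vapply(specs, `[[`, "", "orientation"),
    vapply(specs, function(s) as.character(s$label), ""))
  jsonlite::write_json(as.list(ori), file.path(outdir, "labels.json"),
                       auto_unbox = TRUE)
  cube <- make_reference_cube(seed = seed)
  write_ply(cube$cloud, file.path(outdir, "cube.ply"))
  pp <- cube$measurement$point_pairs
  pp$up_edge <- FALSE
  up <- data.frame(ax = cube$measurement$up_edge[1, 1],
                   ay = cube$measurement$up_edge[1, 2],
                   az = cube$measurement$up_edge[1, 3],
                   bx = cube$measurement$up_edge[2, 1],
                   by = cube$measurement$up_edge[2, 2],
                   bz = cube$measurement$up_edge[2, 3],
                   known_cm = NA, up_edge = TRUE)
  utils::write.csv(rbind(pp, up),
                   file.path(outdir, "cube_measurement.csv"),
                   row.names = FALSE)
  samples <- make_calibration_samples(curve, seed = seed)
  utils::write.csv(data.frame(normalized_red = samples$normalized_red,
                              chlorophyll_ug_mm2 = samples$chlorophyll),
                   file.path(outdir, "calibration_samples.csv"),
                   row.names = FALSE)
  invisible(c(paths, file.path(outdir, c("labels.json", "cube.ply",
                                         "cube_measurement.csv",
                                         "calibration_samples.csv"))))
}
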