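# End-to-end workflow: scale calibration -> chlorophyll calibration ->
# per-point chlorophyll map -> angle field -> monitoring outputs, with a
# manifest that fully determines the run.

#' Pipeline configuration
#'
#' All tunables of the workflow in one validated object. Unknown keys are
#' rejected so a typo in a config file cannot silently fall back to a
#' default.
#'
#' @param cube_side neighborhood cube side in cm.
#' @param min_points minimum neighborhood size for a plane fit.
#' @param region_radius pooling radius for leaf regions in cm.
#' @param cv_mode `"loo"` or `"kfold"` cross-validation of the calibration.
#' @param chl_bin_width,angle_bin_width histogram bin widths.
#' @param horizontal_threshold zenith below which azimuth is flagged
#'   undefined (degrees).
#' @param seed integer seed for any stochastic step (k-fold assignment).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cube_side = 0.5, min_points = 10L,
                            region_radius = 0.25, cv_mode = c("loo", "kfold"),
                            chl_bin_width = 1, angle_bin_width = 5,
                            horizontal_threshold = 1, seed = 1L) {
  cv_mode <- match.arg(cv_mode)
  stopifnot(cube_side > 0, min_points >= 3, region_radius > 0,
            chl_bin_width > 0, angle_bin_width > 0,
            horizontal_threshold >= 0)
  structure(list(cube_side = cube_side, min_points = as.integer(min_points),
                 region_radius = region_radius, cv_mode = cv_mode,
                 chl_bin_width = chl_bin_width,
                 angle_bin_width = angle_bin_width,
                 horizontal_threshold = horizontal_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys are [pipeline_config()] arguments;
#'   unknown keys are an error.
#' @param overrides named list applied on top of the file (CLI flags beat
#'   the file, the file beats the documented defaults).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_phyto("pipeline stage '%s' failed: %s", name, conditionMessage(e),
               class = "pipeline_stage_error")
  })
}

#' Run the full monitoring pipeline
#'
#' Workflow: (optional) estimate the scale calibration from reference-cube
#' measurements and apply it to every cloud; fit and cross-validate the
#' chlorophyll calibration; map chlorophyll over each cloud; compute the
#' angle field; aggregate per-leaf histograms, the per-region day series
#' and the day-1 vs final-day omnibus test. Outputs: annotated
#' `dayN_annotated.ply`, `curve.json`, `series.csv`, per-day histogram
#' CSVs, `tests.csv`, and `manifest.json` (effective config, package
#' version, input checksums) — the manifest fully determines the outputs.
#' On any stage failure partial outputs are removed and the error names
#' the stage.
#'
#' @param config a [pipeline_config()].
#' @param cloud_paths PLY paths, one per observation day (in day order).
#' @param samples_path calibration-sample CSV
#'   (see [read_calibration_samples()]).
#' @param labels_path optional JSON of per-leaf orientation flags
#'   (`{"1": "up", "2": "down"}`); enables the signed zenith.
#' @param cube_path optional cube-measurement CSV/JSON; when given, clouds
#'   are read as raw and calibrated, otherwise they must already be in the
#'   calibrated frame.
#' @param out_dir output directory.
#' @param days integer day indices, default `1..length(cloud_paths)`.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the fitted `curve`, the `series` data
#'   frame, the `tests` data frame and the manifest.
#' @export
run_pipeline <- function(config, cloud_paths, samples_path,
                         labels_path = NULL, cube_path = NULL,
                         out_dir, days = seq_along(cloud_paths),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  created <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(created), add = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  inputs <- c(cloud_paths, samples_path, labels_path, cube_path)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop_phyto("pipeline stage 'validate' failed: missing input file(s): %s",
               paste(missing, collapse = ", "),
               class = "pipeline_stage_error")
  }

  clouds <- .stage("read", {
    frame <- if (is.null(cube_path)) "calibrated" else "raw"
    lapply(cloud_paths, read_ply, frame = frame)
  })
  if (!is.null(cube_path)) {
    cal <- .stage("scale", estimate_scale_calibration(
      read_cube_measurement(cube_path)))
    clouds <- .stage("scale", lapply(clouds, apply_calibration, cal = cal))
    note("scale: %.6g cm per model unit", cal$scale)
  }

  curve_cv <- .stage("calibrate", {
    samples <- read_calibration_samples(samples_path)
    curve <- fit_calibration(samples)
    cv <- if (config$cv_mode == "loo") loocv_mae(samples)
          else kfold_mae(samples, seed = config$seed)
    list(curve = curve, cv_mae = cv)
  })
  curve <- curve_cv$curve
  note("calibrate: slope=%.4g intercept=%.4g R2=%.3f cv_mae=%.4g (n=%d)",
       curve$slope, curve$intercept, curve$r_squared, curve_cv$cv_mae,
       curve$n)
  p <- file.path(out_dir, "curve.json")
  write_curve(curve, p); created <- c(created, p)

  clouds <- .stage("map-chlorophyll", lapply(clouds, map_chlorophyll, curve))

  spec <- neighborhood_spec(config$cube_side, config$min_points,
                            config$horizontal_threshold)
  orientation <- if (!is.null(labels_path)) {
    jsonlite::read_json(labels_path, simplifyVector = TRUE)
  }
  clouds <- .stage("angles", lapply(seq_along(clouds), function(i) {
    fld <- compute_angle_field(clouds[[i]], spec)
    masked <- sum(!fld$valid)
    if (masked > 0) {
      warning(sprintf("day %d: %d of %d points masked in the angle field",
                      days[i], masked, length(fld$valid)))
    }
    if (!is.null(orientation) && !is.null(clouds[[i]]$leaf_labels)) {
      fld <- apply_leaf_sign(fld, orientation)
    }
    fld$cloud
  }))

  for (i in seq_along(clouds)) {
    p <- file.path(out_dir, sprintf("day%d_annotated.ply", days[i]))
    write_ply(clouds[[i]], p, format = "binary_little_endian")
    created <- c(created, p)
    note("angles: day %d, %d points", days[i], n_points(clouds[[i]]))
  }

  res <- .stage("monitor", {
    series <- build_series(clouds, days = days,
                           radius = config$region_radius)
    labs <- sort(unique(unlist(lapply(clouds, function(cl) {
      l <- cl$leaf_labels; l[l != 0L]
    }))))
    hists <- list()
    for (i in seq_along(clouds)) {
      for (lab in labs) {
        if (!lab %in% clouds[[i]]$leaf_labels) next
        for (q in c("chlorophyll", "zenith", "azimuth")) {
          bw <- if (q == "chlorophyll") config$chl_bin_width
                else config$angle_bin_width
          h <- tryCatch(leaf_histogram(clouds[[i]], lab, q, bw),
                        phytocloud_error = function(e) NULL)
          if (is.null(h)) next
          df <- histogram_df(h)
          df <- cbind(data.frame(day = days[i], leaf = lab, quantity = q),
                      df)
          hists[[length(hists) + 1L]] <- df
        }
      }
    }
    tests <- NULL
    if (length(clouds) >= 2) {
      d1 <- 1L; dn <- length(clouds)
      tests <- do.call(rbind, lapply(c("chlorophyll", "zenith", "azimuth"),
        function(q) {
          vals <- list(cloud_attr(clouds[[d1]], q),
                       cloud_attr(clouds[[dn]], q))
          names(vals) <- paste0("day", days[c(d1, dn)])
          ct <- tryCatch(compare_days(vals),
                         phytocloud_error = function(e) NULL)
          if (is.null(ct)) return(NULL)
          data.frame(quantity = q, day_a = days[d1], day_b = days[dn],
                     statistic = ct$statistic, df = ct$df,
                     p_value = ct$p_value, method = ct$method)
        }))
    }
    list(series = series, hists = hists, tests = tests)
  })

  p <- file.path(out_dir, "series.csv")
  utils::write.csv(res$series, p, row.names = FALSE)
  created <- c(created, p)
  if (length(res$hists)) {
    p <- file.path(out_dir, "histograms.csv")
    utils::write.csv(do.call(rbind, res$hists), p, row.names = FALSE)
    created <- c(created, p)
  }
  if (!is.null(res$tests)) {
    p <- file.path(out_dir, "tests.csv")
    utils::write.csv(res$tests, p, row.names = FALSE)
    created <- c(created, p)
  }

  manifest <- list(
    package = "phytocloud",
    version = as.character(utils::packageVersion("phytocloud")),
    config = unclass(config),
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                     basename(inputs))),
    days = days,
    outputs = basename(created))
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  created <- c(created, p)
  note("done in %.1f s", proc.time()[["elapsed"]] - t0)
  ok <- TRUE
  invisible(list(curve = curve, cv_mae = curve_cv$cv_mae,
                 series = res$series, tests = res$tests,
                 manifest = manifest))
}
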