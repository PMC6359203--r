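# Chlorophyll estimation from color: the normalized Red value R/(R+G+B)
# decreases as chlorophyll (a red-light absorber) increases, so a linear
# calibration against wet-chemistry measurements turns per-point color into
# a per-point chlorophyll map.

#' Normalized Red value
#'
#' `R / (R + G + B)`: the red channel's fraction of total intensity,
#' invariant under uniform brightness scaling. Black pixels
#' (`r + g + b == 0`) have no defined chroma; by default this is an error,
#' while `na_on_undefined = TRUE` returns `NA` for those entries (how
#' [map_chlorophyll()] builds its validity mask).
#'
#' @param r,g,b integer channel values in `[0, 255]`, vectorized.
#' @param na_on_undefined return `NA` instead of erroring on black pixels.
#' @return normalized Red in `[0, 1]`.
#' @export
normalized_red <- function(r, g, b, na_on_undefined = FALSE) {
  ch <- c(r, g, b)
  if (anyNA(ch) || any(ch < 0 | ch > 255) || any(ch != round(ch))) {
    stop("r, g, b must be integers in [0, 255]")
  }
  s <- r + g + b
  bad <- s == 0
  if (any(bad) && !na_on_undefined) {
    stop_phyto("undefined color: r+g+b = 0 (black pixel has no chroma)",
               class = "undefined_color_error")
  }
  out <- r / s
  out[bad] <- NA_real_
  out
}

#' Total chlorophyll from spectrophotometric absorbances (Porra 1989)
#'
#' Chlorophyll a+b concentration of an 80% acetone extract from absorbances
#' at 646.6 nm and 663.6 nm: `17.76 * A646.6 + 7.34 * A663.6` (ug/mL).
#'
#' @param a646_6 absorbance at 646.6 nm (dimensionless, >= 0), vectorized.
#' @param a663_6 absorbance at 663.6 nm (dimensionless, >= 0).
#' @return total chlorophyll a+b in ug/mL.
#' @references Porra, R.J., Thompson, W.A., Kriedemann, P.E. (1989).
#'   Determination of accurate extinction coefficients and simultaneous
#'   equations for assaying chlorophylls a and b. Biochim. Biophys. Acta
#'   975, 384-394.
#' @export
porra_total_chlorophyll <- function(a646_6, a663_6) {
  if (anyNA(c(a646_6, a663_6)) || any(a646_6 < 0) || any(a663_6 < 0)) {
    stop("absorbances must be non-negative")
  }
  17.76 * a646_6 + 7.34 * a663_6
}

#' Convert extract concentration to areal chlorophyll content
#'
#' A leaf disc of area `punch_area` mm2 extracted into `extract_volume` mL
#' holds `conc * extract_volume` ug of chlorophyll, i.e.
#' `conc * extract_volume / punch_area` ug/mm2 of leaf surface.
#'
#' @param conc concentration in ug/mL, vectorized.
#' @param extract_volume acetone extract volume in mL (> 0).
#' @param punch_area hole-punch disc area in mm2 (> 0).
#' @return areal chlorophyll content in ug/mm2.
#' @export
concentration_to_areal <- function(conc, extract_volume, punch_area) {
  if (any(extract_volume <= 0)) stop("extract_volume must be > 0")
  if (any(punch_area <= 0)) stop("punch_area must be > 0")
  conc * extract_volume / punch_area
}

#' Assemble calibration samples
#'
#' @param normalized_red normalized Red values in (0, 1).
#' @param chlorophyll measured areal chlorophyll contents (ug/mm2, >= 0).
#' @param source_point optional indices of the cloud points the samples
#'   were picked from.
#' @return a data frame of class `calibration_samples`.
#' @export
calibration_samples <- function(normalized_red, chlorophyll,
                                source_point = NULL) {
  stopifnot(length(normalized_red) == length(chlorophyll))
  if (any(normalized_red <= 0 | normalized_red >= 1)) {
    stop("normalized_red must lie strictly inside (0, 1)")
  }
  if (any(chlorophyll < 0)) stop("chlorophyll must be >= 0")
  df <- data.frame(normalized_red = as.double(normalized_red),
                   chlorophyll = as.double(chlorophyll))
  if (!is.null(source_point)) df$source_point <- as.integer(source_point)
  class(df) <- c("calibration_samples", "data.frame")
  df
}

#' Read calibration samples from CSV
#'
#' Two layouts are accepted. Direct: columns `normalized_red`,
#' `chlorophyll_ug_mm2`. Raw-absorbance: columns `normalized_red`,
#' `a646_6`, `a663_6`, `volume_ml`, `punch_area_mm2`, converted through
#' [porra_total_chlorophyll()] and [concentration_to_areal()].
#'
#' @param path CSV path.
#' @return a [calibration_samples()] data frame.
#' @export
read_calibration_samples <- function(path) {
  df <- utils::read.csv(path)
  if ("chlorophyll_ug_mm2" %in% names(df)) {
    chl <- df$chlorophyll_ug_mm2
  } else if (all(c("a646_6", "a663_6", "volume_ml", "punch_area_mm2") %in%
                 names(df))) {
    chl <- concentration_to_areal(
      porra_total_chlorophyll(df$a646_6, df$a663_6),
      df$volume_ml, df$punch_area_mm2)
  } else {
    stop("CSV must have chlorophyll_ug_mm2, or a646_6/a663_6/volume_ml/punch_area_mm2")
  }
  calibration_samples(df$normalized_red, chl)
}

# Plain OLS on (x, y) via the textbook moment formulas; shared by the fit
# and by every LOOCV fold.
.ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) {
    stop_phyto("rank deficiency: all normalized Red values identical",
               class = "rank_deficiency_error")
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}

#' Construct a calibration curve directly
#'
#' Builds the linear map `chlorophyll = slope * normalized_red + intercept`
#' from known coefficients, e.g. loaded from JSON or chosen for a synthetic
#' scenario. Curves estimated from data come from [fit_calibration()].
#'
#' @param slope slope in ug/mm2 per unit normalized Red.
#' @param intercept intercept in ug/mm2.
#' @param r_squared,n optional fit diagnostics to carry along.
#' @return an object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, r_squared = NA_real_,
                              n = 0L) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n = as.integer(n),
                 residuals = numeric()),
            class = "calibration_curve")
}

#' Fit the chlorophyll calibration curve
#'
#' Ordinary least-squares regression of measured chlorophyll on the
#' normalized Red value. Chlorophyll is regressed on color (not the
#' reverse) because the curve is used predictively: color is what the
#' whole-cloud map supplies. R-squared is the squared Pearson correlation,
#' identical to `1 - SSE/SST` in this single-predictor setting.
#'
#' @param samples a [calibration_samples()] data frame (n >= 3, at least
#'   two distinct normalized Red values).
#' @return a `calibration_curve` with `slope`, `intercept`, `r_squared`,
#'   `n` and per-sample `residuals` (which sum to zero).
#' @export
fit_calibration <- function(samples) {
  x <- samples$normalized_red
  y <- samples$chlorophyll
  n <- length(x)
  if (n < 3) stop("need at least 3 calibration samples")
  co <- .ols(x, y)
  fitted <- co["slope"] * x + co["intercept"]
  res <- y - fitted
  r2 <- if (stats::var(y) <= 0) 0 else stats::cor(x, y)^2
  structure(list(slope = unname(co["slope"]),
                 intercept = unname(co["intercept"]),
                 r_squared = r2, n = n, residuals = unname(res)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> chl = %.4g * r_n + %.4g  (R2=%s, n=%d)\n",
              x$slope, x$intercept,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
              x$n))
  invisible(x)
}

#' Predict chlorophyll from normalized Red
#' @param object a `calibration_curve`.
#' @param normalized_red numeric vector.
#' @param ... unused.
#' @return predicted chlorophyll (ug/mm2); `NA` in gives `NA` out.
#' @export
predict.calibration_curve <- function(object, normalized_red, ...) {
  object$slope * normalized_red + object$intercept
}

#' Leave-one-out cross-validated absolute error of the calibration
#'
#' Each sample is predicted from a curve refitted to the other `n - 1`
#' samples; the mean absolute prediction error summarizes how well the
#' calibration generalizes. Leave-one-out is used because calibration sets
#' in this application are small (tens of leaf discs) and the procedure is
#' deterministic; [kfold_mae()] offers the seeded k-fold alternative.
#'
#' @param samples a [calibration_samples()] data frame (n >= 4).
#' @return mean absolute prediction error in ug/mm2.
#' @export
loocv_mae <- function(samples) {
  x <- samples$normalized_red
  y <- samples$chlorophyll
  n <- length(x)
  if (n < 4) stop("need at least 4 samples for cross-validation")
  err <- vapply(seq_len(n), function(i) {
    co <- .ols(x[-i], y[-i])
    abs(y[i] - (co["slope"] * x[i] + co["intercept"]))
  }, 0)
  mean(err)
}

#' @rdname loocv_mae
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @export
kfold_mae <- function(samples, k = 5, seed = 1L) {
  x <- samples$normalized_red
  y <- samples$chlorophyll
  n <- length(x)
  if (n < k || k < 2) stop("need k >= 2 and n >= k samples")
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  err <- numeric(n)
  for (f in seq_len(k)) {
    hold <- fold == f
    co <- .ols(x[!hold], y[!hold])
    err[hold] <- abs(y[hold] - (co["slope"] * x[hold] + co["intercept"]))
  }
  mean(err)
}

#' Map a calibration curve over a whole cloud
#'
#' Adds three attributes to the cloud: `chlorophyll` (predicted ug/mm2,
#' `NA` where the normalized Red value is undefined, i.e. black pixels),
#' `chl_valid` (1/0 validity mask) and `chl_out_of_range` (1 where the
#' prediction is negative). Out-of-range predictions are retained, not
#' clipped, so downstream histograms expose calibration extrapolation
#' instead of hiding it.
#'
#' @param cloud a [point_cloud()] with colors.
#' @param curve a `calibration_curve`.
#' @return the cloud with chlorophyll attributes attached.
#' @export
map_chlorophyll <- function(cloud, curve) {
  stopifnot(inherits(cloud, "point_cloud"),
            inherits(curve, "calibration_curve"))
  rn <- normalized_red(cloud$colors[, 1], cloud$colors[, 2],
                       cloud$colors[, 3], na_on_undefined = TRUE)
  chl <- predict(curve, rn)
  cloud <- set_cloud_attr(cloud, "chlorophyll", chl)
  cloud <- set_cloud_attr(cloud, "chl_valid", as.double(!is.na(chl)))
  cloud <- set_cloud_attr(cloud, "chl_out_of_range",
                          as.double(!is.na(chl) & chl < 0))
  cloud
}

#' Save / load a calibration curve as JSON
#' @param curve a `calibration_curve`.
#' @param path JSON path.
#' @return `write_curve` returns `path` invisibly; `read_curve` the curve.
#' @export
write_curve <- function(curve, path) {
  jsonlite::write_json(list(slope = curve$slope, intercept = curve$intercept,
                            r_squared = curve$r_squared, n = curve$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(obj$slope, obj$intercept,
                    r_squared = if (is.null(obj$r_squared)) NA_real_ else obj$r_squared,
                    n = if (is.null(obj$n)) 0L else obj$n)
}
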