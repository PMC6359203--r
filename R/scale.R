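#' Reference-cube measurement
#'
#' Picked point pairs on a reference object of known dimensions (the field
#' practice is a rigid box, e.g. 13 cm x 12 cm x 9 cm, placed next to the
#' plant) used to assign metric scale — and, via an edge known to be
#' vertical, a z-up orientation — to a dimensionless photogrammetric model.
#'
#' @param point_pairs data frame (or matrix) with columns
#'   `ax, ay, az, bx, by, bz, known_cm`: model-space endpoints of each
#'   measured edge and its true length in cm.
#' @param up_edge optional length-2 list / 2 x 3 matrix of model-space
#'   points whose direction (first to second) is known to be vertical
#'   (pointing up).
#' @return an object of class `cube_measurement`.
#' @export
cube_measurement <- function(point_pairs, up_edge = NULL) {
  pp <- as.data.frame(point_pairs)
  need <- c("ax", "ay", "az", "bx", "by", "bz", "known_cm")
  if (!all(need %in% names(pp))) {
    stop("`point_pairs` needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(pp) < 1) stop("at least one point pair is required")
  if (any(pp$known_cm <= 0)) stop("known distances must be > 0")
  if (!is.null(up_edge)) {
    if (is.list(up_edge)) up_edge <- do.call(rbind, up_edge)
    up_edge <- matrix(as.numeric(up_edge), 2, 3)
  }
  structure(list(point_pairs = pp[, need], up_edge = up_edge),
            class = "cube_measurement")
}

#' Read a cube measurement from CSV or JSON
#'
#' CSV: columns `ax,ay,az,bx,by,bz,known_cm`, plus optional rows flagged
#' with a logical `up_edge` column marking the vertical edge. JSON: an
#' object `{"point_pairs": [...], "up_edge": [[x,y,z],[x,y,z]]}`.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return a [cube_measurement()].
#' @export
read_cube_measurement <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(cube_measurement(as.data.frame(obj$point_pairs), obj$up_edge))
  }
  df <- utils::read.csv(path)
  up <- NULL
  if ("up_edge" %in% names(df)) {
    flag <- as.logical(df$up_edge)
    if (any(flag)) {
      r <- df[which(flag)[1], ]
      up <- rbind(c(r$ax, r$ay, r$az), c(r$bx, r$by, r$bz))
    }
    df <- df[!flag, , drop = FALSE]
  }
  cube_measurement(df, up)
}

#' Estimate the model-to-world similarity transform from a reference cube
#'
#' The scale factor (cm per model unit) is the unweighted arithmetic mean,
#' over the measured edges, of known length / model length. If a vertical
#' edge is supplied, the rotation is the one about the axis perpendicular
#' to both directions that maps the edge direction onto +z (identity when
#' already aligned); otherwise identity. Translation defaults to zero.
#'
#' @param measurement a [cube_measurement()].
#' @return an object of class `scale_calibration` with fields `scale`
#'   (cm per model unit), `rotation` (3 x 3, det +1), `translation` (cm),
#'   and `per_pair_scale` diagnostics.
#' @seealso [apply_calibration()]
#' @export
estimate_scale_calibration <- function(measurement) {
  stopifnot(inherits(measurement, "cube_measurement"))
  pp <- measurement$point_pairs
  a <- as.matrix(pp[, c("ax", "ay", "az")])
  b <- as.matrix(pp[, c("bx", "by", "bz")])
  d <- sqrt(rowSums((b - a)^2))
  if (any(d <= 0)) {
    stop_phyto("degenerate measurement: model-space pair %d has zero length",
               which(d <= 0)[1], class = "degenerate_measurement_error")
  }
  scales <- pp$known_cm / d
  rot <- diag(3)
  if (!is.null(measurement$up_edge)) {
    u <- measurement$up_edge[2, ] - measurement$up_edge[1, ]
    nu <- sqrt(sum(u^2))
    if (nu <= 0) {
      stop_phyto("degenerate measurement: up edge has zero length",
                 class = "degenerate_measurement_error")
    }
    rot <- rotation_between(u / nu, c(0, 0, 1))
  }
  structure(list(scale = mean(scales), rotation = rot,
                 translation = c(0, 0, 0), per_pair_scale = scales),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration> scale=%.6g cm/unit, %s rotation\n",
              x$scale,
              if (isTRUE(all.equal(x$rotation, diag(3)))) "identity"
              else "non-trivial"))
  invisible(x)
}

#' Transform coordinates by a similarity calibration
#'
#' Low-level helper: `p' = scale * R p + t` applied row-wise.
#'
#' @param points numeric n x 3 matrix.
#' @param cal a `scale_calibration`.
#' @return transformed n x 3 matrix.
#' @export
transform_points <- function(points, cal) {
  pts <- cal$scale * (as.matrix(points) %*% t(cal$rotation))
  sweep(pts, 2, cal$translation, `+`)
}

#' Invert a similarity calibration
#'
#' @param cal a `scale_calibration`.
#' @return the `scale_calibration` whose transform undoes `cal` (so
#'   [transform_points()] with both, in either order, is the identity to
#'   floating-point precision).
#' @export
invert_calibration <- function(cal) {
  rinv <- t(cal$rotation)
  structure(list(scale = 1 / cal$scale, rotation = rinv,
                 translation = as.vector(-(rinv %*% cal$translation) / cal$scale),
                 per_pair_scale = numeric()),
            class = "scale_calibration")
}

#' Apply a scale calibration to a raw point cloud
#'
#' Rescales, rotates and translates positions into the calibrated frame
#' (cm, z-up); colors, attributes and labels are unchanged. Refusing
#' already-calibrated input prevents accidental double scaling.
#'
#' @param cloud a [point_cloud()] with `frame == "raw"`.
#' @param cal a `scale_calibration` from [estimate_scale_calibration()].
#' @return the calibrated cloud (`frame == "calibrated"`).
#' @export
apply_calibration <- function(cloud, cal) {
  stopifnot(inherits(cloud, "point_cloud"),
            inherits(cal, "scale_calibration"))
  if (cloud$frame != "raw") {
    stop_phyto("cloud is already calibrated; refusing to scale twice",
               class = "double_calibration_error")
  }
  cloud$points <- transform_points(cloud$points, cal)
  cloud$frame <- "calibrated"
  cloud
}
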