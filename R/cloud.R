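#' Colored 3D point cloud
#'
#' The central container of the package: point positions, 8-bit RGB colors,
#' optional named per-point scalar attributes (chlorophyll in ug/mm2, zenith
#' and azimuth in degrees, ...), optional integer leaf labels (0 =
#' unassigned), and a frame tag. A `"raw"` cloud is in the dimensionless
#' model units of the photogrammetric reconstruction; a `"calibrated"` cloud
#' has isotropic units of cm with the z axis pointing up (antiparallel to
#' gravity), established by [apply_calibration()].
#'
#' @param points numeric n x 3 matrix of xyz coordinates.
#' @param colors integer n x 3 matrix of RGB values in `[0, 255]`.
#' @param attributes named list of numeric per-point vectors (length n);
#'   `NA` marks points where an attribute is undefined.
#' @param leaf_labels optional integer vector of per-point leaf ids
#'   (0 = unassigned).
#' @param frame `"raw"` (model units) or `"calibrated"` (cm, z-up).
#' @return an object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), 10, 3),
#'                   matrix(100L, 10, 3), frame = "calibrated")
#' n_points(pc)
#' @export
point_cloud <- function(points, colors, attributes = list(),
                        leaf_labels = NULL, frame = c("raw", "calibrated")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must have 3 columns")
  storage.mode(points) <- "double"
  colors <- as.matrix(colors)
  if (!all(dim(colors) == c(nrow(points), 3))) {
    stop("`colors` must be an n x 3 matrix matching `points`")
  }
  if (anyNA(colors) || any(colors < 0 | colors > 255) ||
      any(colors != round(colors))) {
    stop("colors must be integers in [0, 255]")
  }
  storage.mode(colors) <- "integer"
  n <- nrow(points)
  if (length(attributes)) {
    if (is.null(names(attributes)) || any(!nzchar(names(attributes)))) {
      stop("`attributes` must be a named list")
    }
    for (nm in names(attributes)) {
      if (length(attributes[[nm]]) != n) {
        stop(sprintf("attribute '%s' has length %d, expected %d",
                     nm, length(attributes[[nm]]), n))
      }
      attributes[[nm]] <- as.double(attributes[[nm]])
    }
  }
  if (!is.null(leaf_labels)) {
    if (length(leaf_labels) != n) stop("`leaf_labels` must have length n")
    leaf_labels <- as.integer(leaf_labels)
  }
  structure(list(points = points, colors = colors,
                 attributes = attributes, leaf_labels = leaf_labels,
                 frame = frame),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, frame=%s\n", n_points(x), x$frame))
  if (length(x$attributes)) {
    cat("  attributes:", paste(names(x$attributes), collapse = ", "), "\n")
  }
  if (!is.null(x$leaf_labels)) {
    labs <- sort(unique(x$leaf_labels[x$leaf_labels != 0L]))
    cat("  leaf labels:", paste(labs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Get or set a per-point attribute
#'
#' @param cloud a [point_cloud()].
#' @param name attribute name, e.g. `"chlorophyll"`, `"zenith"`.
#' @param values numeric vector of length `n_points(cloud)`.
#' @return `cloud_attr` returns the attribute vector (or `NULL`);
#'   `set_cloud_attr` returns the modified cloud.
#' @export
cloud_attr <- function(cloud, name) cloud$attributes[[name]]

#' @rdname cloud_attr
#' @export
set_cloud_attr <- function(cloud, name, values) {
  if (length(values) != n_points(cloud)) {
    stop("attribute length must equal the number of points")
  }
  cloud$attributes[[name]] <- as.double(values)
  cloud
}

#' Concatenate point clouds
#'
#' Stacks points, colors, leaf labels and attributes of several clouds; all
#' clouds must share the frame tag. Attributes missing from some clouds are
#' padded with `NA`; leaf labels missing from some clouds are padded with 0.
#'
#' @param ... `point_cloud` objects.
#' @return a single `point_cloud`.
#' @export
combine_clouds <- function(...) {
  clouds <- list(...)
  if (length(clouds) == 1 && is.list(clouds[[1]]) &&
      !inherits(clouds[[1]], "point_cloud")) {
    clouds <- clouds[[1]]
  }
  stopifnot(length(clouds) >= 1)
  frames <- unique(vapply(clouds, `[[`, "", "frame"))
  if (length(frames) != 1) stop("cannot combine clouds with mixed frames")
  pts <- do.call(rbind, lapply(clouds, `[[`, "points"))
  cols <- do.call(rbind, lapply(clouds, `[[`, "colors"))
  anames <- unique(unlist(lapply(clouds, function(cl) names(cl$attributes))))
  attrs <- list()
  for (nm in anames) {
    attrs[[nm]] <- unlist(lapply(clouds, function(cl) {
      v <- cl$attributes[[nm]]
      if (is.null(v)) rep(NA_real_, n_points(cl)) else v
    }))
  }
  labs <- NULL
  if (any(vapply(clouds, function(cl) !is.null(cl$leaf_labels), TRUE))) {
    labs <- unlist(lapply(clouds, function(cl) {
      if (is.null(cl$leaf_labels)) rep(0L, n_points(cl)) else cl$leaf_labels
    }))
  }
  point_cloud(pts, cols, attrs, labs, frame = frames)
}
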