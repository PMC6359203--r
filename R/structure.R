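# Leaf inclination (zenith) and azimuth per point: fit a plane to the
# points inside an axis-aligned cube centered at the target point, take the
# orientation of its normal. The zenith of the normal is the leaf
# inclination angle (0 = horizontal leaf, 90 = vertical).

#' Cubic-neighborhood specification
#'
#' @param cube_side side length L of the axis-aligned neighborhood cube in
#'   cm (default 0.5 cm).
#' @param min_points minimum neighborhood size for a plane fit; smaller
#'   neighborhoods are masked, never extrapolated.
#' @param horizontal_threshold zenith (degrees) below which the azimuth of
#'   a near-horizontal normal is flagged as meaningless.
#' @return an object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(cube_side = 0.5, min_points = 10L,
                              horizontal_threshold = 1) {
  stopifnot(cube_side > 0, min_points >= 3, horizontal_threshold >= 0)
  structure(list(cube_side = cube_side, min_points = as.integer(min_points),
                 horizontal_threshold = horizontal_threshold),
            class = "neighborhood_spec")
}

# Uniform-grid spatial index with cell size L: a point's Chebyshev-L/2
# neighbors can only live in the 27 cells around its own. The query
# contract is exact equality with an exhaustive scan; the grid is purely an
# accelerator.
.grid_index <- function(points, cell) {
  ijk <- floor(sweep(points, 2, c(0, 0, 0)) / cell)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  list(cells = split(seq_len(nrow(points)), key), ijk = ijk, cell = cell)
}

.grid_candidates <- function(index, i) {
  base <- index$ijk[i, ]
  out <- vector("list", 27)
  m <- 0L
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- paste(base[1] + dx, base[2] + dy, base[3] + dz)
    hit <- index$cells[[k]]
    if (!is.null(hit)) { m <- m + 1L; out[[m]] <- hit }
  }
  unlist(out[seq_len(m)], use.names = FALSE)
}

#' Points inside the cubic neighborhood of a target point
#'
#' All cloud points within the axis-aligned cube of side `spec$cube_side`
#' centered on the target point: `|p_k - c_k| <= L/2` on every axis, with
#' a closed boundary (a point exactly at L/2 on an axis is included). The
#' target point itself is always a member.
#'
#' @param cloud a calibrated [point_cloud()] (L is in cm).
#' @param index target point index.
#' @param spec a [neighborhood_spec()].
#' @return integer vector of point indices (ascending).
#' @export
cube_neighborhood <- function(cloud, index, spec = neighborhood_spec()) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cloud$frame != "calibrated") {
    stop_phyto("cube neighborhoods need a calibrated cloud: the cube side is in cm",
               class = "uncalibrated_cloud_error")
  }
  stopifnot(index >= 1, index <= n_points(cloud))
  gi <- .grid_index(cloud$points, spec$cube_side)
  cand <- .grid_candidates(gi, index)
  half <- spec$cube_side / 2
  ctr <- cloud$points[index, ]
  d <- abs(cloud$points[cand, , drop = FALSE] -
             matrix(ctr, length(cand), 3, byrow = TRUE))
  sort(cand[d[, 1] <= half & d[, 2] <= half & d[, 3] <= half])
}

#' Orthogonal least-squares plane normal
#'
#' Unit normal of the plane minimizing summed squared perpendicular
#' distances: the eigenvector of the neighborhood covariance with the
#' smallest eigenvalue. Orthogonal (total) least squares is used instead of
#' regressing z on xy because steep leaves make the z-regression ill-posed.
#' The sign is fixed so the z component is >= 0 (up-signed normal); for an
#' exactly vertical plane (z component 0) the first nonzero of (x, y) is
#' made positive.
#'
#' @param points numeric m x 3 matrix, m >= 3, not all collinear.
#' @return unit 3-vector.
#' @export
fit_plane_normal <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) {
    stop_phyto("degenerate neighborhood: fewer than 3 points",
               class = "degenerate_neighborhood_error")
  }
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  cv <- crossprod(x) / nrow(x)
  e <- eigen(cv, symmetric = TRUE)
  # eigenvalues descending: lambda2 ~ 0 means the points are (near-)collinear
  # or coincident, so the plane normal is not identifiable
  if (e$values[1] <= 0 || e$values[2] <= e$values[1] * 1e-12) {
    stop_phyto("degenerate neighborhood: points are collinear or coincident",
               class = "degenerate_neighborhood_error")
  }
  n <- e$vectors[, 3]
  if (n[3] < 0) {
    n <- -n
  } else if (n[3] == 0) {
    lead <- if (n[1] != 0) n[1] else n[2]
    if (lead < 0) n <- -n
  }
  n / sqrt(sum(n^2))
}

#' Zenith and azimuth of a surface normal
#'
#' Zenith: angle from vertical, `acos(n_z)` in degrees, in `[0, 90]` for
#' up-signed normals — the leaf inclination angle. Azimuth: direction of
#' the normal's horizontal projection, `atan2(n_y, n_x)` mapped to
#' `[0, 360)`, measured counterclockwise from +x of the calibrated frame.
#' For near-horizontal surfaces the horizontal projection is numerically
#' meaningless; `azimuth_defined` flags zeniths below the threshold.
#'
#' @param normal unit 3-vector with non-negative z (as produced by
#'   [fit_plane_normal()]).
#' @param horizontal_threshold zenith (degrees) below which the azimuth is
#'   flagged undefined.
#' @return list with `zenith`, `azimuth` (degrees) and `azimuth_defined`.
#' @export
normal_to_angles <- function(normal, horizontal_threshold = 1) {
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6) {
    stop("`normal` must be a unit vector (tolerance 1e-6)")
  }
  if (normal[3] < -1e-6) stop("`normal` must be up-signed (z >= 0)")
  zen <- rad2deg(acos(min(1, max(-1, normal[3]))))
  az <- rad2deg(atan2(normal[2], normal[1])) %% 360
  list(zenith = zen, azimuth = az,
       azimuth_defined = zen >= horizontal_threshold)
}

#' Per-point leaf angle field
#'
#' Runs [cube_neighborhood()], [fit_plane_normal()] and
#' [normal_to_angles()] at every point of a calibrated cloud. Points whose
#' neighborhood is underpopulated (`< min_points`) or degenerate are masked
#' (`valid = FALSE`, angles `NA`). The results are also written back to the
#' cloud as attributes `zenith`, `azimuth`, `angle_valid`, `n_neighbors`
#' (retrieve the annotated cloud from the `cloud` field of the result).
#'
#' @param cloud a calibrated [point_cloud()].
#' @param spec a [neighborhood_spec()].
#' @param stride compute every `stride`-th point (default 1 = all points);
#'   skipped points are masked.
#' @return an object of class `angle_field`: per-point `zenith`, `azimuth`
#'   (degrees, `NA` where masked), `valid`, `azimuth_defined`,
#'   `n_neighbors`, plus the annotated `cloud`.
#' @export
compute_angle_field <- function(cloud, spec = neighborhood_spec(),
                                stride = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cloud$frame != "calibrated") {
    stop_phyto("angle estimation needs a calibrated cloud: the cube side is in cm",
               class = "uncalibrated_cloud_error")
  }
  n <- n_points(cloud)
  zen <- rep(NA_real_, n)
  az <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  azdef <- rep(FALSE, n)
  nn <- integer(n)
  if (n > 0) {
    gi <- .grid_index(cloud$points, spec$cube_side)
    half <- spec$cube_side / 2
    pts <- cloud$points
    for (i in seq(1L, n, by = stride)) {
      cand <- .grid_candidates(gi, i)
      ctr <- pts[i, ]
      d <- abs(pts[cand, , drop = FALSE] -
                 matrix(ctr, length(cand), 3, byrow = TRUE))
      nb <- cand[d[, 1] <= half & d[, 2] <= half & d[, 3] <= half]
      nn[i] <- length(nb)
      if (length(nb) < spec$min_points) next
      nrm <- tryCatch(fit_plane_normal(pts[nb, , drop = FALSE]),
                      phytocloud_error = function(e) NULL)
      if (is.null(nrm)) next
      ang <- normal_to_angles(nrm, spec$horizontal_threshold)
      zen[i] <- ang$zenith
      az[i] <- ang$azimuth
      azdef[i] <- ang$azimuth_defined
      valid[i] <- TRUE
    }
  }
  if (!any(valid) && n > 0) {
    warning("no point had a valid neighborhood; the angle field is fully masked")
  }
  cloud <- set_cloud_attr(cloud, "zenith", zen)
  cloud <- set_cloud_attr(cloud, "azimuth", az)
  cloud <- set_cloud_attr(cloud, "angle_valid", as.double(valid))
  cloud <- set_cloud_attr(cloud, "n_neighbors", as.double(nn))
  structure(list(zenith = zen, azimuth = az, valid = valid,
                 azimuth_defined = azdef, n_neighbors = nn,
                 spec = spec, cloud = cloud),
            class = "angle_field")
}

#' @export
print.angle_field <- function(x, ...) {
  cat(sprintf("<angle_field> %d points, %d valid (L=%.3g cm, min_points=%d)\n",
              length(x$zenith), sum(x$valid), x$spec$cube_side,
              x$spec$min_points))
  invisible(x)
}

#' Signed zenith from per-leaf orientation flags
#'
#' A plane fit cannot tell a leaf's top surface from its bottom, so
#' downward-inclined leaves are distinguished by a per-leaf flag: the
#' zenith of every point in a leaf flagged `"down"` is negated, giving a
#' signed inclination in `[-90, 90]` for time-series plots.
#'
#' @param field an [compute_angle_field()] result whose cloud has leaf
#'   labels.
#' @param leaf_orientation named character vector or list, one `"up"` or
#'   `"down"` per leaf label (names are the labels).
#' @return the `angle_field` with a `signed_zenith` component added (and a
#'   `signed_zenith` attribute on the embedded cloud).
#' @export
apply_leaf_sign <- function(field, leaf_orientation) {
  stopifnot(inherits(field, "angle_field"))
  labs <- field$cloud$leaf_labels
  if (is.null(labs)) stop("cloud has no leaf labels")
  ori <- unlist(leaf_orientation)
  if (!all(ori %in% c("up", "down"))) {
    stop("orientation flags must be 'up' or 'down'")
  }
  flag_labels <- as.integer(names(ori))
  missing <- setdiff(flag_labels, unique(labs))
  if (length(missing)) {
    stop_phyto("orientation flag for label(s) absent from the cloud: %s",
               paste(missing, collapse = ", "),
               class = "unknown_label_error")
  }
  sign <- rep(1, length(labs))
  for (lab in flag_labels[ori == "down"]) sign[labs == lab] <- -1
  sz <- sign * field$zenith
  field$signed_zenith <- sz
  field$cloud <- set_cloud_attr(field$cloud, "signed_zenith", sz)
  field
}
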