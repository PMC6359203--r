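# Internal numerics shared across modules.

DEG <- 180 / pi

deg2rad <- function(x) x / DEG
rad2deg <- function(x) x * DEG

#' Circular mean of angles in degrees
#'
#' Mean direction computed by vector averaging, so angles straddling the
#' 0/360 wrap (e.g. 350 and 10) average to 0, not 180. Used for all azimuth
#' summaries.
#'
#' @param x angles in degrees.
#' @param na.rm drop missing values first.
#' @return mean direction in degrees in `[0, 360)`; `NA` if no finite input
#'   or the resultant vector has zero length (perfectly balanced directions).
#' @export
circular_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0 || anyNA(x)) return(NA_real_)
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  r <- (rad2deg(atan2(s, c))) %% 360
  if (360 - r < 1e-9) 0 else r
}

# Circular standard deviation in degrees: sqrt(-2 log Rbar).
circular_sd <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0 || anyNA(x)) return(NA_real_)
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  r <- min(1, sqrt(s^2 + c^2))
  if (r <= 0) return(NA_real_)
  rad2deg(sqrt(-2 * log(r)))
}

# Smallest absolute angular difference in degrees (circular metric).
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Rotation matrix about z by `deg` degrees (counterclockwise looking down +z).
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# Rodrigues rotation taking unit vector `from` onto unit vector `to`,
# rotating about the axis perpendicular to both. Degenerate antiparallel
# case: 180 degrees about an arbitrary perpendicular axis.
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(from * to)
  if (s < 1e-15) {
    if (c_ > 0) return(diag(3))
    # antiparallel: pick any axis perpendicular to `from`
    ref <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(from[2] * ref[3] - from[3] * ref[2],
            from[3] * ref[1] - from[1] * ref[3],
            from[1] * ref[2] - from[2] * ref[1])
    ax <- ax / sqrt(sum(ax^2))
    return(2 * tcrossprod(ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

stop_phyto <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "phytocloud_error")))
}
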