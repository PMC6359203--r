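# Independent oracles used across tests. These deliberately avoid the code
# paths they check: exhaustive scans instead of the grid index, stats::lm
# instead of the package's moment-formula OLS, hand-computed ranks instead
# of stats::kruskal.test.

# Exhaustive O(n) cubic-neighborhood scan (closed boundary).
scan_neighborhood <- function(points, i, L) {
  d <- abs(sweep(points, 2, points[i, ]))
  which(d[, 1] <= L / 2 & d[, 2] <= L / 2 & d[, 3] <= L / 2)
}

# Brute-force LOOCV: n separate stats::lm refits.
lm_loocv_mae <- function(x, y) {
  n <- length(x)
  err <- vapply(seq_len(n), function(i) {
    fit <- stats::lm(y[-i] ~ x[-i])
    abs(y[i] - (coef(fit)[1] + coef(fit)[2] * x[i]))
  }, 0)
  mean(err)
}

# Kruskal-Wallis H from first principles (midranks, tie correction).
kw_h_oracle <- function(groups) {
  all_v <- unlist(groups)
  r <- rank(all_v)
  n <- length(all_v)
  sizes <- lengths(groups)
  idx <- split(seq_len(n), rep(seq_along(groups), sizes))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(idx, function(ii) sum(r[ii])^2 / length(ii), 0)) -
    3 * (n + 1)
  ties <- table(all_v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Random colored cloud in a box of the given extent (cm, calibrated).
random_cloud <- function(n, extent = 5, seed = 1L) {
  withr::with_seed(seed, {
    point_cloud(matrix(stats::runif(3 * n, -extent, extent), n, 3),
                matrix(sample(0:255, 3 * n, replace = TRUE), n, 3),
                frame = "calibrated")
  })
}

default_curve <- function() calibration_curve(slope = -40, intercept = 20)

# A small noiseless planar leaf at a given orientation.
flat_leaf <- function(zenith, azimuth, seed = 1L, density = 200,
                      curvature = 0, noise = 0, long = 1.6, short = 0.8) {
  make_leaf(leaf_spec(1L, center = c(0, 0, 10), long_axis_length = long,
                      short_axis_length = short, zenith = zenith,
                      azimuth = azimuth, curvature = curvature,
                      point_density = density, noise_sigma = noise),
            default_curve(), seed = seed)
}
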