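make_rect_leaf_cloud <- function() {
  # 4 x 2 cm rectangle in the xy-plane, long axis +x, grid pitch 0.2 cm
  g <- as.matrix(expand.grid(x = seq(-2, 2, 0.2), y = seq(-1, 1, 0.2),
                             z = 0))
  point_cloud(g, matrix(90L, nrow(g), 3),
              leaf_labels = rep(1L, nrow(g)), frame = "calibrated")
}

test_that("region anchors sit at the centroid and across-blade extremes", {
  pc <- make_rect_leaf_cloud()
  regs <- locate_regions(pc, 1, radius = 0.25)
  expect_equal(unname(pc$points[regs$centroid$anchor_index, ]), c(0, 0, 0))
  expect_equal(unname(pc$points[regs$left_edge$anchor_index, 2]), -1)
  expect_equal(unname(pc$points[regs$right_edge$anchor_index, 2]), 1)
  # memberships equal an exhaustive distance scan
  for (reg in regs) {
    anchor <- pc$points[reg$anchor_index, ]
    d <- sqrt(rowSums(sweep(pc$points, 2, anchor)^2))
    expect_identical(reg$point_indices, which(d <= 0.25))
  }
  # a radius larger than the leaf saturates all three regions
  sat <- locate_regions(pc, 1, radius = 10)
  for (reg in sat) {
    expect_identical(reg$point_indices, which(pc$leaf_labels == 1L))
  }
  expect_error(locate_regions(pc, 7), class = "unknown_label_error")
})

test_that("degenerate (coincident) leaves are refused", {
  pc <- point_cloud(matrix(1, 5, 3), matrix(0L, 5, 3),
                    leaf_labels = rep(2L, 5), frame = "calibrated")
  expect_error(locate_regions(pc, 2), class = "degenerate_leaf_error")
})

test_that("leaf histograms conserve counts and average the valid points", {
  pc <- make_rect_leaf_cloud()
  pc <- set_cloud_attr(pc, "chlorophyll", rep(4.2, n_points(pc)))
  h <- leaf_histogram(pc, 1, "chlorophyll")
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$mean, 4.2)
  expect_equal(sum(h$counts), n_points(pc))
  # NA values are excluded from both counts and mean
  vals <- c(rep(NA_real_, 10), runif(n_points(pc) - 10, 10, 30))
  pc <- set_cloud_attr(pc, "zenith", vals)
  h2 <- leaf_histogram(pc, 1, "zenith")
  expect_equal(sum(h2$counts), n_points(pc) - 10)
  expect_equal(h2$mean, mean(vals, na.rm = TRUE))
  expect_true(all(diff(h2$bin_edges) > 0))
  df <- histogram_df(h2)
  expect_equal(sum(df$count), h2$n)
  expect_error(leaf_histogram(pc, 1, "azimuth"),
               class = "missing_attribute_error")
})

test_that("azimuth summaries are circular", {
  expect_equal(circular_mean(c(350, 10)), 0)
  expect_equal(circular_mean(c(80, 100)), 90)
  pc <- make_rect_leaf_cloud()
  wrap <- rep(c(355, 5), length.out = n_points(pc))
  pc <- set_cloud_attr(pc, "azimuth", wrap)
  h <- leaf_histogram(pc, 1, "azimuth")
  expect_lt(circ_diff(h$mean, circular_mean(wrap)), 1e-9)
})

test_that("a synthetic leaf histogram reproduces the imposed mean zenith", {
  lf <- flat_leaf(zenith = 33.9, azimuth = 120, seed = 40, density = 400,
                  noise = 0.02, long = 2, short = 1)
  fld <- compute_angle_field(lf$cloud)
  h <- leaf_histogram(fld$cloud, 1, "zenith")
  expect_lt(abs(h$mean - 33.9), 1)
})

test_that("one-day series equals direct region means and days sort stably", {
  preset <- water_stress_scenario()
  sim <- make_stress_timeseries(
    list(leaf_spec(1, zenith = 30, azimuth = 90, chl_base = 12,
                   long_axis_length = 2, short_axis_length = 1)),
    stress_scenario(3, data.frame(day = c(1, 3), leaf = 1,
                                  chl_delta = c(0, -5),
                                  zenith_delta = c(0, 8),
                                  azimuth_delta = c(0, 30))),
    preset$curve, seed = 6)
  clouds <- lapply(sim$clouds, function(cl) {
    cl <- map_chlorophyll(cl, preset$curve)
    compute_angle_field(cl)$cloud
  })
  s1 <- build_series(clouds[1])
  regs <- locate_regions(clouds[[1]], 1, 0.25)
  direct <- mean(cloud_attr(clouds[[1]], "chlorophyll")[
    regs$centroid$point_indices], na.rm = TRUE)
  got <- s1[s1$region == "centroid" & s1$quantity == "chlorophyll", ]
  expect_equal(got$mean, direct)
  expect_equal(nrow(s1), 9)     # 3 regions x 3 quantities, one day
  # permuting the day order of inputs gives identical sorted output
  s_fwd <- build_series(clouds, days = 1:3)
  s_rev <- build_series(rev(clouds), days = 3:1)
  expect_equal(s_fwd, s_rev)
  # the programmed trends appear in the recovered day means
  chl <- s_fwd[s_fwd$quantity == "chlorophyll" & s_fwd$region == "centroid", ]
  expect_true(all(diff(chl$mean[order(chl$day)]) < 0))
})

test_that("compare_days matches a first-principles Kruskal-Wallis H", {
  withr::with_seed(10, {
    null_days <- rep(list(c(1, 2, 2, 3, 4, 5, 5, 6)), 3)
    nt <- compare_days(null_days)
    expect_lt(nt$statistic, 1e-9)
    expect_gt(nt$p_value, 0.99)
    # strong separation is detected
    sep <- list(day1 = rnorm(100, 0, 1), day5 = rnorm(100, 10, 1))
    expect_lt(compare_days(sep)$p_value, 0.05)
    # H equals the rank-based oracle, ties included
    g <- list(day1 = c(1.2, 3.4, 3.4, 2.2, 5.1),
              day2 = c(2.2, 6.7, 8.1, 3.4))
    expect_equal(compare_days(g)$statistic, kw_h_oracle(g),
                 tolerance = 1e-12)
    expect_equal(compare_days(g)$df, 1)
    # welch option returns a finite alternative statistic
    expect_true(is.finite(compare_days(sep, method = "welch")$statistic))
    expect_error(compare_days(list(day1 = 1:5, day9 = 2)), "day9",
                 class = "underpowered_day_error")
  })
})
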