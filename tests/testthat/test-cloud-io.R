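test_that("a hand-written ascii PLY round-trips colors bit-exactly", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header",
               "0 0 0 255 0 0", "1 0 0 0 255 0", "0 1 0 0 0 255"), f)
  pc <- read_ply(f)
  expect_equal(n_points(pc), 3)
  expect_identical(pc$colors,
                   matrix(c(255L, 0L, 0L, 0L, 255L, 0L, 0L, 0L, 255L),
                          3, 3, byrow = TRUE))
  expect_identical(pc$frame, "raw")
})

test_that("write/read round trip is lossless for both formats", {
  pc <- random_cloud(40, seed = 7)
  pc <- set_cloud_attr(pc, "chlorophyll", c(NA, runif(39)))
  pc$leaf_labels <- rep(c(1L, 2L), 20)
  for (fmt in c("ascii", "binary_little_endian")) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_ply(pc, f, format = fmt)
    back <- read_ply(f, frame = "calibrated")
    expect_lt(max(abs(back$points - pc$points)), 1e-6)
    expect_identical(back$colors, pc$colors)
    expect_identical(back$leaf_labels, pc$leaf_labels)
    chl <- cloud_attr(back, "chlorophyll")
    expect_true(is.na(chl[1]))          # NA survives as NaN payload
    expect_lt(max(abs(chl[-1] - cloud_attr(pc, "chlorophyll")[-1])), 1e-6)
  }
})

test_that("ascii and binary outputs of the same cloud re-read equal", {
  pc <- random_cloud(25, seed = 3)
  fa <- withr::local_tempfile(fileext = ".ply")
  fb <- withr::local_tempfile(fileext = ".ply")
  write_ply(pc, fa, "ascii")
  write_ply(pc, fb, "binary_little_endian")
  a <- read_ply(fa); b <- read_ply(fb)
  expect_equal(a$points, b$points, tolerance = 1e-12)
  expect_identical(a$colors, b$colors)
})

test_that("an empty cloud writes a valid PLY with vertex count 0", {
  pc <- point_cloud(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(pc, f)
  expect_equal(n_points(read_ply(f)), 0)
})

test_that("colorless and malformed PLY files raise named errors", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0"), f)
  expect_error(read_ply(f), "colorless", class = "colorless_cloud_error")

  g <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 5",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header", "0 0 0 1 2 3"), g)
  expect_error(read_ply(g), "vertex", class = "ply_parse_error")
  h <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not a ply"), h)
  expect_error(read_ply(h), class = "ply_parse_error")
})

test_that("scale is the mean of per-edge known/model ratios", {
  m1 <- cube_measurement(data.frame(ax = 0, ay = 0, az = 0, bx = 1, by = 0,
                                    bz = 0, known_cm = 13))
  expect_equal(estimate_scale_calibration(m1)$scale, 13)
  m3 <- cube_measurement(data.frame(ax = 0, ay = 0, az = 0,
                                    bx = c(1, 0, 0), by = c(0, 1, 0),
                                    bz = c(0, 0, 1),
                                    known_cm = c(13, 12, 9)))
  expect_equal(estimate_scale_calibration(m3)$scale, (13 + 12 + 9) / 3)
  expect_error(estimate_scale_calibration(
    cube_measurement(data.frame(ax = 0, ay = 0, az = 0, bx = 0, by = 0,
                                bz = 0, known_cm = 13))),
    class = "degenerate_measurement_error")
})

test_that("the up edge fixes the rotation (identity when aligned)", {
  pp <- data.frame(ax = 0, ay = 0, az = 0, bx = 1, by = 0, bz = 0,
                   known_cm = 13)
  cal <- estimate_scale_calibration(
    cube_measurement(pp, up_edge = rbind(c(0, 0, 0), c(0, 0, 2))))
  expect_equal(cal$rotation, diag(3))
  # a tilted up edge is mapped onto +z by a proper rotation
  u <- c(0.3, -0.4, 0.866)
  cal2 <- estimate_scale_calibration(
    cube_measurement(pp, up_edge = rbind(c(0, 0, 0), u)))
  expect_equal(det(cal2$rotation), 1, tolerance = 1e-12)
  expect_equal(as.vector(cal2$rotation %*% (u / sqrt(sum(u^2)))),
               c(0, 0, 1), tolerance = 1e-12)
})

test_that("apply_calibration is a similarity transform and refuses double application", {
  pc <- random_cloud(30, seed = 5)
  pc$frame <- "raw"
  cal <- estimate_scale_calibration(cube_measurement(
    data.frame(ax = 0, ay = 0, az = 0, bx = 1, by = 0, bz = 0,
               known_cm = 2),
    up_edge = rbind(c(0, 0, 0), c(0.2, 0.1, 0.97))))
  out <- apply_calibration(pc, cal)
  expect_identical(out$frame, "calibrated")
  expect_identical(out$colors, pc$colors)
  # simple point check: scale 2, identity rotation
  cal_id <- estimate_scale_calibration(cube_measurement(
    data.frame(ax = 0, ay = 0, az = 0, bx = 1, by = 0, bz = 0,
               known_cm = 2)))
  expect_equal(transform_points(rbind(c(1, 1, 1)), cal_id),
               rbind(c(2, 2, 2)))
  # pairwise distances scale uniformly
  d0 <- as.matrix(dist(pc$points)); d1 <- as.matrix(dist(out$points))
  expect_equal(d1, cal$scale * d0, tolerance = 1e-9)
  # inverse restores coordinates
  back <- transform_points(out$points, invert_calibration(cal))
  expect_lt(max(abs(back - pc$points)), 1e-9)
  expect_error(apply_calibration(out, cal),
               class = "double_calibration_error")
})

test_that("cube measurements survive the CSV round trip", {
  cube <- make_reference_cube(seed = 2, true_scale = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  pp <- cube$measurement$point_pairs
  pp$up_edge <- FALSE
  up <- cube$measurement$up_edge
  pp <- rbind(pp, data.frame(ax = up[1, 1], ay = up[1, 2], az = up[1, 3],
                             bx = up[2, 1], by = up[2, 2], bz = up[2, 3],
                             known_cm = NA, up_edge = TRUE))
  write.csv(pp, f, row.names = FALSE)
  m <- read_cube_measurement(f)
  expect_equal(estimate_scale_calibration(m)$scale, 3, tolerance = 1e-9)
})
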