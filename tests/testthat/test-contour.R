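test_that("boundary tracing recovers a filled rectangle", {
  img <- matrix(0, 40, 50)
  img[11:30, 11:40] <- 255
  o <- extract_outline(img, threshold = 128)
  # pixel-center polygon of a 20 x 30 block encloses 19 x 29 units
  expect_equal(outline_area(o), 19 * 29)
  expect_true(is_simple_outline(o))
  expect_gt(otoshape:::signed_area(o$x, o$y), 0)
})

test_that("traced disk matches the analytic circle after smoothing", {
  n <- 121
  ctr <- 61
  img <- matrix(0, n, n)
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  img[d2 <= 50^2] <- 255
  o <- extract_outline(img, 128)
  sm <- smooth_outline(o, 10)
  expect_equal(outline_perimeter(sm), 2 * pi * 50, tolerance = 0.02)
  expect_equal(outline_area(sm), pi * 50^2, tolerance = 0.03)
})

test_that("extraction keeps the largest component and flags edge cases", {
  img <- matrix(0, 40, 40)
  img[5:10, 5:10] <- 255       # small blob
  img[15:35, 15:35] <- 255     # large blob
  o <- extract_outline(img, 128)
  expect_equal(outline_area(o), 20 * 20)
  expect_error(extract_outline(matrix(0, 10, 10), 128), "empty mask")
  img_border <- matrix(0, 10, 10)
  img_border[1:5, 3:7] <- 255
  expect_warning(extract_outline(img_border, 128), "border")
})

test_that("otsu threshold separates a bimodal image", {
  img <- matrix(30, 50, 50)
  img[20:35, 20:35] <- 220
  th <- otsu_threshold(img)
  expect_gt(th, 30)
  expect_lt(th, 220)
  o <- extract_outline(img)
  expect_equal(outline_area(o), 15 * 15)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

test_that("smoothing is identity at 0 iterations and contracts toward centroid", {
  o <- random_star_polygon(32)
  expect_equal(smooth_outline(o, 0), o)
  sq <- outline(c(0, 4, 4, 0), c(0, 0, 4, 4))
  r_max <- function(o) {
    ctr <- otoshape:::point_centroid(o)
    max(sqrt((o$x - ctr[1])^2 + (o$y - ctr[2])^2))
  }
  radii <- vapply(c(0, 5, 20, 80), function(k) r_max(smooth_outline(sq, k)),
                  numeric(1))
  expect_true(all(diff(radii) <= 1e-12))
  expect_lt(radii[4], 0.1 * radii[1])
})

test_that("smoothing never increases the perimeter of convex outlines", {
  set.seed(31)
  for (i in 1:100) {
    k <- sample(6:14, 1)
    pts <- cbind(stats::rnorm(k), stats::rnorm(k))
    hull <- grDevices::chull(pts)
    o <- outline(pts[hull, 1], pts[hull, 2])
    per <- vapply(0:4, function(it) outline_perimeter(smooth_outline(o, it)),
                  numeric(1))
    expect_true(all(diff(per) <= 1e-10))
  }
})

test_that("resampling centers, normalizes size, and is scale invariant", {
  o <- random_star_polygon(40)
  r <- resample_and_center(o, 256)
  expect_equal(nrow(r), 256)
  ctr <- otoshape:::point_centroid(r)
  expect_lt(sqrt(sum(ctr^2)), 1e-9)
  expect_equal(otoshape:::centroid_size(r), 1, tolerance = 1e-12)
  # equal arc-length spacing (checked on a smooth outline, where equal
  # arc steps imply near-equal chords)
  rs <- resample_and_center(ellipse_outline(2, 1, 512), 256)
  seg <- sqrt(diff(c(rs$x, rs$x[1]))^2 + diff(c(rs$y, rs$y[1]))^2)
  expect_lt(diff(range(seg)) / mean(seg), 0.05)
  r2 <- resample_and_center(outline(o$x * 7.3, o$y * 7.3), 256)
  expect_equal(r$x, r2$x, tolerance = 1e-9)
  expect_equal(r$y, r2$y, tolerance = 1e-9)
  # unit circle stays a unit-radius circle after normalization
  circ <- resample_and_center(ellipse_outline(5, 5, 512), 256)
  expect_equal(sqrt(circ$x^2 + circ$y^2), rep(1, 256), tolerance = 1e-6)
  expect_error(resample_and_center(o, 8), "n_points")
})

test_that("morphometrics match analytic square and ellipse", {
  sq <- measure_morphometrics(outline(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(sq$area, 1)
  expect_equal(sq$perimeter, 4)
  expect_equal(sq$feret_length, sqrt(2), tolerance = 1e-9)
  expect_equal(sq$feret_width, 1, tolerance = 1e-4)
  expect_equal(sq$major_axis, sqrt(2), tolerance = 1e-4)
  expect_equal(sq$minor_axis, sqrt(2), tolerance = 1e-4)
  el <- measure_morphometrics(ellipse_outline(2, 1, 1024))
  expect_equal(el$feret_length, 4, tolerance = 0.005)
  expect_equal(el$feret_width, 2, tolerance = 0.005)
  expect_equal(el$major_axis, 4, tolerance = 0.005)
  expect_equal(el$minor_axis, 2, tolerance = 0.005)
  expect_equal(el$area, 2 * pi, tolerance = 0.005)
  # scale propagates linearly / quadratically
  sc <- measure_morphometrics(ellipse_outline(2, 1, 1024), scale = 0.5)
  expect_equal(sc$feret_length, 2, tolerance = 0.005)
  expect_equal(sc$area, pi / 2, tolerance = 0.005)
})

test_that("morphometrics reject degenerate and self-crossing inputs", {
  expect_error(outline(c(0, 1), c(0, 0)))
  bowtie <- outline(c(0, 1, 0, 1), c(0, 1, 1, 0), enforce_ccw = FALSE)
  expect_error(measure_morphometrics(bowtie), "self-intersecting")
})

test_that("feret length equals brute-force max pairwise distance", {
  set.seed(33)
  for (i in 1:20) {
    o <- random_star_polygon(n = sample(10:50, 1))
    m <- measure_morphometrics(o, check_simple = FALSE)
    d <- as.matrix(stats::dist(cbind(o$x, o$y)))
    expect_equal(m$feret_length, max(d), tolerance = 1e-12)
    expect_lte(m$feret_width, m$feret_length)
    expect_lte(m$minor_axis, m$major_axis + 1e-9)
  }
})

test_that("feret measures and area are rotation invariant", {
  set.seed(34)
  o <- random_star_polygon(40)
  m0 <- measure_morphometrics(o, check_simple = FALSE)
  for (th in c(0.3, 1.1, 2.5)) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    xy <- as.matrix(cbind(o$x, o$y)) %*% t(R)
    m <- measure_morphometrics(outline(xy[, 1], xy[, 2]), check_simple = FALSE)
    expect_equal(m$feret_length, m0$feret_length, tolerance = 0.005)
    expect_equal(m$feret_width, m0$feret_width, tolerance = 0.005)
    expect_equal(m$area, m0$area, tolerance = 1e-9)
  }
})
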