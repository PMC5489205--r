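test_that("an ellipse is represented by its first harmonic alone", {
  e <- efa_forward(ellipse_outline(2, 1, 256), 12)
  expect_equal(unname(abs(e$coef[1, "a"])), 2, tolerance = 1e-3)
  expect_equal(unname(abs(e$coef[1, "d"])), 1, tolerance = 1e-3)
  mag1 <- sqrt(sum(e$coef[1, ]^2))
  expect_lt(max(abs(e$coef[-1, ])), 1e-6 * mag1)
  pw <- rowSums(e$coef^2) / 2
  expect_lt(sum(pw[-1]) / sum(pw), 1e-6)
})

test_that("forward/inverse round trip reproduces the outline", {
  set.seed(41)
  for (lab in c("comb", "hatchet", "mixed")) {
    o <- resample_and_center(gen_outline(shape_phenotype(lab), 100, 256), 256)
    rec <- efa_inverse(efa_forward(o, 128), 256)
    rms <- sqrt(mean((rec$x - o$x)^2 + (rec$y - o$y)^2))
    expect_lt(rms, 1e-3)
  }
})

test_that("reconstruction error is non-increasing in harmonic count", {
  set.seed(42)
  for (i in 1:10) {
    o <- resample_and_center(random_star_polygon(64), 128)
    rms <- vapply(c(2, 4, 8, 16, 32, 64), function(H) {
      rec <- efa_inverse(efa_forward(o, H), 128)
      sqrt(mean((rec$x - o$x)^2 + (rec$y - o$y)^2))
    }, numeric(1))
    expect_true(all(diff(rms) <= 1e-9))
    # sharp polygon corners retain content at the sampling limit, so the
    # floor is relative: the full-harmonic error is far below the coarse one
    expect_lt(rms[length(rms)], 0.1 * rms[1])
  }
})

test_that("traversal direction flips the sign of the first-harmonic area", {
  tri <- outline(c(0, 1, 0.5), c(0, 0, 1), enforce_ccw = FALSE)
  tri_cw <- outline(rev(tri$x), rev(tri$y), enforce_ccw = FALSE)
  a_ccw <- otoshape:::first_harmonic_area(
    efa_forward(resample_and_center(tri, 96), 8))
  a_cw <- otoshape:::first_harmonic_area(
    efa_forward(resample_and_center(tri_cw, 96), 8))
  expect_gt(a_ccw, 0)
  expect_lt(a_cw, 0)
  expect_equal(a_ccw, -a_cw, tolerance = 1e-3)
})

test_that("total harmonic power matches the Parseval sum on the curve", {
  set.seed(43)
  for (i in 1:5) {
    o <- resample_and_center(random_star_polygon(48), 256)
    co <- efa_forward(o, 128)$coef
    expect_equal(sum(rowSums(co^2) / 2), mean(o$x^2 + o$y^2),
                 tolerance = 0.01)
  }
})

test_that("normalization removes rotation, scale, and starting point", {
  set.seed(44)
  for (i in 1:12) {
    lab <- sample(c("comb", "hatchet", "mixed"), 1)
    o <- resample_and_center(
      gen_outline(shape_phenotype(lab), 100, 256, seed = i, jitter_sd = 0.01),
      256)
    ref <- efa_normalize(efa_forward(o, 12))
    th <- stats::runif(1, 0, 2 * pi)
    sc <- exp(stats::rnorm(1, 0, 1))
    shift <- sample(nrow(o), 1)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    xy <- as.matrix(cbind(o$x, o$y)) %*% t(R) * sc
    idx <- c(shift:nrow(o), seq_len(shift - 1))
    alt <- efa_normalize(efa_forward(
      outline(xy[idx, 1], xy[idx, 2], enforce_ccw = FALSE), 12))
    expect_lt(max(abs(ref$coef - alt$coef)), 1e-6)
  }
})

test_that("normalization fixes three descriptors and is idempotent", {
  o <- resample_and_center(gen_outline(shape_phenotype("comb"), 80, 256), 256)
  nrm <- efa_normalize(efa_forward(o, 12))
  expect_equal(nrm$coef[1, c("a", "b", "c")], c(a = 1, b = 0, c = 0))
  expect_gt(nrm$coef[1, "d"], 0)
  expect_equal(nrm$dropped, c("a1", "b1", "c1"))
  expect_length(otoshape:::free_descriptors(nrm), 4 * 12 - 3)
  again <- efa_normalize(nrm)
  expect_lt(max(abs(again$coef - nrm$coef)), 1e-9)
})

test_that("normalization enforces counterclockwise orientation (d1 > 0)", {
  o <- resample_and_center(gen_outline(shape_phenotype("hatchet"), 80, 256), 256)
  ccw <- efa_normalize(efa_forward(o, 12))
  cw <- efa_normalize(efa_forward(
    outline(rev(o$x), rev(o$y), enforce_ccw = FALSE), 12))
  expect_gt(cw$coef[1, "d"], 0)
  expect_equal(cw$coef[1, "d"], ccw$coef[1, "d"], tolerance = 1e-3)
})

test_that("harmonic selection follows cumulative power", {
  ellipses <- lapply(seq(0.2, 0.8, length.out = 6), function(r) {
    resample_and_center(ellipse_outline(1, r, 256), 256)
  })
  expect_equal(choose_harmonics(ellipses, 0.99), 1L)
  set.seed(45)
  combs <- lapply(1:6, function(i) {
    gen_outline(shape_phenotype("comb", crenulation_freq = 10L), 100, 256,
                seed = i, jitter_sd = 0.002)
  })
  expect_gte(choose_harmonics(combs, 0.9999), 10L)
  # threshold monotonicity
  expect_gte(choose_harmonics(combs, 0.999), choose_harmonics(combs, 0.99))
  expect_error(choose_harmonics(list(), 0.99), "no outlines")
})

test_that("inverse transform handles single-harmonic and degenerate input", {
  o <- resample_and_center(gen_outline(shape_phenotype("comb"), 80, 256), 256)
  e <- efa_forward(o, 12)
  e1 <- e
  e1$coef[-1, ] <- 0
  rec <- efa_inverse(e1, 256)
  pw <- rowSums(efa_forward(rec, 12)$coef^2) / 2
  expect_lt(sum(pw[-1]) / sum(pw), 1e-9)
  ez <- e
  ez$coef[] <- 0
  ez$a0 <- 0
  ez$c0 <- 0
  expect_warning(efa_inverse(ez, 64), "degenerates to a point")
})

test_that("harmonic count beyond the sampling limit is rejected", {
  o <- ellipse_outline(1, 1, 64)
  expect_error(efa_forward(o, 33), "floor")
  expect_silent(efa_forward(o, 32))
})

test_that("group mean shapes behave as descriptor averages", {
  set.seed(46)
  ds <- gen_dataset(synth_config(n_per_group = 8, seed = 17,
                                 allometry_slopes = c(d2 = 0)))
  dm <- dataset_descriptors(ds)
  one <- dm[dm$label == "comb", ][1, ]
  ms <- group_mean_shape(one, "comb")
  rec <- efa_inverse(otoshape:::efd_from_free(
    as.numeric(one[otoshape:::descriptor_cols(one)]), 12), 256)
  expect_equal(ms$x, rec$x)
  expect_equal(ms$y, rec$y)
  expect_error(group_mean_shape(dm, "unknown"), "no specimens")
  # hatchet mean shape has a narrower end than the comb mean shape
  end_width <- function(o, frac = 0.15) {
    xr <- range(o$x)
    w <- function(lo, hi) diff(range(o$y[o$x >= lo & o$x <= hi]))
    min(w(xr[1], xr[1] + frac * diff(xr)), w(xr[2] - frac * diff(xr), xr[2]))
  }
  expect_lt(end_width(group_mean_shape(dm, "hatchet")),
            end_width(group_mean_shape(dm, "comb")))
})

test_that("mirror-symmetric specimens average to a symmetric mean shape", {
  o <- resample_and_center(gen_outline(shape_phenotype("hatchet"), 80, 256), 256)
  mirror <- outline(o$x, -o$y)
  e1 <- efa_normalize(efa_forward(o, 12))
  e2 <- efa_normalize(efa_forward(resample_and_center(mirror, 256), 12))
  dm <- make_dm(rbind(otoshape:::free_descriptors(e1),
                      otoshape:::free_descriptors(e2)),
                label = "comb")
  ms <- group_mean_shape(dm, "comb")
  # the mean shape should be its own mirror image: reflecting it and
  # renormalizing must reproduce the same descriptors
  v_ms <- otoshape:::free_descriptors(
    efa_normalize(efa_forward(resample_and_center(ms, 256), 12)))
  v_ref <- otoshape:::free_descriptors(
    efa_normalize(efa_forward(resample_and_center(outline(ms$x, -ms$y), 256), 12)))
  expect_lt(max(abs(v_ms - v_ref)), 1e-3)
})
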