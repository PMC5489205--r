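test_that("PCA recovers a dominant constructed axis", {
  set.seed(61)
  n <- 100
  z <- stats::rnorm(n, 0, 5)
  Y <- cbind(z, 0.5 * z, matrix(stats::rnorm(n * 3, 0, 0.1), n))
  res <- pca_scores(make_dm(Y, "comb"))
  expect_gt(res$variance_fraction[1], 0.9)
  # scores are uncorrelated across components
  sc <- as.matrix(res$scores[, -(1:2)])
  cv <- stats::cov(sc)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-9)
  expect_equal(sum(res$variance_fraction), 1)
})

test_that("PCA variances equal brute-force covariance eigenvalues", {
  set.seed(62)
  Y <- matrix(stats::rnorm(20), 5, 4)
  res <- pca_scores(make_dm(Y, "comb"))
  ev <- eigen(stats::cov(Y), symmetric = TRUE)$values
  vars <- apply(as.matrix(res$scores[, -(1:2)]), 2, stats::var)
  expect_equal(unname(vars), ev[seq_along(vars)], tolerance = 1e-9)
  expect_error(pca_scores(make_dm(matrix(1, 5, 3), "comb")), "constant")
})

test_that("shape MANOVA rejects separated groups and respects preconditions", {
  set.seed(63)
  n <- 150
  lab <- rep(c("comb", "mixed", "hatchet"), each = 50)
  Y <- matrix(stats::rnorm(n * 10), n)
  Y[lab == "hatchet", 1] <- Y[lab == "hatchet", 1] + 3
  res <- manova_shape(make_dm(Y, lab))
  expect_lt(res$p_value[res$statistic == "Pillai"], 1e-6)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_error(manova_shape(make_dm(Y, "comb")), "2 shape groups")
  expect_error(
    manova_shape(make_dm(Y, c(rep("comb", n - 1), "hatchet"))),
    "more than one specimen")
})

test_that("permuting the labels of a separated dataset destroys significance", {
  set.seed(64)
  n <- 90
  lab <- rep(c("comb", "mixed", "hatchet"), each = 30)
  Y <- matrix(stats::rnorm(n * 5), n)
  Y[, 1] <- Y[, 1] + c(comb = 0, mixed = 2, hatchet = 4)[lab]
  expect_lt(manova_shape(make_dm(Y, lab))$p_value[1], 1e-6)
  perm_p <- replicate(50, {
    manova_shape(make_dm(Y, sample(lab)))$p_value[1]
  })
  expect_gt(mean(perm_p > 0.05), 0.7)
})

test_that("LDA separates disjoint clouds perfectly and honors preconditions", {
  set.seed(65)
  Y <- rbind(matrix(stats::rnorm(40 * 3, 0, 0.2), 40),
             matrix(stats::rnorm(40 * 3, 5, 0.2), 40))
  dm <- make_dm(Y, rep(c("comb", "hatchet"), each = 40))
  res <- lda_loocv(dm)
  expect_equal(sum(res$confusion) - sum(diag(res$confusion)), 0)
  expect_equal(res$accuracy, 1)
  expect_equal(sum(res$confusion), 80)
  expect_error(lda_loocv(make_dm(Y, "comb")), "2 shape groups")
})

test_that("full-fit accuracy is at least the cross-validated accuracy", {
  set.seed(66)
  for (i in 1:15) {
    n <- 45
    lab <- rep(c("comb", "mixed", "hatchet"), each = 15)
    Y <- matrix(stats::rnorm(n * 6), n)
    Y[, 1] <- Y[, 1] + c(comb = 0, mixed = 0.8, hatchet = 1.6)[lab]
    dm <- make_dm(Y, lab)
    res <- lda_loocv(dm)
    fit <- otoshape:::shrunken_lda_fit(Y, factor(lab), 0,
                                       rep(1 / 3, 3))
    full_pred <- otoshape:::shrunken_lda_predict(fit, Y)$class
    expect_gte(mean(full_pred == lab), res$accuracy)
  }
})

test_that("LDA decisions are invariant to affine column rescaling", {
  set.seed(67)
  n <- 60
  lab <- rep(c("comb", "mixed", "hatchet"), each = 20)
  Y <- matrix(stats::rnorm(n * 5), n)
  Y[, 2] <- Y[, 2] + c(comb = 0, mixed = 1, hatchet = 2)[lab]
  r1 <- lda_loocv(make_dm(Y, lab))
  Y2 <- sweep(Y, 2, c(100, 0.01, 3, 7, 0.5), "*")
  Y2 <- sweep(Y2, 2, c(5, -2, 0, 1, 9), "+")
  r2 <- lda_loocv(make_dm(Y2, lab))
  expect_equal(r1$posteriors$predicted, r2$posteriors$predicted)
})

test_that("shrinkage engages on singular pooled covariance", {
  set.seed(68)
  n <- 24
  lab <- rep(c("comb", "hatchet"), each = 12)
  Y <- matrix(stats::rnorm(n * 30), n)   # p > n - groups: singular
  Y[lab == "hatchet", 1] <- Y[lab == "hatchet", 1] + 4
  dm <- make_dm(Y, lab)
  expect_error(lda_loocv(dm, shrinkage = "none"), "near-singular")
  expect_warning(res <- lda_loocv(dm, shrinkage = "auto"), "shrinkage")
  expect_gt(res$shrinkage_lambda, 0)
  expect_gt(res$accuracy, 0.9)
})

test_that("confusion summaries reproduce the published reference percentages", {
  cs <- confusion_summary(grenadier_confusion())
  expect_equal(cs$overall_percent, 59)
  per <- stats::setNames(cs$per_class$percent, cs$per_class$label)
  expect_equal(per[["hatchet"]], 69)
  expect_equal(per[["comb"]], 48)
  expect_equal(per[["mixed"]], 51)
  c2m <- cs$cells[cs$cells$visual == "comb" & cs$cells$predicted == "mixed", ]
  expect_equal(c2m$row_percent, 52)
  expect_equal(cs$overall_exact, 113 / 193)
})

test_that("confusion summaries handle identity and empty rows", {
  ident <- diag(c(5L, 7L, 9L))
  dimnames(ident) <- list(c("comb", "mixed", "hatchet"),
                          c("comb", "mixed", "hatchet"))
  expect_equal(confusion_summary(ident)$overall_percent, 100)
  zr <- ident
  zr[2, ] <- 0L
  cs <- confusion_summary(zr)
  expect_true(is.na(cs$per_class$percent[2]))
  # reporting convention: halves round away from zero
  expect_equal(otoshape:::round_half_up(c(0.5, 1.5, 2.5, -0.5)),
               c(1, 2, 3, -1))
})

test_that("mean confidence ellipses follow the closed form and 1/sqrt(n) scaling", {
  set.seed(69)
  axes <- replicate(200, {
    s <- matrix(stats::rnorm(200), 100, 2)
    e <- mean_confidence_ellipse(s, 0.90)
    c(e$semi_major, e$semi_minor)
  })
  expected <- sqrt(stats::qchisq(0.90, 2) / 100)
  expect_equal(mean(axes), expected, tolerance = 0.1)
  ratios <- replicate(100, {
    base <- matrix(stats::rnorm(2 * 60), 60, 2)
    quad <- matrix(stats::rnorm(2 * 240), 240, 2)
    mean_confidence_ellipse(base, 0.9)$semi_major /
      mean_confidence_ellipse(quad, 0.9)$semi_major
  })
  expect_equal(mean(ratios), 2, tolerance = 0.1)
  # monotone in level
  s <- matrix(stats::rnorm(60), 30, 2)
  lv <- c(0.5, 0.9, 0.99, 0.999)
  ax <- vapply(lv, function(l) mean_confidence_ellipse(s, l)$semi_major,
               numeric(1))
  expect_true(all(diff(ax) > 0))
  expect_error(mean_confidence_ellipse(s[1:2, ], 0.9), "at least 3")
})

test_that("the in-package discriminant matches MASS::lda without shrinkage", {
  set.seed(70)
  n <- 75
  lab <- rep(c("comb", "mixed", "hatchet"), each = 25)
  Y <- matrix(stats::rnorm(n * 6), n)
  Y[, 1] <- Y[, 1] + c(comb = 0, mixed = 1, hatchet = 2)[lab]
  dm <- make_dm(Y, lab)
  ours <- lda_loocv(dm)
  ref <- MASS::lda(Y, grouping = factor(lab, levels = c("comb", "mixed", "hatchet")), CV = TRUE)
  expect_equal(ours$posteriors$predicted, as.character(ref$class))
  full <- MASS::lda(Y, grouping = factor(lab))
  expect_equal(unname(ours$discriminant_fractions),
               unname(full$svd^2 / sum(full$svd^2)), tolerance = 1e-6)
})
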