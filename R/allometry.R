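#' Screen Fourier descriptors for allometric size effects
#'
#' Fits one analysis of covariance per descriptor: descriptor ~ otolith
#' Feret length + shape group, with a common (pooled within-group) length
#' slope. Descriptors whose slope differs significantly from zero at `alpha`
#' are flagged for correction.
#'
#' @param dm An `otl_descriptors` tibble with `feret_length` and `label`.
#' @param alpha Significance level of the slope test (default 0.05;
#'   `alpha = 0` flags nothing).
#' @return A tibble: `descriptor_id`, `slope`, `p_value`, `significant`.
#' @export
screen_descriptors <- function(dm, alpha = 0.05) {
  L <- dm$feret_length
  if (anyNA(L)) stop("feret_length metadata is required for the screen")
  if (stats::sd(L) == 0) stop("otolith length is constant across specimens")
  Y <- descriptor_values(dm)
  g <- factor(dm$label)
  X <- if (nlevels(g) > 1L) stats::model.matrix(~ L + g) else cbind(1, L)
  fit <- stats::lm.fit(X, Y)
  df <- nrow(X) - ncol(X)
  if (df < 1) stop("too few specimens for the ANCOVA screen")
  rss <- colSums(fit$residuals^2)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  slope <- fit$coefficients[2L, ]
  se <- sqrt(rss / df * xtx_inv[2L, 2L])
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df)
  tibble::tibble(
    descriptor_id = colnames(Y),
    slope = unname(slope),
    p_value = unname(p),
    significant = p < alpha
  )
}

#' Apply pooled-slope allometric corrections
#'
#' For every descriptor flagged significant, subtracts the pooled slope
#' times the mean-centered otolith length: `FD_A = FD_O - b * (L - mean(L))`.
#' Centering keeps corrected descriptors on their original scale; it differs
#' from subtracting `b * L` only by a per-descriptor constant, which no
#' downstream centered statistic can detect. Unflagged descriptors are
#' untouched.
#'
#' @param dm The `otl_descriptors` tibble the corrections were computed on.
#' @param corrections Output of [screen_descriptors()] on `dm`.
#' @return A corrected `otl_descriptors` tibble (same dimensions, same row
#'   order).
#' @export
correct_descriptors <- function(dm, corrections) {
  cols <- descriptor_cols(dm)
  if (!setequal(corrections$descriptor_id, cols)) {
    stop("corrections do not match the descriptor columns of `dm`")
  }
  lc <- dm$feret_length - mean(dm$feret_length)
  out <- dm
  apply_rows <- corrections[corrections$significant, , drop = FALSE]
  for (i in seq_len(nrow(apply_rows))) {
    id <- apply_rows$descriptor_id[i]
    out[[id]] <- out[[id]] - apply_rows$slope[i] * lc
  }
  out
}

#' Test overall size and age effects on the descriptor set
#'
#' One-predictor MANOVAs of the full descriptor matrix on fish age and on
#' otolith Feret length, reported with both Pillai's trace and Wilks'
#' lambda.
#'
#' @param dm An `otl_descriptors` tibble.
#' @return A tibble with columns `effect` (`age`, `length`), `statistic`
#'   (`Pillai`, `Wilks`), `value`, `approx_f`, `df1`, `df2`, `p_value`.
#' @export
test_size_age_effects <- function(dm) {
  Y <- descriptor_values(dm)
  if (nrow(Y) < ncol(Y) + 2L) {
    stop("descriptor matrix is rank deficient for MANOVA: need at least ",
         ncol(Y) + 2L, " specimens; reduce the harmonic count")
  }
  dplyr::bind_rows(
    manova_one(Y, dm$age, "age"),
    manova_one(Y, dm$feret_length, "length")
  )
}

# single-term MANOVA summary rows (Pillai + Wilks)
manova_one <- function(Y, x, effect_name) {
  if (anyNA(x)) stop("missing values in predictor '", effect_name, "'")
  fit <- stats::manova(Y ~ x)
  purrr::map_dfr(c("Pillai", "Wilks"), function(testname) {
    s <- summary(fit, test = testname)$stats
    tibble::tibble(
      effect = effect_name,
      statistic = testname,
      value = s[1, 2],
      approx_f = s[1, 3],
      df1 = s[1, 4],
      df2 = s[1, 5],
      p_value = s[1, 6]
    )
  })
}
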