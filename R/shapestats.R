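#' Principal component analysis of the descriptor matrix
#'
#' Eigendecomposition of the (column-centered, unscaled) descriptor
#' covariance. Component signs follow the convention that each component's
#' largest-magnitude loading is positive.
#'
#' @param dm An `otl_descriptors` tibble.
#' @return An object of class `otl_pca`: `scores` (tibble with
#'   `specimen_id`, `label`, `PC1..PCk`), `loadings` (matrix), and
#'   `variance_fraction`.
#' @export
pca_scores <- function(dm) {
  Y <- descriptor_values(dm)
  if (nrow(Y) < 3L) stop("PCA needs at least 3 specimens")
  if (all(apply(Y, 2, stats::sd) == 0)) stop("constant descriptor matrix")
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  scores <- dplyr::bind_cols(
    tibble::tibble(specimen_id = dm$specimen_id, label = dm$label),
    tibble::as_tibble(pc$x)
  )
  structure(
    list(scores = scores, loadings = pc$rotation,
         variance_fraction = pc$sdev^2 / sum(pc$sdev^2)),
    class = "otl_pca"
  )
}

#' @export
print.otl_pca <- function(x, ...) {
  cat(sprintf("# PCA of %d specimens, %d components\n",
              nrow(x$scores), length(x$variance_fraction)))
  cat("variance fractions:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$variance_fraction, 5)),
             collapse = " "), "...\n")
  invisible(x)
}

#' @method tidy otl_pca
#' @export
tidy.otl_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$variance_fraction),
    variance_fraction = x$variance_fraction,
    cumulative = cumsum(x$variance_fraction)
  )
}

#' One-way MANOVA of descriptors on shape category
#'
#' Tests whether the set of Fourier descriptors differs among shape groups.
#'
#' @param dm An `otl_descriptors` tibble with >= 2 groups, each with more
#'   than one specimen.
#' @return A tibble (class `otl_manova`) with `statistic` (`Pillai`,
#'   `Wilks`), `value`, `approx_f`, `df1`, `df2`, `p_value`.
#' @export
manova_shape <- function(dm) {
  g <- factor(dm$label)
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 shape groups")
  if (any(table(g) < 2L)) stop("every group needs more than one specimen")
  Y <- descriptor_values(dm)
  if (nrow(Y) <= ncol(Y) + nlevels(g)) {
    stop("too few specimens relative to descriptor count for MANOVA")
  }
  fit <- stats::manova(Y ~ g)
  out <- purrr::map_dfr(c("Pillai", "Wilks"), function(testname) {
    s <- summary(fit, test = testname)$stats
    tibble::tibble(statistic = testname, value = s[1, 2], approx_f = s[1, 3],
                   df1 = s[1, 4], df2 = s[1, 5], p_value = s[1, 6])
  })
  class(out) <- c("otl_manova", class(out))
  out
}

#' Linear discriminant analysis with leave-one-out cross-validation
#'
#' Fits an LDA on the descriptor matrix and classifies every specimen by
#' the jackknife rule: each specimen is predicted from a discriminant
#' function fitted to the other n - 1. Counts are accumulated into a
#' visual-versus-predicted confusion matrix in the fixed label order comb,
#' mixed, hatchet. When the pooled within-group covariance is
#' ill-conditioned (possible when descriptors outnumber the smallest
#' group), a Ledoit-Wolf-style shrinkage toward a scaled identity is
#' applied, with a warning under `shrinkage = "auto"`.
#'
#' @param dm An `otl_descriptors` tibble (>= 2 groups, per-group n >= 3).
#' @param shrinkage `"auto"` (shrink only when near-singular, with a
#'   warning), `"none"` (error instead), or `"always"`.
#' @param priors Class prior probabilities: `"proportions"` (default, the
#'   sample frequencies) or `"equal"`.
#' @return An object of class `otl_lda`: `confusion` (3 x 3 counts),
#'   `discriminant_fractions` (between-group variance proportions of the
#'   discriminants on the full fit), `posteriors` and `scores` tibbles,
#'   `accuracy`, and the shrinkage intensity used (0 when none).
#' @export
lda_loocv <- function(dm, shrinkage = c("auto", "none", "always"),
                      priors = c("proportions", "equal")) {
  shrinkage <- match.arg(shrinkage)
  priors <- match.arg(priors)
  g <- factor(dm$label, levels = intersect(shape_levels(), unique(dm$label)))
  if (nlevels(g) < 2L) stop("need at least 2 shape groups")
  if (any(table(g) < 3L)) stop("every group needs at least 3 specimens")
  Y <- descriptor_values(dm)
  n <- nrow(Y)
  lambda <- 0
  cond <- pooled_cov_condition(Y, g)
  need_shrink <- !is.finite(cond) || cond > 1e10
  if (shrinkage == "always" || (shrinkage == "auto" && need_shrink)) {
    lambda <- ledoit_wolf_lambda(Y, g)
    if (shrinkage == "auto") {
      warning(sprintf(
        "pooled within-group covariance is ill-conditioned; applying shrinkage (lambda = %.3f)",
        lambda))
    }
  } else if (shrinkage == "none" && need_shrink) {
    stop("pooled within-group covariance is near-singular; rerun with ",
         "shrinkage = \"always\" or reduce the harmonic count")
  }
  prior_vec <- if (priors == "equal") rep(1 / nlevels(g), nlevels(g))
               else as.numeric(table(g) / n)
  pred <- character(n)
  post <- matrix(NA_real_, n, nlevels(g), dimnames = list(NULL, levels(g)))
  for (i in seq_len(n)) {
    fit_i <- shrunken_lda_fit(Y[-i, , drop = FALSE], g[-i], lambda, prior_vec)
    pr <- shrunken_lda_predict(fit_i, Y[i, , drop = FALSE])
    pred[i] <- pr$class
    post[i, ] <- pr$posterior
  }
  pred <- factor(pred, levels = levels(g))
  cm <- confusion_counts(g, pred)
  full <- shrunken_lda_fit(Y, g, lambda, prior_vec)
  scores <- Y %*% full$scaling
  structure(
    list(
      confusion = cm,
      discriminant_fractions = full$svd^2 / sum(full$svd^2),
      posteriors = dplyr::bind_cols(
        tibble::tibble(specimen_id = dm$specimen_id, label = as.character(g),
                       predicted = as.character(pred)),
        tibble::as_tibble(post)
      ),
      scores = dplyr::bind_cols(
        tibble::tibble(specimen_id = dm$specimen_id, label = as.character(g)),
        tibble::as_tibble(scores)
      ),
      accuracy = mean(pred == g),
      shrinkage_lambda = lambda
    ),
    class = "otl_lda"
  )
}

confusion_counts <- function(truth, pred) {
  lv <- intersect(shape_levels(), levels(truth))
  m <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  m <- matrix(as.integer(m), nrow = length(lv),
              dimnames = list(visual = lv, predicted = lv))
  class(m) <- c("otl_confusion", class(m))
  m
}

pooled_within_cov <- function(Y, g) {
  centered <- Y - rowsum(Y, g)[g, ] / as.numeric(table(g))[g]
  crossprod(centered) / (nrow(Y) - nlevels(g))
}

pooled_cov_condition <- function(Y, g) {
  ev <- eigen(pooled_within_cov(Y, g), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(Inf)
  max(ev) / min(ev)
}

# Ledoit-Wolf shrinkage intensity toward mean(diag(S)) * I, computed on the
# within-group-centered observations
ledoit_wolf_lambda <- function(Y, g) {
  Xc <- Y - rowsum(Y, g)[g, ] / as.numeric(table(g))[g]
  n <- nrow(Xc)
  S <- crossprod(Xc) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, ncol(S)))^2)
  b2 <- sum(vapply(seq_len(n), function(i) {
    xi <- Xc[i, ]
    sum((tcrossprod(xi) - S)^2)
  }, numeric(1))) / n^2
  b2 <- min(b2, d2)
  if (d2 <= 0) return(0)
  min(1, max(0, b2 / d2))
}

# gaussian LDA with optional covariance shrinkage; mirrors MASS::lda's
# sphering construction so discriminant svd fractions are comparable
shrunken_lda_fit <- function(Y, g, lambda, prior) {
  g <- droplevels(g)
  k <- nlevels(g)
  means <- rowsum(Y, g) / as.numeric(table(g))
  S <- pooled_within_cov(Y, g)
  if (lambda > 0) {
    S <- (1 - lambda) * S + lambda * diag(mean(diag(S)), ncol(S))
  }
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) <= 0) stop("singular pooled covariance; use shrinkage")
  W <- es$vectors %*% diag(1 / sqrt(es$values), ncol(S)) %*% t(es$vectors)
  # between-group structure in the sphered space
  grand <- colMeans(Y)
  Mb <- sweep(means, 2, grand) %*% W * sqrt(as.numeric(table(g)))
  sv <- svd(Mb, nv = ncol(W))
  r <- min(k - 1L, ncol(Y))
  scaling <- W %*% sv$v[, seq_len(r), drop = FALSE]
  colnames(scaling) <- paste0("LD", seq_len(r))
  list(means = means, W = W, scaling = scaling,
       svd = sv$d[seq_len(r)], prior = prior, levels = levels(g))
}

shrunken_lda_predict <- function(fit, newx) {
  Z <- newx %*% fit$W
  Mz <- fit$means %*% fit$W
  d2 <- outer(rowSums(Z^2), rowSums(Mz^2), "+") - 2 * Z %*% t(Mz)
  logp <- -0.5 * d2 + matrix(log(fit$prior), nrow(newx), nrow(Mz), byrow = TRUE)
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp)
  post <- post / rowSums(post)
  colnames(post) <- fit$levels
  list(class = fit$levels[max.col(post)], posterior = drop(post))
}

#' Summarize a confusion matrix
#'
#' Per-class correct percentages (diagonal over row sum), the overall
#' percentage (trace over total), and per-cell row percentages. Percentages
#' are rounded half-away-from-zero to the nearest integer for reporting;
#' exact fractions are retained alongside.
#'
#' @param cm A square count matrix (visual rows x predicted columns), e.g.
#'   from [lda_loocv()] or [grenadier_confusion()].
#' @return A list with tibbles `per_class`, `cells`, and scalars
#'   `overall_percent` / `overall_exact`.
#' @export
confusion_summary <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), sum(cm) > 0, all(cm >= 0))
  lv <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  row_n <- rowSums(cm)
  per_exact <- ifelse(row_n > 0, diag(cm) / row_n, NA_real_)
  cells <- tibble::tibble(
    visual = rep(lv, times = ncol(cm)),
    predicted = rep(lv, each = nrow(cm)),
    count = as.integer(cm),
    row_fraction = as.numeric(cm / ifelse(row_n == 0, NA_real_, row_n)[row(cm)])
  )
  cells$row_percent <- round_half_up(100 * cells$row_fraction)
  list(
    per_class = tibble::tibble(
      label = lv,
      n = as.integer(row_n),
      correct = as.integer(diag(cm)),
      exact_fraction = per_exact,
      percent = round_half_up(100 * per_exact)
    ),
    cells = cells,
    overall_exact = sum(diag(cm)) / sum(cm),
    overall_percent = round_half_up(100 * sum(diag(cm)) / sum(cm))
  )
}

# round half away from zero (the reporting convention for percentages)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Confidence ellipse of a group mean in score space
#'
#' Ellipse of the sampling distribution of a group's mean score pair: the
#' sample covariance divided by n, scaled by the chi-square quantile with 2
#' degrees of freedom at the given level.
#'
#' @param scores A data frame or matrix with two columns of scores for one
#'   group (n >= 3).
#' @param level Confidence level in (0, 1); default 0.90.
#' @return A one-row tibble: `center_x`, `center_y`, `semi_major`,
#'   `semi_minor`, `angle` (radians), `level`, `n`.
#' @export
mean_confidence_ellipse <- function(scores, level = 0.90) {
  stopifnot(level > 0, level < 1)
  m <- as.matrix(scores)
  stopifnot(ncol(m) == 2L)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 observations for a mean ellipse")
  ctr <- colMeans(m)
  S <- stats::cov(m) / n
  es <- eigen(S, symmetric = TRUE)
  r2 <- stats::qchisq(level, df = 2)
  tibble::tibble(
    center_x = ctr[1], center_y = ctr[2],
    semi_major = sqrt(es$values[1] * r2),
    semi_minor = sqrt(max(es$values[2], 0) * r2),
    angle = atan2(es$vectors[2, 1], es$vectors[1, 1]),
    level = level, n = n
  )
}

# polygonized ellipse boundary, for plotting
ellipse_points <- function(e, n = 120L) {
  t <- seq(0, 2 * pi, length.out = n)
  ca <- cos(e$angle)
  sa <- sin(e$angle)
  tibble::tibble(
    x = e$center_x + e$semi_major * cos(t) * ca - e$semi_minor * sin(t) * sa,
    y = e$center_y + e$semi_major * cos(t) * sa + e$semi_minor * sin(t) * ca
  )
}
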