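#' Fit the morphometric general linear model
#'
#' Models one morphometric measurement as a function of fish length, fish
#' age, otolith shape, and the age-by-shape and length-by-shape
#' interactions. If neither interaction is significant at `alpha` (partial
#' F-tests), the model is refitted without them and the reduced additive
#' model is used for inference.
#'
#' @param morpho A data frame of morphometric measurements with
#'   `specimen_id` (e.g. stacked rows of [measure_morphometrics()]).
#' @param records A specimen table with `specimen_id`, `pafl_cm`, `age_yr`,
#'   and a shape column (`label` or `shape`).
#' @param response Name of the measurement column to model (e.g.
#'   `"feret_length"`).
#' @param alpha Significance level for the interaction screen.
#' @return An object of class `otl_morpho_fit`: the working `model`, the
#'   `full_model`, interaction p-values, and whether the reduced model was
#'   adopted.
#' @export
fit_morpho_model <- function(morpho, records, response, alpha = 0.05) {
  stopifnot(response %in% names(morpho))
  rec <- records
  if (!"shape" %in% names(rec) && "label" %in% names(rec)) {
    rec$shape <- rec$label
  }
  need <- c("specimen_id", "pafl_cm", "age_yr", "shape")
  stopifnot(all(need %in% names(rec)))
  df <- dplyr::inner_join(morpho[c("specimen_id", response)],
                          rec[need], by = "specimen_id")
  if (nrow(df) < 1L) stop("no specimens shared between `morpho` and `records`")
  df$shape <- factor(df$shape, levels = intersect(shape_levels(), df$shape))
  if (nlevels(df$shape) < 2L) stop("need at least 2 shape groups")
  df$.response <- df[[response]]
  mm <- stats::model.matrix(~ pafl_cm + age_yr + shape, data = df)
  if (kappa(mm) > 1e10) {
    stop("collinear covariates (condition number ", format(kappa(mm), digits = 3),
         "); check length/age inputs")
  }
  full <- stats::lm(.response ~ pafl_cm + age_yr + shape +
                      age_yr:shape + pafl_cm:shape, data = df)
  dr <- stats::drop1(full, test = "F")
  p_int <- stats::setNames(dr[["Pr(>F)"]][match(c("age_yr:shape", "pafl_cm:shape"),
                                                rownames(dr))],
                           c("age_by_shape", "length_by_shape"))
  use_reduced <- all(p_int > alpha, na.rm = TRUE)
  model <- if (use_reduced) {
    stats::lm(.response ~ pafl_cm + age_yr + shape, data = df)
  } else {
    full
  }
  structure(
    list(model = model, full_model = full, interaction_p = p_int,
         reduced = use_reduced, response = response, alpha = alpha,
         data = df),
    class = "otl_morpho_fit"
  )
}

#' @export
print.otl_morpho_fit <- function(x, ...) {
  cat(sprintf("# GLM for %s: %s model (interaction p = %.3f, %.3f)\n",
              x$response, if (x$reduced) "reduced additive" else "full",
              x$interaction_p[1], x$interaction_p[2]))
  print(stats::coef(x$model))
  invisible(x)
}

#' @method tidy otl_morpho_fit
#' @export
tidy.otl_morpho_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1],
    std_error = s[, 2],
    statistic = s[, 3],
    p_value = s[, 4]
  )
}

#' @method glance otl_morpho_fit
#' @export
glance.otl_morpho_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    response = x$response,
    r_squared = s$r.squared,
    sigma = s$sigma,
    reduced_model = x$reduced,
    p_age_by_shape = x$interaction_p[["age_by_shape"]],
    p_length_by_shape = x$interaction_p[["length_by_shape"]],
    n = nrow(x$data)
  )
}

#' Tukey-Kramer pairwise comparisons of shape groups
#'
#' Compares covariate-adjusted (least-squares) means of all shape pairs with
#' the studentized-range criterion and Kramer's unequal-n adjustment,
#' evaluated at the grand means of the covariates.
#'
#' @param fit An `otl_morpho_fit` (or any `lm` containing a `shape` factor).
#' @param level Confidence level for the LS-mean intervals.
#' @return An object of class `otl_tukey` with tibbles `ls_means` (`shape`,
#'   `ls_mean`, `ci_low`, `ci_high`, `arithmetic_mean`) and `pairs`
#'   (`contrast`, `estimate`, `se`, `p_value`, `significant`).
#' @export
tukey_kramer <- function(fit, level = 0.95) {
  model <- if (inherits(fit, "otl_morpho_fit")) fit$model else fit
  if (!"shape" %in% all.vars(stats::formula(model))) {
    stop("model has no `shape` factor")
  }
  df <- stats::model.frame(model)
  if (nlevels(droplevels(factor(df$shape))) < 2L) {
    stop("need at least 2 shape groups")
  }
  emm <- emmeans::emmeans(model, "shape")
  em_sum <- summary(emm, level = level)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  resp <- all.vars(stats::formula(model))[1]
  arith <- tapply(df[[resp]], df$shape, mean)
  structure(
    list(
      ls_means = tibble::tibble(
        shape = as.character(em_sum$shape),
        ls_mean = em_sum$emmean,
        ci_low = em_sum$lower.CL,
        ci_high = em_sum$upper.CL,
        arithmetic_mean = as.numeric(arith[as.character(em_sum$shape)])
      ),
      pairs = tibble::tibble(
        contrast = as.character(prs$contrast),
        estimate = prs$estimate,
        se = prs$SE,
        p_value = prs$p.value,
        significant = prs$p.value < 1 - level
      ),
      level = level
    ),
    class = "otl_tukey"
  )
}

#' @export
print.otl_tukey <- function(x, ...) {
  cat("# Tukey-Kramer pairwise comparisons of LS means\n")
  print(x$ls_means)
  print(x$pairs)
  invisible(x)
}

#' @method tidy otl_tukey
#' @export
tidy.otl_tukey <- function(x, ...) x$pairs
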