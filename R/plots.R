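#' Score scatter with mean-shape confidence ellipses
#'
#' Plots one principal-component score pair per specimen, colored by shape
#' label, with the confidence ellipse of each group's mean score.
#'
#' @param object An `otl_pca` from [pca_scores()].
#' @param pc_pair Which components to plot (default PC1 vs PC3, the pair
#'   that typically separates otolith shape groups best).
#' @param level Confidence level of the mean ellipses.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot otl_pca
#' @export
autoplot.otl_pca <- function(object, pc_pair = c(1L, 3L), level = 0.90, ...) {
  pcs <- paste0("PC", pc_pair)
  df <- object$scores
  ell <- dplyr::group_by(df, .data$label) |>
    dplyr::group_modify(function(d, ...) {
      ellipse_points(mean_confidence_ellipse(d[pcs], level))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                                   color = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, color = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_path(data = ell, ggplot2::aes(x = .data$x, y = .data$y,
                                                color = .data$label),
                       inherit.aes = FALSE) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1],
                  100 * object$variance_fraction[pc_pair[1]]),
      y = sprintf("%s (%.1f%%)", pcs[2],
                  100 * object$variance_fraction[pc_pair[2]]),
      color = "shape") +
    ggplot2::theme_minimal()
}

#' Plot discriminant scores by shape group
#'
#' @param object An `otl_lda` from [lda_loocv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot otl_lda
#' @export
autoplot.otl_lda <- function(object, ...) {
  df <- object$scores
  if (!"LD2" %in% names(df)) df$LD2 <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                   color = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("LD1 (%.1f%%)", 100 * object$discriminant_fractions[1]),
      y = if (length(object$discriminant_fractions) > 1)
        sprintf("LD2 (%.1f%%)", 100 * object$discriminant_fractions[2])
      else "LD2",
      color = "shape") +
    ggplot2::theme_minimal()
}

#' Plot group mean shapes
#'
#' Overlays the reconstructed mean outlines of each shape group.
#'
#' @param dm An `otl_descriptors` tibble.
#' @param n_points Reconstruction resolution.
#' @return A ggplot object.
#' @export
plot_mean_shapes <- function(dm, n_points = 256L) {
  labs <- unique(dm$label)
  df <- purrr::map_dfr(labs, function(l) {
    o <- group_mean_shape(dm, l, n_points)
    tibble::tibble(label = l, x = c(o$x, o$x[1]), y = c(o$y, o$y[1]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$label)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(color = "shape") +
    ggplot2::theme_minimal()
}

#' Plot a fitted growth curve over the data
#'
#' @param object An `otl_vb_fit` from [vb_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot otl_vb_fit
#' @export
autoplot.otl_vb_fit <- function(object, ...) {
  ages <- seq(min(object$data$age), max(object$data$age), length.out = 200)
  curve <- tibble::tibble(age = ages, len = predict(object, ages))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age, y = .data$len)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = curve, color = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "age (yr)", y = "pre-anal fin length (mm)") +
    ggplot2::theme_minimal()
}
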