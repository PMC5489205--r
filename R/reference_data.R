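#' Reference von Bertalanffy parameters for giant grenadier shape groups
#'
#' Published length-at-age parameter estimates for female giant grenadier
#' (*Albatrossia pectoralis*) with hatchet-, comb-, and mixed-shaped
#' otoliths. `linf_mm` is asymptotic pre-anal fin length in millimeters,
#' `k_per_yr` the growth coefficient as printed (negative sign convention;
#' evaluation uses its magnitude, see [vb_predict()]), `t0_yr` the
#' theoretical age at zero length, and `n` the sample size behind each fit.
#' These serve as the default growth conditions of the synthetic-data
#' generator and as worked-example inputs.
#'
#' @return A tibble with one row per shape group.
#' @export
grenadier_growth_params <- function() {
  tibble::tibble(
    label = c("hatchet", "comb", "mixed"),
    linf_mm = c(514, 469, 527),
    k_per_yr = c(-2.46e-2, -2.35e-2, -1.49e-2),
    t0_yr = c(-10.40, -12.06, -30.02),
    n = c(265L, 129L, 193L)
  )
}

#' Reference visual-versus-LDA classification counts for giant grenadier
#'
#' Published confusion matrix from a leave-one-out cross-validated linear
#' discriminant classification of female giant grenadier otolith shapes
#' against the visual assignments of an experienced age reader. Rows are
#' visual labels, columns predicted labels, in the fixed order comb, mixed,
#' hatchet. Used as a worked example for [confusion_summary()].
#'
#' @return A 3 x 3 integer matrix with dimnames `visual` x `predicted`.
#' @export
grenadier_confusion <- function() {
  m <- matrix(c(13L, 14L, 0L,
                23L, 40L, 16L,
                7L, 20L, 60L),
              nrow = 3, byrow = TRUE,
              dimnames = list(visual = c("comb", "mixed", "hatchet"),
                              predicted = c("comb", "mixed", "hatchet")))
  class(m) <- c("otl_confusion", class(m))
  m
}

shape_levels <- function() c("comb", "mixed", "hatchet")
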