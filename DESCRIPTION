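Package: otoshape
Title: Otolith Outline Morphometrics, Elliptical Fourier Shape Analysis,
    and Growth-Curve Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for stock-discrimination studies built on otolith shape
    and body growth. Extracts, smooths, and measures closed otolith outlines
    from grayscale images; decomposes outlines with elliptical Fourier
    analysis (Kuhl-Giardina coefficients with size, rotation, and
    starting-point normalization); screens Fourier descriptors for allometric
    size effects and applies pooled-slope corrections; compares shape groups
    with MANOVA, principal components, and linear discriminant analysis with
    leave-one-out cross-validation; fits general linear models with
    Tukey-Kramer pairwise comparisons to classical morphometric measurements;
    and fits and compares von Bertalanffy growth curves between shape groups
    with likelihood-ratio tests. Includes a synthetic-data generator that
    emulates overlapping otolith shape phenotypes and group-specific growth
    so the full pipeline is testable without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
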