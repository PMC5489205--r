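# otoshape

Otolith outline morphometrics, elliptical Fourier shape analysis, and von
Bertalanffy growth-curve comparison for fish stock-discrimination studies.

Otoliths — the calcium-carbonate ear stones of teleost fishes — record both
shape and growth history, and within-species shape variants can signal
stock structure. The motivating case is the giant grenadier (*Albatrossia
pectoralis*), whose otoliths fall visually into a narrow-ended "hatchet"
type, a crenulated, rounded "comb" type, and an intermediate "mixed" type.
`otoshape` provides the whole analysis chain a study of such variation
needs, for anyone working with closed 2-D outlines and length-at-age data:

* **Contours** — extract outlines from grayscale images (Otsu threshold,
  Moore boundary tracing), smooth them with a cyclic 3-point moving
  average, resample to equal arc length at unit centroid size, and measure
  area, perimeter, Feret length/width (caliper extents), and the
  major/minor axes through the center of mass.
* **Elliptical Fourier analysis** — Kuhl–Giardina coefficients
  `(a_h, b_h, c_h, d_h)` per harmonic; normalization by the first-harmonic
  ellipse removes size, rotation, and starting point, fixing three
  descriptors so H harmonics leave `4H − 3` free descriptors (45 at the
  default H = 12); harmonic selection by cumulative power
  `(a² + b² + c² + d²)/2`.
* **Allometry** — per-descriptor ANCOVA screen against otolith Feret
  length and pooled-slope correction `FD_A = FD_O − b(L − L̄)`.
* **Shape statistics** — MANOVA on shape category, PCA with 90%
  confidence ellipses of group mean scores, and LDA with leave-one-out
  cross-validation summarized as a visual-vs-predicted confusion matrix.
* **Morphometric GLM** — `M = μ + L + A + S + A×S + L×S + e` with
  interaction screening and Tukey–Kramer comparisons of least-squares
  means.
* **Growth** — von Bertalanffy fits `L = L∞(1 − e^{−K(age − t₀)})` with
  asymptotic 95% limits, and Kimura-style likelihood-ratio comparison of
  curves between shape groups, `χ² = N ln(RSS_constrained / RSS_full)`.
* **Synthetic data** — a generator producing overlapping hatchet / comb /
  mixed outline phenotypes, size-coupled otoliths with injectable
  allometric effects, and group-specific length-at-age data, so the whole
  pipeline is testable with no specimen download.

## Worked example

Published reference inputs ship as functions. The confusion matrix of a
cross-validated LDA against visual labels, summarized:

```r
library(otoshape)
cs <- confusion_summary(grenadier_confusion())
cs$per_class
#> # A tibble: 3 × 5
#>   label       n correct exact_fraction percent
#>   <chr>   <int>   <int>          <dbl>   <dbl>
#> 1 comb       27      13          0.481      48
#> 2 mixed      79      40          0.506      51
#> 3 hatchet    87      60          0.690      69
cs$overall_percent
#> [1] 59
```

So 59% of shape predictions match the visual labels overall; hatchet
otoliths classify best (69%) because of their distinctive narrow end.
Growth differs too — predicted pre-anal fin length at age 45 from the
published parameters:

```r
gp <- grenadier_growth_params()
vb_predict(gp[gp$label == "hatchet", ], 45) / 10   # cm
#> [1] 38.2
vb_predict(gp[gp$label == "comb", ], 45) / 10
#> [1] 34.6
```

A full synthetic run (90 specimens, three balanced groups):

```r
ds  <- gen_dataset(synth_config(n_per_group = 30, seed = 1))
res <- run_pipeline(ds$outlines, ds$specimens, config = pipeline_config(seed = 1))
res$manova
#> # A tibble: 2 × 6
#>   statistic     value approx_f   df1   df2  p_value
#> 1 Pillai    1.98          104.    90    88 6.53e-65
#> 2 Wilks     0.0000443     143.    90    86 2.46e-69
res$confusion_summary$overall_percent
#> [1] 100
res$growth_comparisons[, c("pair", "chi2", "df", "p_value")]
#> # A tibble: 3 × 4
#>   pair              chi2    df p_value
#> 1 comb vs hatchet  12.8      3 0.00499
#> 2 comb vs mixed     1.76     3 0.624
#> 3 hatchet vs mixed 15.1      3 0.00176
```

The synthetic phenotypes are fully separable by design (100% leave-one-out
accuracy), unlike real material where the mixed type overlaps both
extremes; the growth comparison correctly rejects equality of the hatchet
and comb curves at these sample sizes. `autoplot()` methods cover PCA
score plots with mean-shape ellipses, LDA scores, outlines, and growth
fits; `tidy()`/`glance()` methods give broom-style summaries of fitted
objects. The methods vignette
(`vignettes/otolith-shape-growth.Rmd`) documents the models, conventions,
and generator assumptions in detail.

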