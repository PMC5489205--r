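#' Otolith shape phenotype parameters
#'
#' Parameterizes the synthetic outline model: a base ellipse whose radius is
#' modulated by (i) a smooth taper concentrated on the posterior semicircle
#' (the narrow end of hatchet-shaped otoliths) and (ii) a sinusoidal
#' crenulation windowed to the ventral arc (the comb edge). The `mixed`
#' phenotype is a convex combination of the comb and hatchet endpoints
#' controlled by `blend`.
#'
#' @param label One of `"comb"`, `"mixed"`, `"hatchet"`.
#' @param taper Posterior narrowing strength in `[0, 1]`; high for hatchet.
#' @param crenulation_amp Ventral wave amplitude as a fraction of radius, in
#'   `[0, 0.15]`; high for comb.
#' @param crenulation_freq Integer wave count per outline (>= 2).
#' @param aspect Major/minor axis ratio of the base ellipse (>= 1).
#' @param blend For `mixed`, interpolation weight from comb (0) to hatchet
#'   (1); ignored for the endpoint labels.
#' @return A list of class `otl_phenotype`.
#' @export
shape_phenotype <- function(label = c("comb", "mixed", "hatchet"),
                            taper = NULL, crenulation_amp = NULL,
                            crenulation_freq = NULL, aspect = NULL,
                            blend = 0.5) {
  label <- match.arg(label)
  ends <- list(
    comb = list(taper = 0.05, crenulation_amp = 0.12,
                crenulation_freq = 11L, aspect = 1.8),
    hatchet = list(taper = 0.55, crenulation_amp = 0.02,
                   crenulation_freq = 10L, aspect = 2.2)
  )
  base <- switch(label,
    comb = ends$comb,
    hatchet = ends$hatchet,
    mixed = {
      stopifnot(blend >= 0, blend <= 1)
      list(
        taper = (1 - blend) * ends$comb$taper + blend * ends$hatchet$taper,
        crenulation_amp = (1 - blend) * ends$comb$crenulation_amp +
          blend * ends$hatchet$crenulation_amp,
        crenulation_freq = as.integer(round(
          (1 - blend) * ends$comb$crenulation_freq +
            blend * ends$hatchet$crenulation_freq)),
        aspect = (1 - blend) * ends$comb$aspect + blend * ends$hatchet$aspect
      )
    }
  )
  p <- list(
    label = label,
    taper = taper %||% base$taper,
    crenulation_amp = crenulation_amp %||% base$crenulation_amp,
    crenulation_freq = as.integer(crenulation_freq %||% base$crenulation_freq),
    aspect = aspect %||% base$aspect,
    blend = blend
  )
  validate_phenotype(p)
  structure(p, class = "otl_phenotype")
}

validate_phenotype <- function(p) {
  if (p$taper < 0 || p$taper > 1) stop("taper must lie in [0, 1]")
  if (p$crenulation_amp < 0 || p$crenulation_amp > 0.15) {
    stop("crenulation_amp must lie in [0, 0.15]")
  }
  if (p$crenulation_freq < 2L) stop("crenulation_freq must be >= 2")
  if (p$aspect < 1) stop("aspect (major/minor ratio) must be >= 1")
  if (p$blend < 0 || p$blend > 1) stop("blend must lie in [0, 1]")
  invisible(p)
}

#' Generate a synthetic otolith outline
#'
#' Samples the phenotype's radial model at `n_points` uniform parameter
#' values: a base ellipse with semi-axes `size * sqrt(aspect)` and
#' `size / sqrt(aspect)` (so `size` is the geometric-mean radius and the
#' pure-ellipse area is `pi * size^2`), multiplied by the taper and
#' crenulation modulations. With `taper = 0` and `crenulation_amp = 0` the
#' result is exactly an ellipse with the requested aspect. Optional radial
#' jitter adds i.i.d. multiplicative Gaussian noise per vertex.
#'
#' @param phenotype An [shape_phenotype()].
#' @param size Geometric-mean radius (pixels or mm).
#' @param n_points Number of vertices (>= 64).
#' @param seed Optional integer seed; the same seed reproduces the outline
#'   exactly.
#' @param jitter_sd Radial jitter standard deviation as a fraction of the
#'   local radius (default 0: noiseless).
#' @return An [outline()].
#' @export
gen_outline <- function(phenotype, size, n_points = 256L, seed = NULL,
                        jitter_sd = 0) {
  stopifnot(inherits(phenotype, "otl_phenotype"))
  validate_phenotype(phenotype)
  if (size <= 0) stop("size must be positive")
  if (n_points < 64) stop("n_points must be >= 64")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  t <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  a <- size * sqrt(phenotype$aspect)
  b <- size / sqrt(phenotype$aspect)
  # taper window: 0 at the anterior end (t = 0), 1 at the posterior (t = pi)
  taper_win <- ((1 - cos(t)) / 2)^2
  # crenulation window: smooth bump on the ventral (y < 0) arc
  cren_win <- ifelse(sin(t) < 0, sin(t)^2, 0)
  m <- (1 - phenotype$taper * taper_win) *
    (1 + phenotype$crenulation_amp * cren_win *
       cos(phenotype$crenulation_freq * t))
  if (jitter_sd > 0) {
    eps <- with_seed_if(seed, stats::rnorm(n_points, 0, jitter_sd))
    m <- m * (1 + eps)
  }
  outline(m * a * cos(t), m * b * sin(t), enforce_ccw = FALSE)
}

# run code under a temporary seed when one is given
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate length-at-age records from a von Bertalanffy curve
#'
#' Ages are drawn uniformly over `age_range`; lengths follow the growth
#' curve (evaluated with the magnitude of `k`, see [vb_predict()]) plus
#' additive Gaussian noise, truncated below at zero.
#'
#' @param vb A one-row data frame or list with `linf_mm`, `k_per_yr`,
#'   `t0_yr` (e.g. one row of [grenadier_growth_params()]).
#' @param n Number of fish.
#' @param age_range Numeric length-2 vector of ages in years.
#' @param noise_sd Additive length noise in mm (>= 0).
#' @param seed Optional integer seed.
#' @param label Optional shape label stored on every record.
#' @return A tibble with `specimen_id`, `age_yr`, `pafl_mm`, `pafl_cm`,
#'   `shape`.
#' @export
gen_growth_data <- function(vb, n, age_range = c(16, 56), noise_sd = 40,
                            seed = NULL, label = NA_character_) {
  stopifnot(n >= 1, noise_sd >= 0, length(age_range) == 2)
  if (diff(age_range) < 0) stop("age_range must have non-negative span")
  sim <- with_seed_if(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    len <- vb_predict(vb, age) + stats::rnorm(n, 0, noise_sd)
    list(age = age, len = pmax(len, 0))
  })
  tibble::tibble(
    specimen_id = sprintf("fish%04d", seq_len(n)),
    age_yr = sim$age,
    pafl_mm = sim$len,
    pafl_cm = sim$len / 10,
    shape = label
  )
}

#' Synthetic-dataset configuration
#'
#' Collects the study conditions emulated by [gen_dataset()]: balanced group
#' sizes, the sampled age range, per-group growth parameters, growth noise,
#' the allometric slopes injected into chosen descriptors, outline
#' resolution, and the phenotype/size scatter of individual otoliths.
#'
#' @param n_per_group Specimens per shape label (>= 1).
#' @param age_range Ages sampled uniformly, years.
#' @param vb_params Tibble with `label`, `linf_mm`, `k_per_yr`, `t0_yr`;
#'   default [grenadier_growth_params()].
#' @param length_noise_sd Additive length-at-age noise, mm.
#' @param allometry_slopes Named numeric vector mapping free-descriptor
#'   columns (e.g. `d5`) to slopes per mm of otolith Feret length. Nonzero
#'   slopes are injected by perturbing normalized descriptors linearly in
#'   size, so the downstream ANCOVA screen can recover them; all-zero slopes
#'   leave outlines untouched by the injection step.
#' @param outline_points Vertices per outline (>= 64).
#' @param seed Integer seed; identical configurations (including seed)
#'   reproduce the dataset exactly.
#' @param taper_jitter,cren_jitter,aspect_sdlog Per-specimen phenotype
#'   scatter (truncated to the valid ranges).
#' @param radial_jitter_sd Per-vertex radial outline noise (fraction of
#'   radius).
#' @param feret_per_mm Mean otolith Feret length per mm of fish length.
#' @param feret_sdlog Lognormal scatter of otolith size around that mean.
#' @return A list of class `otl_synth_config`.
#' @export
synth_config <- function(n_per_group = 64L,
                         age_range = c(16, 56),
                         vb_params = grenadier_growth_params(),
                         length_noise_sd = 40,
                         allometry_slopes = c(d5 = 2e-3, d9 = 2e-3,
                                              d13 = 2e-3, d17 = 2e-3),
                         outline_points = 256L,
                         seed = 1L,
                         taper_jitter = 0.05,
                         cren_jitter = 0.015,
                         aspect_sdlog = 0.04,
                         radial_jitter_sd = 0.004,
                         feret_per_mm = 0.06,
                         feret_sdlog = 0.04) {
  stopifnot(n_per_group >= 1, length_noise_sd >= 0, outline_points >= 64,
            diff(age_range) >= 0)
  structure(
    list(n_per_group = as.integer(n_per_group), age_range = age_range,
         vb_params = vb_params, length_noise_sd = length_noise_sd,
         allometry_slopes = allometry_slopes,
         outline_points = as.integer(outline_points), seed = as.integer(seed),
         taper_jitter = taper_jitter, cren_jitter = cren_jitter,
         aspect_sdlog = aspect_sdlog, radial_jitter_sd = radial_jitter_sd,
         feret_per_mm = feret_per_mm, feret_sdlog = feret_sdlog),
    class = "otl_synth_config"
  )
}

#' Generate a full synthetic specimen set
#'
#' Produces one outline plus one specimen record per fish, balanced across
#' the three shape labels. Fish ages and lengths follow the configured
#' growth curves; otolith size scales with fish length (lognormal scatter);
#' per-specimen phenotype jitter and per-vertex radial jitter create
#' overlapping shape groups. When any allometric slope is nonzero, outlines
#' are rebuilt from size-perturbed normalized Fourier descriptors so the
#' injected size effect is recoverable by [screen_descriptors()].
#'
#' @param config An [synth_config()].
#' @param phenotypes Optional named list of [shape_phenotype()] overrides
#'   (names `comb`, `mixed`, `hatchet`), e.g. to equalize groups for null
#'   simulations.
#' @return A list with `specimens` (tibble: `specimen_id`, `label`,
#'   `pafl_cm`, `age_yr`, `station`, `area`, `year`, `otolith_feret_mm`,
#'   `side`) and `outlines` (named list of [outline()]s in mm coordinates).
#' @export
gen_dataset <- function(config = synth_config(), phenotypes = NULL) {
  stopifnot(inherits(config, "otl_synth_config"))
  labels <- shape_levels()
  phen <- lapply(labels, function(l) {
    if (!is.null(phenotypes) && !is.null(phenotypes[[l]])) phenotypes[[l]]
    else shape_phenotype(l)
  })
  names(phen) <- labels
  n <- config$n_per_group
  total <- 3L * n
  withr::with_seed(config$seed, {
    label <- rep(labels, each = n)
    age <- stats::runif(total, config$age_range[1], config$age_range[2])
    vbp <- config$vb_params
    pafl_mm <- numeric(total)
    for (l in labels) {
      i <- label == l
      row <- vbp[vbp$label == l, ]
      pafl_mm[i] <- pmax(vb_predict(row, age[i]) +
                           stats::rnorm(sum(i), 0, config$length_noise_sd), 0)
    }
    feret_mm <- config$feret_per_mm * pafl_mm *
      exp(stats::rnorm(total, 0, config$feret_sdlog))
    l_center <- mean(feret_mm)
    outlines <- vector("list", total)
    for (i in seq_len(total)) {
      p <- phen[[label[i]]]
      p2 <- p
      p2$taper <- clamp(p$taper + stats::rnorm(1, 0, config$taper_jitter), 0, 1)
      p2$crenulation_amp <- clamp(
        p$crenulation_amp + stats::rnorm(1, 0, config$cren_jitter), 0, 0.15)
      p2$aspect <- max(1, p$aspect * exp(stats::rnorm(1, 0, config$aspect_sdlog)))
      o <- gen_outline(p2, size = feret_mm[i] / (2 * sqrt(p2$aspect)),
                       n_points = config$outline_points)
      if (config$radial_jitter_sd > 0) {
        eps <- stats::rnorm(nrow(o), 0, config$radial_jitter_sd)
        o <- outline(o$x * (1 + eps), o$y * (1 + eps), enforce_ccw = FALSE)
      }
      outlines[[i]] <- o
    }
    if (any(config$allometry_slopes != 0)) {
      outlines <- lapply(seq_len(total), function(i) {
        inject_allometry(outlines[[i]], config$allometry_slopes,
                         feret_mm[i] - l_center, feret_mm[i],
                         config$outline_points)
      })
    }
    ids <- sprintf("oto%04d", seq_len(total))
    names(outlines) <- ids
    specimens <- tibble::tibble(
      specimen_id = ids,
      label = label,
      pafl_cm = pafl_mm / 10,
      age_yr = age,
      station = sample(c(13L, 15L, 85L, 107L, 108L), total, replace = TRUE),
      area = sample(c("EBS", "CGOA", "EGOA"), total, replace = TRUE),
      year = 2013L,
      otolith_feret_mm = feret_mm,
      side = "left"
    )
    list(specimens = specimens, outlines = outlines)
  })
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# rebuild an outline from its normalized descriptors with a linear-in-size
# perturbation added to the targeted free descriptors, then restore size
inject_allometry <- function(o, slopes, l_centered, feret_mm, n_points) {
  rs <- resample_and_center(o, n_points)
  efd <- efa_normalize(efa_forward(rs, 12L))
  v <- free_descriptors(efd)
  idx <- as.integer(sub("^d", "", names(slopes)))
  ok <- idx >= 1L & idx <= length(v)
  v[idx[ok]] <- v[idx[ok]] + slopes[ok] * l_centered
  rec <- efa_inverse(efd_from_free(v, 12L), n_points)
  # normalized semi-major axis is 1; scale so the Feret length ~ feret_mm
  outline(rec$x * feret_mm / 2, rec$y * feret_mm / 2, enforce_ccw = FALSE)
}
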