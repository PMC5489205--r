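# shared fixture builders (everything is generated in code; no data files)

# descriptor tibble from a plain specimen x descriptor matrix
make_dm <- function(Y, label, feret_length = 20, age = 30) {
  Y <- as.matrix(Y)
  colnames(Y) <- paste0("d", seq_len(ncol(Y)))
  dm <- dplyr::bind_cols(
    tibble::tibble(
      specimen_id = sprintf("s%04d", seq_len(nrow(Y))),
      label = rep_len(label, nrow(Y)),
      feret_length = rep_len(feret_length, nrow(Y)),
      age = rep_len(age, nrow(Y))
    ),
    tibble::as_tibble(Y)
  )
  attr(dm, "n_harmonics") <- (ncol(Y) + 3L) %/% 4L
  class(dm) <- c("otl_descriptors", class(dm))
  dm
}

# random simple star-shaped polygon around the origin
random_star_polygon <- function(n = 24, r_sd = 0.25) {
  t <- sort(stats::runif(n, 0, 2 * pi))
  r <- exp(stats::rnorm(n, 0, r_sd))
  outline(r * cos(t), r * sin(t))
}

# ellipse sampled at uniform parameter (exactly first-harmonic under EFA)
ellipse_outline <- function(a = 2, b = 1, n = 256) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  outline(a * cos(t), b * sin(t))
}

# descriptor matrix of a synthetic dataset run through the EFA stages
dataset_descriptors <- function(ds, n_harmonics = 12L, n_points = 256L) {
  prep <- lapply(ds$outlines, function(o) resample_and_center(o, n_points))
  efds <- lapply(prep, function(o) efa_normalize(efa_forward(o, n_harmonics)))
  descriptor_matrix(efds, ds$specimens$specimen_id, ds$specimens$label,
                    feret_length = ds$specimens$otolith_feret_mm,
                    age = ds$specimens$age_yr)
}

# three-group specimen table for morphometric GLM simulations
glm_sim_data <- function(n_per, offsets = c(0, 0, 0), sd = 1) {
  lab <- rep(c("comb", "mixed", "hatchet"), times = n_per)
  n <- length(lab)
  tibble::tibble(
    specimen_id = sprintf("g%04d", seq_len(n)),
    shape = lab,
    pafl_cm = stats::runif(n, 25, 45),
    age_yr = stats::runif(n, 16, 56),
    feret_length = 20 + rep(offsets, times = n_per) + stats::rnorm(n, 0, sd)
  )
}
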