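#' Elliptical Fourier decomposition of a closed outline
#'
#' Computes Kuhl-Giardina elliptical Fourier coefficients (a_h, b_h, c_h,
#' d_h per harmonic) of the closed polygon. Vertices are treated as equally
#' spaced in the curve parameter; [resample_and_center()] guarantees equal
#' arc-length spacing, under which this coincides with the classical
#' chord-length parameterization, while analytically parameterized curves
#' (e.g. an ellipse sampled at uniform eccentric anomaly) are represented
#' exactly by their true harmonics.
#'
#' @param o An [outline()], normally resampled and centered.
#' @param n_harmonics Number of harmonics H (<= floor(n_points / 2)).
#' @return An object of class `otl_efd`: coefficient matrix `coef` (H x 4,
#'   columns a, b, c, d), the curve center (`a0`, `c0`), and normalization
#'   state.
#' @export
efa_forward <- function(o, n_harmonics = 12L) {
  o <- as_outline(o)
  n <- nrow(o)
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("need at least one harmonic")
  if (n_harmonics > floor(n / 2)) {
    stop("n_harmonics must be <= floor(n_points / 2) = ", floor(n / 2))
  }
  x <- o$x
  y <- o$y
  dx <- x - c(x[n], x[-n])
  dy <- y - c(y[n], y[-n])
  t_i <- seq_len(n)            # uniform parameter, T = n
  h <- seq_len(n_harmonics)
  # phase differences cos/sin(2*pi*h*t/T) at t_i and t_{i-1}
  ang <- 2 * pi * outer(t_i, h) / n          # n x H
  ang_prev <- 2 * pi * outer(t_i - 1, h) / n
  dcos <- cos(ang) - cos(ang_prev)
  dsin <- sin(ang) - sin(ang_prev)
  const <- n / (2 * pi^2 * h^2)
  a <- const * colSums(dx * dcos)
  b <- const * colSums(dx * dsin)
  cc <- const * colSums(dy * dcos)
  d <- const * colSums(dy * dsin)
  structure(
    list(coef = cbind(a = a, b = b, c = cc, d = d),
         a0 = mean((x + c(x[n], x[-n])) / 2),
         c0 = mean((y + c(y[n], y[-n])) / 2),
         n_harmonics = n_harmonics,
         normalized = FALSE,
         dropped = character(0)),
    class = "otl_efd"
  )
}

#' @export
print.otl_efd <- function(x, ...) {
  cat(sprintf("# Elliptical Fourier coefficients: %d harmonics, %s\n",
              x$n_harmonics,
              if (x$normalized) "normalized" else "unnormalized"))
  print(utils::head(x$coef, 3))
  if (x$n_harmonics > 3) cat(sprintf("# ... %d more harmonics\n", x$n_harmonics - 3L))
  invisible(x)
}

#' @method tidy otl_efd
#' @export
tidy.otl_efd <- function(x, ...) {
  tibble::tibble(
    harmonic = rep(seq_len(x$n_harmonics), 4L),
    coefficient = rep(c("a", "b", "c", "d"), each = x$n_harmonics),
    value = c(x$coef[, "a"], x$coef[, "b"], x$coef[, "c"], x$coef[, "d"])
  )
}

# signed area of the first-harmonic ellipse (pi * (a1 d1 - b1 c1))
first_harmonic_area <- function(efd) {
  co <- efd$coef
  pi * (co[1, "a"] * co[1, "d"] - co[1, "b"] * co[1, "c"])
}

#' Normalize elliptical Fourier coefficients
#'
#' Removes size, rotation, and starting-point information using the
#' first-harmonic ellipse: the starting point is rotated to the end of the
#' semi-major axis, the shape is rotated so the semi-major axis lies along x,
#' and all coefficients are divided by the semi-major length. A clockwise
#' coefficient set (negative first-harmonic area) is re-parameterized to
#' counterclockwise first. After normalization `a1 = 1` and `b1 = c1 = 0`
#' exactly; these three descriptors are recorded in `dropped`, leaving
#' `4 * H - 3` free descriptors. The residual 180-degree starting-point
#' ambiguity is broken by requiring the first non-negligible even-harmonic
#' coefficient to be positive, a shape-intrinsic rule that preserves
#' rotation/scale/start-point invariance.
#'
#' @param efd An unnormalized `otl_efd` from [efa_forward()]; normalized
#'   input is returned unchanged (the operation is idempotent).
#' @return A normalized `otl_efd`.
#' @export
efa_normalize <- function(efd) {
  stopifnot(inherits(efd, "otl_efd"))
  co <- efd$coef
  H <- efd$n_harmonics
  h <- seq_len(H)
  if (first_harmonic_area(efd) < 0) {
    co[, "b"] <- -co[, "b"]
    co[, "d"] <- -co[, "d"]
  }
  a1 <- co[1, "a"]; b1 <- co[1, "b"]; c1 <- co[1, "c"]; d1 <- co[1, "d"]
  theta0 <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  candidates <- lapply(theta0 + (0:3) * pi / 2, function(th) {
    rotate_efd(co, h, start_shift = th)
  })
  semi_major <- vapply(candidates, function(cc) abs(cc[1, "a"]), numeric(1))
  if (max(semi_major) <= 0) stop("degenerate first harmonic: zero semi-major axis")
  keep <- which(semi_major > max(semi_major) * (1 - 1e-9))
  candidates <- candidates[keep]
  pick <- candidates[[1]]
  if (length(candidates) > 1L) {
    pick <- resolve_even_sign(candidates)
  }
  scale <- pick[1, "a"]
  pick <- pick / scale
  pick[1, c("a", "b", "c")] <- c(1, 0, 0)
  structure(
    list(coef = pick, a0 = 0, c0 = 0, n_harmonics = H,
         normalized = TRUE, dropped = c("a1", "b1", "c1")),
    class = "otl_efd"
  )
}

# apply starting-point shift then rotate the shape so the first-harmonic
# semi-major axis lies along +x
rotate_efd <- function(co, h, start_shift) {
  ch <- cos(h * start_shift)
  sh <- sin(h * start_shift)
  a <- co[, "a"] * ch + co[, "b"] * sh
  b <- -co[, "a"] * sh + co[, "b"] * ch
  cc <- co[, "c"] * ch + co[, "d"] * sh
  d <- -co[, "c"] * sh + co[, "d"] * ch
  psi <- atan2(cc[1], a[1])
  cp <- cos(psi)
  sp <- sin(psi)
  cbind(a = cp * a + sp * cc,
        b = cp * b + sp * d,
        c = -sp * a + cp * cc,
        d = -sp * b + cp * d)
}

# the two surviving candidates differ by negation of all even harmonics;
# require the first even-harmonic entry of non-negligible magnitude positive
resolve_even_sign <- function(candidates) {
  ref <- candidates[[1]]
  H <- nrow(ref)
  if (H < 2L) return(ref)
  even <- seq(2L, H, by = 2L)
  for (cand in candidates) {
    v <- as.numeric(t(cand[even, , drop = FALSE]))
    idx <- which(abs(v) > 1e-9)
    if (length(idx) == 0L) return(cand)      # no even content: ambiguity moot
    if (v[idx[1]] > 0) return(cand)
  }
  candidates[[1]]
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` equally spaced
#' parameter values.
#'
#' @param efd An `otl_efd`.
#' @param n_points Number of points to evaluate.
#' @return An [outline()]; if all coefficients are zero the reconstruction
#'   collapses to a point, which is returned as a degenerate outline with a
#'   warning.
#' @export
efa_inverse <- function(efd, n_points = 256L) {
  stopifnot(inherits(efd, "otl_efd"), n_points >= 3)
  h <- seq_len(efd$n_harmonics)
  t <- seq_len(n_points) / n_points
  ang <- 2 * pi * outer(t, h)
  x <- efd$a0 + cos(ang) %*% efd$coef[, "a"] + sin(ang) %*% efd$coef[, "b"]
  y <- efd$c0 + cos(ang) %*% efd$coef[, "c"] + sin(ang) %*% efd$coef[, "d"]
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (all(abs(efd$coef) < .Machine$double.eps * 10)) {
    warning("all coefficients are zero: reconstruction degenerates to a point")
    return(tibble::new_tibble(list(x = x, y = y), class = "otl_outline"))
  }
  outline(x, y, enforce_ccw = FALSE)
}

#' Harmonic power spectrum of a set of outlines
#'
#' Per-harmonic power (a^2 + b^2 + c^2 + d^2) / 2 summed over outlines.
#'
#' @param outlines A list of [outline()]s (resampled/centered).
#' @param n_harmonics Number of harmonics to evaluate; defaults to the
#'   maximum supported by the shortest outline.
#' @return A tibble with `harmonic`, `power`, `cum_fraction`.
#' @export
harmonic_power <- function(outlines, n_harmonics = NULL) {
  if (length(outlines) == 0L) stop("no outlines supplied")
  n_min <- min(vapply(outlines, nrow, integer(1)))
  if (is.null(n_harmonics)) n_harmonics <- floor(n_min / 2)
  pow <- numeric(n_harmonics)
  for (o in outlines) {
    co <- efa_forward(o, n_harmonics)$coef
    pow <- pow + rowSums(co^2) / 2
  }
  tibble::tibble(
    harmonic = seq_len(n_harmonics),
    power = pow,
    cum_fraction = cumsum(pow) / sum(pow)
  )
}

#' Choose the number of harmonics by cumulative power
#'
#' Smallest H whose cumulative harmonic power reaches the given fraction of
#' the total (the conventional criterion is 99%).
#'
#' @param outlines A list of [outline()]s.
#' @param variance_threshold Fraction of total power to reach, in (0, 1].
#' @param n_harmonics Harmonic range to consider (see [harmonic_power()]).
#' @return The selected harmonic count (integer).
#' @export
choose_harmonics <- function(outlines, variance_threshold = 0.99,
                             n_harmonics = NULL) {
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  hp <- harmonic_power(outlines, n_harmonics)
  as.integer(which(hp$cum_fraction >= variance_threshold - 1e-12)[1])
}

#' Assemble a descriptor matrix from normalized coefficient sets
#'
#' Flattens each specimen's free descriptors (d1 of the first harmonic, then
#' a, b, c, d of harmonics 2..H) into columns `d1..d(4H-3)` alongside the
#' specimen metadata used downstream (shape label, otolith Feret length,
#' age).
#'
#' @param efds A list of normalized `otl_efd`, one per specimen.
#' @param specimen_id Character or integer ids.
#' @param label Shape labels (`comb`, `mixed`, `hatchet`).
#' @param feret_length Otolith Feret lengths (size covariate for the
#'   allometric screen).
#' @param age Fish ages in years.
#' @return A tibble of class `otl_descriptors` with attribute `n_harmonics`.
#' @export
descriptor_matrix <- function(efds, specimen_id, label,
                              feret_length = NA_real_, age = NA_real_) {
  stopifnot(length(efds) >= 1L)
  if (!all(vapply(efds, function(e) isTRUE(e$normalized), logical(1)))) {
    stop("all coefficient sets must be normalized (see efa_normalize())")
  }
  H <- efds[[1]]$n_harmonics
  if (!all(vapply(efds, function(e) e$n_harmonics, integer(1)) == H)) {
    stop("all coefficient sets must share the same harmonic count")
  }
  mat <- t(vapply(efds, free_descriptors, numeric(4L * H - 3L)))
  colnames(mat) <- paste0("d", seq_len(ncol(mat)))
  out <- tibble::tibble(
    specimen_id = specimen_id,
    label = as.character(label),
    feret_length = rep_len(as.numeric(feret_length), length(efds)),
    age = rep_len(as.numeric(age), length(efds))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  attr(out, "n_harmonics") <- H
  class(out) <- c("otl_descriptors", class(out))
  out
}

# free descriptor vector of a normalized EFD: d1, then harmonics 2..H
free_descriptors <- function(efd) {
  co <- efd$coef
  H <- nrow(co)
  if (H == 1L) return(co[1, "d"])
  c(co[1, "d"], as.numeric(t(co[-1, , drop = FALSE])))
}

# rebuild a normalized otl_efd from a free descriptor vector
efd_from_free <- function(v, n_harmonics) {
  n_harmonics <- as.integer(n_harmonics)
  stopifnot(length(v) == 4L * n_harmonics - 3L)
  co <- matrix(0, n_harmonics, 4L,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  co[1, ] <- c(1, 0, 0, v[1])
  if (n_harmonics > 1L) {
    co[-1, ] <- matrix(v[-1], ncol = 4L, byrow = TRUE)
  }
  structure(
    list(coef = co, a0 = 0, c0 = 0, n_harmonics = n_harmonics,
         normalized = TRUE, dropped = c("a1", "b1", "c1")),
    class = "otl_efd"
  )
}

# names of the descriptor columns of an otl_descriptors tibble
descriptor_cols <- function(dm) {
  grep("^d[0-9]+$", names(dm), value = TRUE)
}

descriptor_values <- function(dm) {
  as.matrix(dm[descriptor_cols(dm)])
}

#' Mean shape of a label group
#'
#' Reconstructs the outline of the column-wise mean descriptor vector of one
#' shape group, with the three normalization constants (`a1 = 1`,
#' `b1 = c1 = 0`) restored.
#'
#' @param dm An `otl_descriptors` tibble (see [descriptor_matrix()]).
#' @param label The shape label to average.
#' @param n_points Points in the reconstructed outline.
#' @return An [outline()].
#' @export
group_mean_shape <- function(dm, label, n_points = 256L) {
  rows <- dm$label == label
  if (!any(rows)) stop("no specimens with label '", label, "'")
  v <- colMeans(descriptor_values(dm)[rows, , drop = FALSE])
  efa_inverse(efd_from_free(v, attr(dm, "n_harmonics")), n_points)
}
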