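#' Read a grayscale image
#'
#' Reads an 8-bit grayscale PNG or TIFF into an intensity matrix on the 0-255
#' scale (rows are image rows, top first). Multi-channel images are averaged
#' to one channel.
#'
#' @param path Path to a `.png` or `.tif`/`.tiff` file.
#' @return A numeric matrix of intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  img * 255
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing between-class variance, used when no
#' threshold is supplied to [extract_outline()] (thresholding otolith images
#' is otherwise operator-dependent).
#'
#' @param image Numeric intensity matrix.
#' @param n_bins Number of histogram bins.
#' @return A threshold on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) stop("image has constant intensity; cannot threshold")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Extract the boundary outline of the largest foreground object
#'
#' Thresholds a grayscale image (bright foreground on dark background), keeps
#' the largest 8-connected foreground component, and traces its outer boundary
#' with Moore neighbor tracing. Pixel centers are reported in math convention
#' (x right, y up, 0-based), so the returned outline is counterclockwise.
#'
#' @param image Numeric intensity matrix (rows top-first), e.g. from
#'   [read_gray_image()].
#' @param threshold Intensity above which a pixel is foreground; defaults to
#'   [otsu_threshold()].
#' @return An [outline()] through the boundary pixel centers.
#' @export
extract_outline <- function(image, threshold = NULL) {
  stopifnot(is.matrix(image), nrow(image) >= 3, ncol(image) >= 3)
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  mask <- image > threshold
  if (!any(mask)) stop("empty mask: no foreground pixels above threshold")
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)])) {
    warning("foreground touches the image border; outline may be clipped")
  }
  mask <- largest_component(mask)
  b <- moore_trace(mask)
  # image (row, col) -> math (x, y) with y up; clockwise in image coordinates
  # becomes counterclockwise after the flip, which outline() enforces anyway
  outline(x = b[, 2] - 1, y = nrow(mask) - b[, 1])
}

# keep only the largest 8-connected TRUE component (iterative flood fill)
largest_component <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  cur <- 0L
  sizes <- integer(0)
  todo <- which(mask)
  stack <- integer(length(todo))
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    top <- 1L
    stack[1L] <- s
    size <- 0L
    while (top > 0L) {
      p <- stack[top]
      top <- top - 1L
      size <- size + 1L
      r <- ((p - 1L) %% nr) + 1L
      cand <- p + nbr
      ok <- rep(TRUE, 8L)
      if (r == 1L) ok[c(1L, 5L, 7L)] <- FALSE
      if (r == nr) ok[c(2L, 6L, 8L)] <- FALSE
      cand <- cand[ok]
      cand <- cand[cand >= 1L & cand <= nr * nc]
      cand <- cand[mask[cand] & lab[cand] == 0L]
      if (length(cand)) {
        lab[cand] <- cur
        stack[(top + 1L):(top + length(cand))] <- cand
        top <- top + length(cand)
      }
    }
    sizes[cur] <- size
  }
  lab == which.max(sizes)
}

# Moore boundary tracing (8-connectivity, clockwise in image coordinates)
# returns a matrix of (row, col) boundary pixel positions
moore_trace <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  # start: first foreground pixel in raster order (row-wise, top-left first)
  start <- NULL
  for (r in seq_len(nr)) {
    cs <- which(mask[r, ])
    if (length(cs)) {
      start <- c(r, cs[1])
      break
    }
  }
  # Moore neighborhood, clockwise starting from west
  moves <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                    0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                  ncol = 2L, byrow = TRUE)
  path <- matrix(0L, nrow = 4L * sum(mask) + 8L, ncol = 2L)
  path[1L, ] <- start
  np <- 1L
  cur <- start
  dir <- 1L  # backtrack is west of start (raster-order start guarantees it)
  start_dir <- NA_integer_
  repeat {
    found <- FALSE
    for (k in 0L:7L) {
      d <- ((dir - 1L + k) %% 8L) + 1L
      r2 <- cur[1] + moves[d, 1]
      c2 <- cur[2] + moves[d, 2]
      if (at(r2, c2)) {
        if (np == 1L) start_dir <- d
        # stopping rule: back at start, about to leave in the same direction
        if (np > 1L && cur[1] == start[1] && cur[2] == start[2] && d == start_dir) {
          return(path[seq_len(np - 1L), , drop = FALSE])
        }
        cur <- c(r2, c2)
        np <- np + 1L
        path[np, ] <- cur
        # next search starts from the neighbor after the backtrack pixel
        dir <- ((d - 1L + 6L) %% 8L) + 1L
        found <- TRUE
        break
      }
    }
    if (!found) return(path[1L, , drop = FALSE])  # isolated pixel
    if (np > 4L * sum(mask)) stop("boundary tracing failed to terminate")
  }
}

#' Smooth an outline by iterated cyclic averaging
#'
#' Each iteration replaces every vertex by the unweighted mean of itself and
#' its two cyclic neighbors. This softens pixel staircase artifacts and minor
#' edge crenulations; typical choices for otolith outlines are 0, 10, 20, or
#' 50 iterations.
#'
#' @param o An [outline()].
#' @param iterations Number of smoothing passes (>= 0).
#' @return A smoothed [outline()] with the same number of vertices.
#' @export
smooth_outline <- function(o, iterations) {
  o <- as_outline(o)
  stopifnot(length(iterations) == 1L, iterations >= 0)
  x <- o$x
  y <- o$y
  n <- length(x)
  prv <- c(n, seq_len(n - 1L))
  nxt <- c(seq_len(n - 1L) + 1L, 1L)
  for (i in seq_len(iterations)) {
    x <- (x[prv] + x + x[nxt]) / 3
    y <- (y[prv] + y + y[nxt]) / 3
  }
  # vertex count is preserved even when heavy smoothing collapses the
  # outline toward its centroid, so bypass the duplicate-vertex filter
  tibble::new_tibble(list(x = x, y = y), class = "otl_outline")
}

#' Resample an outline to equal arc-length spacing and normalize position/size
#'
#' Resamples the closed polygon to `n_points` vertices equally spaced by arc
#' length (starting at the first input vertex), translates the vertex centroid
#' to the origin, and scales to unit centroid size (root mean squared vertex
#' distance from the centroid). This is the alignment applied before
#' elliptical Fourier analysis.
#'
#' @param o An [outline()].
#' @param n_points Number of output vertices (>= 16).
#' @return A centered, unit-centroid-size [outline()].
#' @export
resample_and_center <- function(o, n_points = 256L) {
  o <- as_outline(o)
  stopifnot(n_points >= 16)
  x <- c(o$x, o$x[1])
  y <- c(o$y, o$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  per <- sum(seg)
  if (per <= 0) stop("degenerate outline with zero perimeter")
  s <- c(0, cumsum(seg))
  target <- seq(0, per, length.out = n_points + 1L)[-(n_points + 1L)]
  xi <- stats::approx(s, x, xout = target, ties = "ordered")$y
  yi <- stats::approx(s, y, xout = target, ties = "ordered")$y
  xi <- xi - mean(xi)
  yi <- yi - mean(yi)
  cs <- sqrt(mean(xi^2 + yi^2))
  if (cs <= 0) stop("degenerate outline collapses to a point")
  outline(xi / cs, yi / cs, enforce_ccw = FALSE)
}

#' Classical morphometric measurements of an outline
#'
#' Computes area (shoelace), perimeter, Feret length and width (caliper
#' extents over all directions: the maximum pairwise convex-hull distance and
#' the minimum projected extent over a 0.5 degree direction sweep), and the
#' major/minor axes (longest chord constrained to pass through the center of
#' mass, and the chord through the center of mass perpendicular to it).
#'
#' @param o An [outline()].
#' @param scale Physical units per coordinate unit (e.g. mm per pixel);
#'   lengths scale linearly, the area quadratically. Default 1 (pixel units).
#' @param otolith_mass Optional mass (g) carried through to the output.
#' @param check_simple Verify the outline is non-self-intersecting first.
#' @return A one-row tibble: `area`, `perimeter`, `feret_length`,
#'   `feret_width`, `major_axis`, `minor_axis`, `otolith_mass`.
#' @export
measure_morphometrics <- function(o, scale = 1, otolith_mass = NA_real_,
                                  check_simple = TRUE) {
  o <- as_outline(o)
  if (check_simple && !is_simple_outline(o)) {
    stop("outline is self-intersecting; morphometrics are undefined")
  }
  hull_idx <- grDevices::chull(o$x, o$y)
  hx <- o$x[hull_idx]
  hy <- o$y[hull_idx]
  feret_len <- sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2))
  angles <- seq(0, pi, by = pi / 360)[-361]  # 0.5 degree sweep over [0, 180)
  ca <- cos(angles)
  sa <- sin(angles)
  proj <- outer(hx, ca) + outer(hy, sa)  # hull points x angles
  extents <- apply(proj, 2, max) - apply(proj, 2, min)
  feret_wid <- min(extents)
  ax <- axes_through_centroid(o, angles)
  tibble::tibble(
    area = outline_area(o) * scale^2,
    perimeter = outline_perimeter(o) * scale,
    feret_length = feret_len * scale,
    feret_width = feret_wid * scale,
    major_axis = unname(ax["major"]) * scale,
    minor_axis = unname(ax["minor"]) * scale,
    otolith_mass = otolith_mass
  )
}

# longest chord through the region's center of mass, plus the chord
# perpendicular to it, via a direction sweep
axes_through_centroid <- function(o, angles) {
  ctr <- region_centroid(o)
  x <- o$x - ctr[1]
  y <- o$y - ctr[2]
  n <- length(x)
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  chord_at <- function(theta) {
    ux <- cos(theta)
    uy <- sin(theta)
    c1 <- ux * y - uy * x
    c2 <- ux * y2 - uy * x2
    hit <- (c1 * c2 <= 0) & (c1 != c2)
    if (!any(hit)) return(0)
    s <- c1[hit] / (c1[hit] - c2[hit])
    px <- x[hit] + s * (x2[hit] - x[hit])
    py <- y[hit] + s * (y2[hit] - y[hit])
    t <- px * ux + py * uy
    max(t) - min(t)
  }
  chords <- vapply(angles, chord_at, numeric(1))
  k <- which.max(chords)
  major <- chords[k]
  minor <- chord_at(angles[k] + pi / 2)
  c(major = major, minor = minor)
}
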