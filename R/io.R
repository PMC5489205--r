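#' Write and read outline CSV files
#'
#' Outlines are exchanged as long-format CSV with columns `specimen_id`,
#' `vertex_index`, `x`, `y`.
#'
#' @param outlines A named list of [outline()]s.
#' @param path CSV file path.
#' @return `write_outlines()` returns `path` invisibly; `read_outlines()`
#'   returns a named list of outlines.
#' @export
write_outlines <- function(outlines, path) {
  stopifnot(length(outlines) >= 1L, !is.null(names(outlines)))
  df <- purrr::imap_dfr(outlines, function(o, id) {
    tibble::tibble(specimen_id = id, vertex_index = seq_len(nrow(o)),
                   x = o$x, y = o$y)
  })
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outlines
#' @export
read_outlines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("specimen_id", "vertex_index", "x", "y") %in% names(df)))
  df <- df[order(df$specimen_id, df$vertex_index), ]
  split(df, df$specimen_id) |>
    lapply(function(d) outline(d$x, d$y))
}

#' Write a descriptor matrix CSV
#'
#' One row per specimen with columns `specimen_id`, `label`,
#' `feret_length`, `age`, `d1..dK`, matching the layout read back by
#' [read_descriptors()].
#'
#' @param dm An `otl_descriptors` tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(dm, path) {
  utils::write.csv(as.data.frame(dm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  k <- length(grep("^d[0-9]+$", names(df)))
  if (k == 0L || (k + 3L) %% 4L != 0L) {
    stop("descriptor CSV must carry 4H-3 columns named d1..dK")
  }
  attr(df, "n_harmonics") <- (k + 3L) %/% 4L
  class(df) <- c("otl_descriptors", class(df))
  df
}

#' Rasterize an outline to a binary image
#'
#' Scanline-fills the polygon into a matrix (white shape on black), for
#' round-trip testing of [extract_outline()] and for exporting synthetic
#' specimens as PNG.
#'
#' @param o An [outline()].
#' @param width,height Image size in pixels; default fits the outline with
#'   `margin` pixels of background.
#' @param margin Background margin in pixels.
#' @return A numeric matrix with values 0 (background) and 255 (shape),
#'   rows top-first as in [read_gray_image()].
#' @export
rasterize_outline <- function(o, width = NULL, height = NULL, margin = 8L) {
  o <- as_outline(o)
  xr <- range(o$x)
  yr <- range(o$y)
  width <- width %||% ceiling(diff(xr) + 2 * margin)
  height <- height %||% ceiling(diff(yr) + 2 * margin)
  # map outline into pixel space, y flipped to image convention
  px <- o$x - xr[1] + margin
  py <- o$y - yr[1] + margin
  img <- matrix(0, nrow = height, ncol = width)
  x1 <- px
  y1 <- py
  x2 <- c(px[-1], px[1])
  y2 <- c(py[-1], py[1])
  for (r in seq_len(height)) {
    yc <- height - r + 0.5  # pixel-center y in math convention
    hit <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(hit)) next
    xs <- sort(x1[hit] + (yc - y1[hit]) / (y2[hit] - y1[hit]) * (x2[hit] - x1[hit]))
    for (j in seq(1, length(xs) - 1, by = 2)) {
      c1 <- max(1L, ceiling(xs[j] + 0.5))
      c2 <- min(width, floor(xs[j + 1] + 0.5))
      if (c2 >= c1) img[r, c1:c2] <- 255
    }
  }
  img
}

#' Write an intensity matrix as 8-bit grayscale PNG
#'
#' @param image Numeric matrix on the 0-255 scale.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
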