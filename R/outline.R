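#' Construct a closed outline
#'
#' An outline is an ordered sequence of distinct (x, y) vertices describing a
#' simple closed polygon; the closing edge from the last vertex back to the
#' first is implicit. Outlines are stored as tibbles with columns `x` and `y`
#' and class `otl_outline` so they flow through dplyr pipelines unchanged.
#'
#' @param x,y Numeric vertex coordinates of equal length (>= 3).
#' @param enforce_ccw Reverse the vertex order if the polygon is traversed
#'   clockwise (negative signed area). Default `TRUE`.
#' @return A tibble of class `otl_outline` with columns `x`, `y`.
#' @examples
#' sq <- outline(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' outline_area(sq)
#' @export
outline <- function(x, y, enforce_ccw = TRUE) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (anyNA(x) || anyNA(y)) stop("outline coordinates must not contain NA")
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]
    y <- y[-n]
    n <- n - 1L
  }
  if (n < 3) stop("an outline needs at least 3 distinct vertices")
  dup <- c(diff(x) == 0 & diff(y) == 0, FALSE)
  if (any(dup)) {
    x <- x[!dup]
    y <- y[!dup]
  }
  if (length(x) < 3) stop("an outline needs at least 3 distinct vertices")
  if (enforce_ccw && signed_area(x, y) < 0) {
    x <- rev(x)
    y <- rev(y)
  }
  tibble::new_tibble(list(x = as.numeric(x), y = as.numeric(y)),
                     class = "otl_outline")
}

#' @export
#' @rdname outline
#' @param data A data frame with columns `x` and `y`.
as_outline <- function(data, enforce_ccw = TRUE) {
  if (inherits(data, "otl_outline")) return(data)
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  outline(data$x, data$y, enforce_ccw = enforce_ccw)
}

is_outline <- function(o) inherits(o, "otl_outline")

# signed (shoelace) area; positive for counterclockwise traversal
signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Enclosed area of an outline
#'
#' Shoelace area of the closed polygon (always positive for outlines, which
#' are stored counterclockwise).
#'
#' @param o An [outline()].
#' @return Area in squared coordinate units.
#' @export
outline_area <- function(o) abs(signed_area(o$x, o$y))

#' Perimeter of an outline
#'
#' @param o An [outline()].
#' @return Summed edge lengths of the closed polygon.
#' @export
outline_perimeter <- function(o) {
  sum(sqrt(diff(c(o$x, o$x[1]))^2 + diff(c(o$y, o$y[1]))^2))
}

# centroid of the vertex set (the morphometric "centroid" used for alignment
# and centroid size); the region's center of mass is `region_centroid()`
point_centroid <- function(o) c(mean(o$x), mean(o$y))

# center of mass of the enclosed region (polygon area centroid)
region_centroid <- function(o) {
  x <- o$x
  y <- o$y
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(point_centroid(o))
  cx <- sum((x[j] + x) * cr) / (6 * a)
  cy <- sum((y[j] + y) * cr) / (6 * a)
  c(cx, cy)
}

# centroid size: root mean squared vertex distance to the vertex centroid
centroid_size <- function(o) {
  ctr <- point_centroid(o)
  sqrt(mean((o$x - ctr[1])^2 + (o$y - ctr[2])^2))
}

#' Test whether an outline is a simple (non-self-intersecting) polygon
#'
#' Pairwise segment-intersection check over all non-adjacent edge pairs.
#'
#' @param o An [outline()].
#' @return `TRUE` if no two non-adjacent edges intersect.
#' @export
is_simple_outline <- function(o) {
  x <- o$x
  y <- o$y
  n <- length(x)
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  idx <- utils::combn(n, 2L)
  i <- idx[1L, ]
  j <- idx[2L, ]
  adjacent <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adjacent]
  j <- j[!adjacent]
  if (length(i) == 0L) return(TRUE)
  !any(segments_cross(x[i], y[i], x2[i], y2[i], x[j], y[j], x2[j], y2[j]))
}

# vectorized proper/improper segment intersection test
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o1 <- orient(ax, ay, bx, by, cx, cy)
  o2 <- orient(ax, ay, bx, by, dx, dy)
  o3 <- orient(cx, cy, dx, dy, ax, ay)
  o4 <- orient(cx, cy, dx, dy, bx, by)
  proper <- (o1 * o2 < 0) & (o3 * o4 < 0)
  # collinear overlap / endpoint touching counts as a crossing
  touch <- (o1 == 0 & on_segment(ax, ay, bx, by, cx, cy)) |
    (o2 == 0 & on_segment(ax, ay, bx, by, dx, dy)) |
    (o3 == 0 & on_segment(cx, cy, dx, dy, ax, ay)) |
    (o4 == 0 & on_segment(cx, cy, dx, dy, bx, by))
  proper | touch
}

orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  sign(v)
}

on_segment <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) & px <= pmax(ax, bx) &
    py >= pmin(ay, by) & py <= pmax(ay, by)
}

#' @export
print.otl_outline <- function(x, ...) {
  cat(sprintf("# Outline: %d vertices, area %.4g, perimeter %.4g\n",
              nrow(x), outline_area(x), outline_perimeter(x)))
  NextMethod()
}

#' Plot an outline
#'
#' @param object An [outline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot otl_outline
#' @export
autoplot.otl_outline <- function(object, ...) {
  df <- tibble::tibble(x = c(object$x, object$x[1]),
                       y = c(object$y, object$y[1]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
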