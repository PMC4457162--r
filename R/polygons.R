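# Polygon utilities shared by region measurement and pattern-area metrics.
# Polygons are n x 2 matrices of (x, y) vertices in pixel coordinates
# (1-based, pixel centres at integers internally; the JSON interchange
# format is 0-based and converted on read/write).

#' Rectangle polygon helper
#'
#' @param x0,y0 Top-left corner (1-based pixel coordinates).
#' @param w,h Width and height in pixels.
#' @return A 4 x 2 vertex matrix (counter-clockwise).
#' @export
rect_polygon <- function(x0, y0, w, h) {
  cbind(x = c(x0 - 0.5, x0 + w - 0.5, x0 + w - 0.5, x0 - 0.5),
        y = c(y0 - 0.5, y0 - 0.5, y0 + h - 0.5, y0 + h - 0.5))
}

# Even-odd point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise a polygon to a pixel mask
#'
#' Tests pixel centres against the polygon (even-odd rule).
#'
#' @param poly Vertex matrix (n x 2, columns x then y).
#' @param width,height Image dimensions in pixels.
#' @return Logical matrix `height x width` (row = y, column = x).
#' @export
polygon_mask <- function(poly, width, height) {
  stopifnot(nrow(poly) >= 3)
  xs <- seq_len(width); ys <- seq_len(height)
  # restrict to bounding box for speed
  xr <- xs[xs >= floor(min(poly[, 1])) & xs <= ceiling(max(poly[, 1]))]
  yr <- ys[ys >= floor(min(poly[, 2])) & ys <= ceiling(max(poly[, 2]))]
  m <- matrix(FALSE, height, width)
  if (!length(xr) || !length(yr)) return(m)
  g <- expand.grid(x = xr, y = yr)
  inside <- points_in_polygon(g$x, g$y, poly)
  m[cbind(g$y[inside], g$x[inside])] <- TRUE
  m
}

# Do two closed segments properly intersect (excluding shared endpoints)?
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Is a polygon simple (non-self-intersecting)?
#'
#' @param poly Vertex matrix (n x 2).
#' @return TRUE/FALSE.
#' @export
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  idx <- rbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (abs(i - j) <= 1L || (i == 1L && j == n)) next
      if (.segments_cross(poly[idx[1, i], ], poly[idx[2, i], ],
                          poly[idx[1, j], ], poly[idx[2, j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Shoelace area of a simple polygon
#'
#' @param poly Vertex matrix (n x 2).
#' @return Area in squared vertex units (always >= 0).
#' @export
polygon_area_px <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}
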