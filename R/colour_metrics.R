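# Single-stimulus signal attributes: tetrahedral colour space, saturation,
# luminance and pattern area.

#' Vertices of the avian tetrahedral colour space
#'
#' Convention used throughout the package: a regular tetrahedron centred
#' on the achromatic origin with circumradius `r` (default 0.75, so a pure
#' single-cone stimulus has saturation 0.75). The UV vertex sits on the
#' positive z axis; SW, MW, LW lie in the `z = -r/3` plane at azimuths 0,
#' 120 and 240 degrees.
#'
#' @param r Circumradius (default 0.75).
#' @return 4 x 3 matrix with rows `uv, sw, mw, lw` and columns `x, y, z`.
#' @export
tetra_vertices <- function(r = 0.75) {
  rho <- r * 2 * sqrt(2) / 3
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  v <- rbind(uv = c(0, 0, r),
             sw = c(rho * cos(ang[1]), rho * sin(ang[1]), -r / 3),
             mw = c(rho * cos(ang[2]), rho * sin(ang[2]), -r / 3),
             lw = c(rho * cos(ang[3]), rho * sin(ang[3]), -r / 3))
  colnames(v) <- c("x", "y", "z")
  v
}

#' Map a cone catch to tetrahedral colour space
#'
#' Relative catches `u, s, m, l` (the four single cones normalised to sum
#' 1) weight the tetrahedron vertices; the achromatic point (equal
#' catches) maps to the origin.
#'
#' @param catch A [cone_catch()] (double cone ignored).
#' @param r Tetrahedron circumradius (default 0.75).
#' @return Object of class `tetra_point`: list with `xyz` (length-3) and
#'   `rel` (u, s, m, l summing to 1).
#' @export
to_tetrahedral <- function(catch, r = 0.75) {
  q <- unclass(catch)[c("uv", "sw", "mw", "lw")]
  tot <- sum(q)
  if (!is.finite(tot) || tot <= 0) stop("zero or invalid total catch")
  rel <- q / tot
  xyz <- drop(rel %*% tetra_vertices(r))
  structure(list(xyz = xyz, rel = rel, r = r), class = "tetra_point")
}

#' @export
print.tetra_point <- function(x, ...) {
  cat(sprintf("<tetra_point> xyz=(%.4f, %.4f, %.4f) sat=%.4f\n",
              x$xyz[1], x$xyz[2], x$xyz[3], saturation(x)))
  invisible(x)
}

#' Saturation: distance from the achromatic centre
#'
#' Euclidean norm of the tetrahedral position; 0 for achromatic stimuli,
#' bounded above by the circumradius (0.75 by default). Invariant to
#' overall intensity scaling of the catches.
#'
#' @param point A [to_tetrahedral()] point or a [cone_catch()].
#' @return Non-negative scalar.
#' @export
saturation <- function(point) {
  if (inherits(point, "cone_catch")) point <- to_tetrahedral(point)
  stopifnot(inherits(point, "tetra_point"))
  sqrt(sum(point$xyz^2))
}

#' Luminance: the double-cone catch
#'
#' Avian achromatic perception is modelled by the double cones, so
#' luminance is simply the double-cone quantum catch.
#'
#' @param catch A [cone_catch()] with a double-cone value.
#' @return Non-negative scalar.
#' @export
luminance <- function(catch) {
  q <- unclass(catch)
  if (!"dbl" %in% names(q) || is.na(q[["dbl"]])) {
    stop("double-cone catch missing")
  }
  q[["dbl"]]
}

#' Pattern area from a polygon and a scale
#'
#' Shoelace area of a simple polygon traced on the photo, converted to
#' square centimetres using the pixels-per-cm scale in the frame.
#'
#' @param polygon Vertex matrix (n x 2, pixel coordinates).
#' @param scale Pixels per centimetre (> 0).
#' @return Area in cm^2.
#' @export
pattern_area <- function(polygon, scale) {
  if (!is.matrix(polygon) || ncol(polygon) != 2 || nrow(polygon) < 3) {
    stop("polygon must be an n x 2 vertex matrix, n >= 3")
  }
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("scale must be a positive pixels-per-cm value")
  }
  if (!is_simple_polygon(polygon)) stop("polygon is self-intersecting")
  polygon_area_px(polygon) / scale^2
}
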