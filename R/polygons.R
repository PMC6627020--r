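#' @title Polygon primitives
#' @description Closed polygons are represented as a list with numeric
#' vectors `x` and `y` (the polyclip convention); the closing edge from the
#' last vertex back to the first is implicit. Vertices may run clockwise or
#' counter-clockwise; all area-based quantities use the absolute value of
#' the signed (shoelace) area.
#' @name polygons
NULL

as_polygon <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) p <- list(x = p[, 1], y = p[, 2])
  stopifnot(is.list(p), length(p$x) == length(p$y))
  list(x = as.numeric(p$x), y = as.numeric(p$y))
}

# signed shoelace area; positive for counter-clockwise in a y-up frame
poly_area_signed <- function(p) {
  p <- as_polygon(p)
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (absolute)
#'
#' @param p polygon as `list(x, y)` or a two-column matrix.
#' @return Absolute enclosed area in squared input units.
#' @export
poly_area <- function(p) abs(poly_area_signed(p))

#' Polygon perimeter
#'
#' @inheritParams poly_area
#' @return Total boundary length, including the implicit closing edge.
#' @export
poly_perimeter <- function(p) {
  p <- as_polygon(p)
  dx <- diff(c(p$x, p$x[1])); dy <- diff(c(p$y, p$y[1]))
  sum(sqrt(dx^2 + dy^2))
}

#' Polygon area centroid
#'
#' @inheritParams poly_area
#' @return Numeric `c(x, y)`: centroid of the enclosed region (not the
#'   vertex mean).
#' @export
poly_centroid <- function(p) {
  p <- as_polygon(p)
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) {
    stop("degenerate polygon: zero area")
  }
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Translate / rotate polygons
#'
#' `poly_translate` shifts a polygon by `(dx, dy)`; `poly_rotate` rotates it
#' by `angle_deg` degrees (counter-clockwise in a y-up frame) about `center`
#' (default: its own area centroid).
#'
#' @inheritParams poly_area
#' @param dx,dy translation offsets.
#' @param angle_deg rotation angle in degrees.
#' @param center length-2 rotation center; defaults to the area centroid.
#' @return The transformed polygon.
#' @export
poly_translate <- function(p, dx, dy) {
  p <- as_polygon(p)
  list(x = p$x + dx, y = p$y + dy)
}

#' @rdname poly_translate
#' @export
poly_rotate <- function(p, angle_deg, center = NULL) {
  p <- as_polygon(p)
  if (is.null(center)) center <- poly_centroid(p)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  x0 <- p$x - center[1]; y0 <- p$y - center[2]
  list(x = center[1] + ct * x0 - st * y0,
       y = center[2] + st * x0 + ct * y0)
}

#' Intersection area of two polygons
#'
#' Exact boolean intersection via polygon clipping (Clipper); works for any
#' simple polygons, convex or not.
#'
#' @param a,b polygons as `list(x, y)`.
#' @return Total area of the intersection region (0 when disjoint).
#' @export
poly_intersection_area <- function(a, b) {
  pieces <- polyclip::polyclip(as_polygon(a), as_polygon(b), op = "intersection")
  if (length(pieces) == 0L) return(0)
  sum(vapply(pieces, poly_area, numeric(1)))
}

#' Second-moment (equivalent-ellipse) axes of a polygon
#'
#' Computes the central second area moments of the enclosed region by exact
#' integration over the polygon and returns the semi-axes of the ellipse
#' with the same moments. For an actual ellipse this recovers its semi-axes.
#'
#' @inheritParams poly_area
#' @return List with `major`, `minor` (semi-axis lengths) and `theta`
#'   (major-axis orientation, radians).
#' @export
poly_ellipse_axes <- function(p) {
  p <- as_polygon(p)
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) stop("degenerate polygon: zero area")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # second moments about the origin, then shifted to the centroid
  ixx <- sum(cr * (y^2 + y * yn + yn^2)) / 12
  iyy <- sum(cr * (x^2 + x * xn + xn^2)) / 12
  ixy <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  ixx <- ixx - a * cy^2
  iyy <- iyy - a * cx^2
  ixy <- ixy - a * cx * cy
  # covariance of the uniform density over the region
  cov <- matrix(c(iyy, ixy, ixy, ixx), 2, 2) / a
  e <- eigen(cov, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(major = 2 * sqrt(lam[1]), minor = 2 * sqrt(lam[2]),
       theta = atan2(e$vectors[2, 1], e$vectors[1, 1]))
}

# min and max distance from a point to the polygon boundary; the minimum
# checks perpendicular feet on every edge, the maximum is attained at a vertex
poly_boundary_radii <- function(p, pt) {
  p <- as_polygon(p)
  x1 <- p$x; y1 <- p$y
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- ((pt[1] - x1) * vx + (pt[2] - y1) * vy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  fx <- x1 + t * vx; fy <- y1 + t * vy
  dmin <- sqrt(min((pt[1] - fx)^2 + (pt[2] - fy)^2))
  dmax <- sqrt(max((pt[1] - x1)^2 + (pt[2] - y1)^2))
  c(min = dmin, max = dmax)
}

#' Reference polygon constructors
#'
#' Analytic test shapes: `polygon_circle` returns a regular `n`-gon
#' approximation of a circle; `polygon_ellipse` a polygonized axis-aligned
#' ellipse; `polygon_rectangle` an axis-aligned rectangle; and
#' `polygon_annulus` a thin ring represented as a single simple polygon via
#' a narrow radial slit (outer boundary traversed one way, inner boundary
#' the other).
#'
#' @param center length-2 center.
#' @param radius,r_outer,r_inner radii.
#' @param a,b ellipse semi-axes; `width,height` rectangle sides.
#' @param width,height rectangle side lengths.
#' @param n vertices per full circle.
#' @return A polygon as `list(x, y)`.
#' @export
polygon_circle <- function(radius = 1, center = c(0, 0), n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

#' @rdname polygon_circle
#' @export
polygon_ellipse <- function(a = 2, b = 1, center = c(0, 0), n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = center[1] + a * cos(th), y = center[2] + b * sin(th))
}

#' @rdname polygon_circle
#' @export
polygon_rectangle <- function(width = 1, height = 1, center = c(0, 0)) {
  w <- width / 2; h <- height / 2
  list(x = center[1] + c(-w, w, w, -w), y = center[2] + c(-h, -h, h, h))
}

#' @rdname polygon_circle
#' @export
polygon_annulus <- function(r_outer = 2, r_inner = 1.5, center = c(0, 0),
                            n = 180L) {
  stopifnot(r_outer > r_inner, r_inner > 0)
  slit <- 1e-3 * 2 * pi / n
  th_out <- seq(slit, 2 * pi - slit, length.out = n)
  th_in <- rev(th_out)
  list(x = center[1] + c(r_outer * cos(th_out), r_inner * cos(th_in)),
       y = center[2] + c(r_outer * sin(th_out), r_inner * sin(th_in)))
}
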