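#' Shape components of the nuclear irregularity index
#'
#' Computes the four dimensionless descriptors that quantify how far a
#' nuclear outline deviates from a circle:
#' \describe{
#'   \item{aspect}{major/minor semi-axis ratio of the second-moment
#'     equivalent ellipse (>= 1).}
#'   \item{area_box}{object area divided by the area of its axis-aligned
#'     bounding box (in (0, 1]; pi/4 for a circle, 1 for an axis-aligned
#'     rectangle). Orientation-sensitive by construction.}
#'   \item{radius_ratio}{maximum over minimum Euclidean distance from the
#'     area centroid to the boundary (>= 1).}
#'   \item{roundness}{perimeter^2 / (4 pi area) (1 for a circle, > 1
#'     otherwise in the continuum limit).}
#' }
#'
#' @param outline closed simple polygon as `list(x, y)` (see [polygons]).
#' @return A list of class `nii_components` with fields `aspect`,
#'   `area_box`, `radius_ratio`, `roundness`, plus `area` and `perimeter`
#'   in input units.
#' @examples
#' comp <- nii_components(polygon_circle(n = 3600))
#' nii(comp)  # 2.2146 for a circle
#' @export
nii_components <- function(outline) {
  p <- as_polygon(outline)
  if (length(p$x) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  a <- poly_area(p)
  if (a <= 0 || !is.finite(a)) stop("degenerate polygon: zero area")
  per <- poly_perimeter(p)
  ax <- poly_ellipse_axes(p)
  cen <- poly_centroid(p)
  rad <- poly_boundary_radii(p, cen)
  bbox <- (max(p$x) - min(p$x)) * (max(p$y) - min(p$y))
  structure(list(
    aspect = ax$major / ax$minor,
    area_box = a / bbox,
    radius_ratio = rad[["max"]] / rad[["min"]],
    roundness = per^2 / (4 * pi * a),
    area = a,
    perimeter = per
  ), class = "nii_components")
}

#' Nuclear irregularity index (NII)
#'
#' Combines the four shape components into a single index:
#' `NII = aspect - area_box + radius_ratio + roundness`.
#' A perfect circle scores `1 - pi/4 + 1 + 1 = 2.2146`; any deviation from
#' circularity increases the index.
#'
#' @param components a `nii_components` object, or a polygon (in which case
#'   components are computed first).
#' @return The NII, a dimensionless scalar >= ~2.2146.
#' @export
nii <- function(components) {
  if (!inherits(components, "nii_components")) {
    components <- nii_components(components)
  }
  with(components, aspect - area_box + radius_ratio + roundness)
}

#' Per-frame NII track and summaries
#'
#' Applies [nii_components()] and [nii()] to every outline of a shape
#' sequence and derives the per-step shape-change series delta-NII.
#'
#' @param x a `shape_sequence` (see [track_single_nucleus()]) or a list of
#'   polygons.
#' @param cell_id identifier copied into the output table.
#' @return A list of class `shape_metrics_track` with `table` (one row per
#'   frame: frame, time_min, aspect, area_box, radius_ratio, roundness,
#'   nii, delta_nii where delta_nii in row t is |NII(t) - NII(t-1)|, NA in
#'   the first row), `mean_nii`, and `mean_delta_nii`. Steps flagged as
#'   gap-interpolated in the input sequence are excluded from the means.
#' @export
shape_metrics_track <- function(x, cell_id = "cell1") {
  outlines <- if (inherits(x, "shape_sequence")) x$outlines else x
  times <- if (inherits(x, "shape_sequence")) x$times_min else seq_along(outlines) - 1
  frames <- if (inherits(x, "shape_sequence")) x$frames else seq_along(outlines)
  gaps <- if (inherits(x, "shape_sequence")) x$gap_interpolated else
    rep(FALSE, length(outlines))
  comp <- lapply(outlines, nii_components)
  nii_v <- vapply(comp, nii, numeric(1))
  d <- delta_nii_series(nii_v)
  tab <- data.frame(
    cell_id = cell_id,
    frame = frames,
    time_min = times,
    aspect = vapply(comp, `[[`, numeric(1), "aspect"),
    area_box = vapply(comp, `[[`, numeric(1), "area_box"),
    radius_ratio = vapply(comp, `[[`, numeric(1), "radius_ratio"),
    roundness = vapply(comp, `[[`, numeric(1), "roundness"),
    nii = nii_v,
    delta_nii = c(NA, d$delta_nii),
    gap_interpolated = gaps
  )
  # a gap-interpolated frame invalidates the steps on both of its sides
  step_valid <- !(gaps[-1] | gaps[-length(gaps)])
  structure(list(
    table = tab,
    mean_nii = mean(nii_v[!gaps]),
    mean_delta_nii = mean(d$delta_nii[step_valid])
  ), class = "shape_metrics_track")
}

#' Frame-to-frame shape change (delta-NII)
#'
#' Step `t` is `|NII(t+1) - NII(t)|`: rapid shape change in either
#' direction gives a large delta-NII. The signed differences are returned
#' alongside (rounding events are negative signed changes).
#'
#' @param nii_track numeric vector of per-frame NII values (>= 2 frames).
#' @return List with `delta_nii` (absolute differences, length n-1),
#'   `signed` (signed differences) and `mean_delta_nii`.
#' @export
delta_nii_series <- function(nii_track) {
  if (length(nii_track) < 2L) stop("delta-NII needs at least 2 frames")
  s <- diff(nii_track)
  list(delta_nii = abs(s), signed = s, mean_delta_nii = mean(abs(s)))
}

#' Per-frame roundness
#'
#' Roundness (`perimeter^2 / (4 pi area)`) alone, as a simpler comparison
#' metric to the full NII.
#'
#' @param outlines list of polygons or a `shape_sequence`.
#' @return Numeric vector of per-frame roundness values.
#' @export
roundness_track <- function(outlines) {
  if (inherits(outlines, "shape_sequence")) outlines <- outlines$outlines
  vapply(outlines, function(p) nii_components(p)$roundness, numeric(1))
}

#' Write a shape-metrics table to CSV
#'
#' @param track a `shape_metrics_track`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shape_metrics <- function(track, path) {
  utils::write.csv(track$table, path, row.names = FALSE)
  invisible(path)
}
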