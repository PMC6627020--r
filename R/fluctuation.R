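#' Raw fluctuation statistic
#'
#' The shape-dissimilarity statistic
#' `(A1 + A2 - 2 |A1 intersect A2|) / (A1 + A2)` evaluated on two polygons
#' as placed, with no alignment or rotation: 0 means identical placement and
#' shape, 1 means no overlap. Equals `1 - Dice` for the two regions.
#'
#' @param shape_a,shape_b simple polygons as `list(x, y)`.
#' @return Fluctuation in \[0, 1\].
#' @export
fluctuation_raw <- function(shape_a, shape_b) {
  a1 <- poly_area(shape_a); a2 <- poly_area(shape_b)
  if (a1 <= 0 || a2 <= 0) stop("degenerate polygon: zero area")
  inter <- poly_intersection_area(shape_a, shape_b)
  min(max((a1 + a2 - 2 * inter) / (a1 + a2), 0), 1)
}

#' Rotational maximum-overlap fluctuation
#'
#' Aligns the centroid of `shape_b` onto that of `shape_a`, then rotates
#' `shape_b` about the common centroid through a full circle in steps of
#' `step_deg` degrees (default 1), computing the exact polygon intersection
#' area at every angle. The maximum intersection defines the fluctuation
#' `(A1 + A2 - 2 max|A1 intersect A2|) / (A1 + A2)`; ties are broken by the
#' smallest angle.
#'
#' @param shape_a,shape_b simple polygons, positive area.
#' @param step_deg rotation step in degrees; angles are every multiple of
#'   `step_deg` in `[0, 360)`.
#' @return A list of class `overlap_result` with `a1`, `a2`,
#'   `max_intersection`, `best_angle` (degrees), `fluctuation`, and
#'   `angles`/`intersections` (the full scan, for diagnostics).
#' @examples
#' d <- polygon_circle(radius = 5, n = 90)
#' rotational_max_overlap(d, d)$fluctuation  # ~0
#' @export
rotational_max_overlap <- function(shape_a, shape_b, step_deg = 1) {
  stopifnot(step_deg > 0, step_deg <= 360)
  a <- as_polygon(shape_a); b <- as_polygon(shape_b)
  a1 <- poly_area(a); a2 <- poly_area(b)
  if (a1 <= 0 || a2 <= 0) stop("degenerate polygon: zero area")
  ca <- poly_centroid(a); cb <- poly_centroid(b)
  b <- poly_translate(b, ca[1] - cb[1], ca[2] - cb[2])
  angles <- seq(0, 360 - step_deg, by = step_deg)
  inter <- vapply(angles, function(th) {
    poly_intersection_area(a, poly_rotate(b, th, center = ca))
  }, numeric(1))
  best <- which.max(inter)  # first maximum = smallest angle on ties
  fl <- min(max((a1 + a2 - 2 * inter[best]) / (a1 + a2), 0), 1)
  structure(list(
    a1 = a1, a2 = a2,
    max_intersection = inter[best],
    best_angle = angles[best],
    fluctuation = fl,
    angles = angles, intersections = inter
  ), class = "overlap_result")
}

#' Per-step fluctuation along a shape sequence
#'
#' Runs [rotational_max_overlap()] on every consecutive pair of outlines of
#' a tracked nucleus and summarises the track by the mean over valid steps.
#' Steps touching a gap-interpolated frame are flagged and excluded from
#' the mean.
#'
#' @param sequence a `shape_sequence` or plain list of polygons (>= 2).
#' @param step_deg rotation step in degrees.
#' @param pixel_size_um optional micron-per-pixel scale used to report
#'   areas in um^2; taken from the sequence when available.
#' @param cell_id identifier copied into the output table.
#' @return A list of class `fluctuation_track` with `table` (frame_pair,
#'   a1, a2, max_intersection, best_angle_deg, fluctuation,
#'   gap_interpolated) and `mean_fluctuation`.
#' @export
fluctuation_track <- function(sequence, step_deg = 1, pixel_size_um = NULL,
                              cell_id = "cell1") {
  is_seq <- inherits(sequence, "shape_sequence")
  outlines <- if (is_seq) sequence$outlines else sequence
  if (length(outlines) < 2L) stop("fluctuation needs at least 2 frames")
  gaps <- if (is_seq) sequence$gap_interpolated else rep(FALSE, length(outlines))
  if (is.null(pixel_size_um)) {
    pixel_size_um <- if (is_seq) sequence$pixel_size_um else 1
  }
  n <- length(outlines)
  res <- lapply(seq_len(n - 1L), function(i) {
    rotational_max_overlap(outlines[[i]], outlines[[i + 1L]], step_deg)
  })
  sc <- pixel_size_um^2
  step_gap <- gaps[-n] | gaps[-1]
  tab <- data.frame(
    cell_id = cell_id,
    frame_pair = paste(seq_len(n - 1L), seq_len(n - 1L) + 1L, sep = "-"),
    a1 = vapply(res, `[[`, numeric(1), "a1") * sc,
    a2 = vapply(res, `[[`, numeric(1), "a2") * sc,
    max_intersection = vapply(res, `[[`, numeric(1), "max_intersection") * sc,
    best_angle_deg = vapply(res, `[[`, numeric(1), "best_angle"),
    fluctuation = vapply(res, `[[`, numeric(1), "fluctuation"),
    gap_interpolated = step_gap
  )
  structure(list(
    table = tab,
    mean_fluctuation = mean(tab$fluctuation[!step_gap])
  ), class = "fluctuation_track")
}

#' Write a fluctuation table to CSV
#'
#' @param track a `fluctuation_track`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fluctuation <- function(track, path) {
  utils::write.csv(track$table, path, row.names = FALSE)
  invisible(path)
}
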