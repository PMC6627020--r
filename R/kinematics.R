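#' Centroid trajectory
#'
#' @param x,y centroid coordinates in um.
#' @param times time stamps in minutes, strictly increasing.
#' @param label `"nucleus"` or `"cell_body"`.
#' @return A `trajectory` object (data.frame with attributes).
#' @export
trajectory <- function(x, y, times, label = c("nucleus", "cell_body")) {
  label <- match.arg(label)
  stopifnot(length(x) == length(y), length(x) == length(times))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(data.frame(time_min = times, x_um = x, y_um = y),
            label = label, class = c("trajectory", "data.frame"))
}

#' Step-to-step speeds
#'
#' Euclidean displacement between consecutive centroids divided by the
#' elapsed time.
#'
#' @param traj a `trajectory` (or data.frame with `time_min`, `x_um`,
#'   `y_um`).
#' @return Numeric vector of per-step speeds (um/min), length n-1.
#' @export
step_speeds <- function(traj) {
  if (nrow(traj) < 2L) stop("need at least 2 points")
  dt <- diff(traj$time_min)
  if (any(dt <= 0)) stop("duplicate or non-increasing timestamps")
  sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2) / dt
}

#' Mean path speed
#'
#' Total migration path length divided by total elapsed time.
#'
#' @inheritParams step_speeds
#' @return Scalar speed in um/min.
#' @export
mean_speed <- function(traj) {
  if (nrow(traj) < 2L) stop("need at least 2 points")
  el <- traj$time_min[nrow(traj)] - traj$time_min[1]
  if (el <= 0) stop("zero elapsed time")
  sum(sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)) / el
}

#' Beeline speed
#'
#' Straight-line distance between the first and last centroid of a time
#' window divided by the window duration; the net (directional) migration
#' speed. With `window = "full"` the whole track is one window; with a
#' numeric window (default 55 min) the track is cut into disjoint windows
#' and per-window beelines plus their mean are returned.
#'
#' @inheritParams step_speeds
#' @param window window length in minutes, or `"full"`.
#' @return For `"full"`: a scalar. Otherwise a list with `windows`
#'   (data.frame: t_start, t_end, beeline_um_min) and `mean_beeline`.
#' @export
beeline_speed <- function(traj, window = 55) {
  if (nrow(traj) < 2L) stop("need at least 2 points")
  span <- traj$time_min[nrow(traj)] - traj$time_min[1]
  bee <- function(i0, i1) {
    d <- sqrt((traj$x_um[i1] - traj$x_um[i0])^2 +
              (traj$y_um[i1] - traj$y_um[i0])^2)
    d / (traj$time_min[i1] - traj$time_min[i0])
  }
  if (identical(window, "full")) return(bee(1L, nrow(traj)))
  stopifnot(is.numeric(window), window > 0)
  if (span < window) stop("trajectory shorter than the beeline window")
  starts <- seq(traj$time_min[1], traj$time_min[nrow(traj)] - window,
                by = window)
  win <- do.call(rbind, lapply(starts, function(t0) {
    i0 <- which(traj$time_min >= t0)[1]
    i1 <- max(which(traj$time_min <= t0 + window))
    data.frame(t_start = traj$time_min[i0], t_end = traj$time_min[i1],
               beeline_um_min = bee(i0, i1))
  }))
  list(windows = win, mean_beeline = mean(win$beeline_um_min))
}

#' Kinematics summary of a trajectory
#'
#' @inheritParams step_speeds
#' @param beeline_window beeline window in minutes or `"full"`.
#' @param cell_id identifier copied into the output table.
#' @return A list of class `kinematics_track`: `table` (per step: frame,
#'   time_min, x_um, y_um, step_speed), `mean_speed`, `beeline_speed`
#'   (mean over disjoint windows, or full-track value), `beeline_window`.
#' @export
kinematics_track <- function(traj, beeline_window = 55, cell_id = "cell1") {
  sp <- step_speeds(traj)
  bl <- tryCatch(beeline_speed(traj, beeline_window),
                 error = function(e) beeline_speed(traj, "full"))
  blv <- if (is.list(bl)) bl$mean_beeline else bl
  structure(list(
    table = data.frame(cell_id = cell_id,
                       label = attr(traj, "label") %||% "nucleus",
                       frame = seq_len(nrow(traj)),
                       time_min = traj$time_min,
                       x_um = traj$x_um, y_um = traj$y_um,
                       step_speed = c(NA, sp)),
    step_speeds = sp,
    mean_speed = mean_speed(traj),
    beeline_speed = blv,
    beeline_window = beeline_window
  ), class = "kinematics_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a kinematics table to CSV
#'
#' @param track a `kinematics_track`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(track, path) {
  utils::write.csv(track$table, path, row.names = FALSE)
  invisible(path)
}
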