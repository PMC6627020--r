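#' Detect recoil ("phase IV") events
#'
#' A recoil event is a transient speed peak accompanied by nuclear
#' rounding (a drop in NII). A step `t` (movement from frame `t` to
#' `t + 1`) is a candidate when its speed is a local maximum with
#' prominence at least `min_prominence` and at least `baseline_factor`
#' times the running median of the speed series. A candidate is accepted
#' when the signed NII change over frames
#' `[t - rounding_window, t + rounding_window]` is negative. Candidates
#' closer than `min_separation_frames` are merged, keeping the larger.
#'
#' @param speeds per-step speed series (um/min), step `t` = frames `t` to
#'   `t + 1` (length `n - 1` for `n` frames).
#' @param nii per-frame NII series (length `n`).
#' @param baseline_factor required speed elevation over the running median
#'   (default 2).
#' @param min_prominence minimum peak prominence, um/min (default 0.1).
#' @param min_separation_frames merge radius for neighbouring peaks
#'   (default 3).
#' @param rounding_window half-width in frames of the NII-change window
#'   (default 1).
#' @param cell_id identifier copied into the output.
#' @return A data.frame of class `phase4_events`: `cell_id`,
#'   `onset_frame` (start of the speed rise), `peak_frame`, `end_frame`
#'   (end of the speed decay), `peak_speed`, `nii_drop` (signed NII change
#'   over the event window, negative).
#' @export
detect_phase4 <- function(speeds, nii,
                          baseline_factor = 2,
                          min_prominence = 0.1,
                          min_separation_frames = 3L,
                          rounding_window = 1L,
                          cell_id = "cell1") {
  n <- length(nii)
  if (length(speeds) != n - 1L) {
    stop("length mismatch: speeds must have one element per step ",
         "(frames - 1)")
  }
  m <- length(speeds)
  if (m < 3L) return(empty_events(cell_id))
  k <- min(11L, m - (1 - m %% 2))  # odd window <= series length
  baseline <- stats::runmed(speeds, k)
  is_max <- c(FALSE, speeds[2:(m - 1)] > speeds[1:(m - 2)] &
                     speeds[2:(m - 1)] >= speeds[3:m], FALSE)
  cand <- which(is_max)
  if (length(cand) == 0L) return(empty_events(cell_id))
  prom <- vapply(cand, function(t) peak_prominence(speeds, t), numeric(1))
  keep <- prom >= min_prominence & speeds[cand] >= baseline_factor * baseline[cand]
  cand <- cand[keep]
  if (length(cand) == 0L) return(empty_events(cell_id))
  # merge close-by peaks, larger one wins
  cand <- cand[order(-speeds[cand])]
  merged <- integer(0)
  for (t in cand) {
    if (all(abs(merged - t) >= min_separation_frames)) merged <- c(merged, t)
  }
  merged <- sort(merged)
  # rounding criterion
  lo <- pmax(merged - rounding_window, 1L)
  hi <- pmin(merged + rounding_window, n)
  drop <- nii[hi] - nii[lo]
  merged <- merged[drop < 0]
  drop <- drop[drop < 0]
  if (length(merged) == 0L) return(empty_events(cell_id))
  onset <- vapply(merged, function(t) {
    while (t > 1L && speeds[t - 1L] < speeds[t]) t <- t - 1L
    t
  }, integer(1))
  endf <- vapply(merged, function(t) {
    while (t < m && speeds[t + 1L] < speeds[t]) t <- t + 1L
    t
  }, integer(1))
  structure(data.frame(cell_id = cell_id, onset_frame = onset,
                       peak_frame = merged, end_frame = endf,
                       peak_speed = speeds[merged], nii_drop = drop),
            class = c("phase4_events", "data.frame"))
}

empty_events <- function(cell_id) {
  structure(data.frame(cell_id = character(0), onset_frame = integer(0),
                       peak_frame = integer(0), end_frame = integer(0),
                       peak_speed = numeric(0), nii_drop = numeric(0)),
            class = c("phase4_events", "data.frame"))
}

# topographic prominence of a local maximum in a 1-D series
peak_prominence <- function(x, t) {
  left <- x[seq_len(t - 1L)]
  right <- x[seq(t + 1L, length(x))]
  higher_l <- which(left >= x[t])
  higher_r <- which(right >= x[t])
  min_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(t - 1L)])
           else min(left)
  min_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)])
           else min(right)
  x[t] - max(min_l, min_r)
}

#' Align event traces into a population ensemble
#'
#' Extracts, for every event, the speed (and optionally NII) trace in a
#' window around the alignment point, places it on a common relative time
#' axis (time 0 at the event onset, the peak, or the pore-centre crossing)
#' and aggregates the traces into per-time-point mean and s.e.m.
#'
#' @param events a `phase4_events` data.frame (ignored for
#'   `mode = "pore_center"` when a pore annotation is given).
#' @param traces data.frame with `time_min`, `speed` and optionally `nii`;
#'   one track. For several tracks, call per track and combine with
#'   `rbind` on the returned `traces` element before pooling.
#' @param mode alignment point: `"onset"`, `"peak"` or `"pore_center"`.
#' @param trajectory required for `"pore_center"`: a `trajectory` whose
#'   crossing of the pore line defines time 0.
#' @param pore pore annotation for `"pore_center"`: either a single x
#'   coordinate (um) of a vertical pore axis, or a list
#'   `list(p1 = c(x, y), p2 = c(x, y))` defining a line.
#' @param window half-width of the aligned window, minutes.
#' @param frame_interval_min sampling step of the common axis, minutes.
#' @return A list of class `aligned_ensemble`: `table` (rel_time_min,
#'   mean_speed, sem_speed, n, and mean/sem NII columns when available)
#'   and `traces` (matrix, one row per event). s.e.m. uses the n-1
#'   denominator and is `NA` where fewer than 2 traces contribute.
#' @export
align_events <- function(events, traces, mode = c("onset", "peak", "pore_center"),
                         trajectory = NULL, pore = NULL,
                         window = 30, frame_interval_min = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("time_min", "speed") %in% names(traces)))
  if (is.null(frame_interval_min)) {
    frame_interval_min <- stats::median(diff(traces$time_min))
  }
  t0 <- switch(mode,
    onset = traces$time_min[events$onset_frame],
    peak = traces$time_min[events$peak_frame],
    pore_center = {
      if (is.null(trajectory) || is.null(pore)) {
        stop("pore_center mode needs a trajectory and a pore annotation")
      }
      pore_crossing_time(trajectory, pore)
    })
  if (length(t0) == 0L) stop("no events to align")
  rel <- seq(-window, window, by = frame_interval_min)
  grab <- function(val, t_center) {
    stats::approx(traces$time_min - t_center, val, xout = rel, rule = 1)$y
  }
  sp <- t(vapply(t0, function(tc) grab(traces$speed, tc), numeric(length(rel))))
  if (all(colSums(!is.na(sp)) == 0)) stop("no trace covers the window")
  agg <- function(m) {
    n <- colSums(!is.na(m))
    mu <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
    sd <- apply(m, 2, stats::sd, na.rm = TRUE)
    sem <- ifelse(n >= 2, sd / sqrt(n), NA_real_)
    list(mean = mu, sem = sem, n = n)
  }
  a <- agg(sp)
  tab <- data.frame(rel_time_min = rel, mean_speed = a$mean,
                    sem_speed = a$sem, n = a$n)
  out_traces <- list(speed = sp)
  if ("nii" %in% names(traces)) {
    ni <- t(vapply(t0, function(tc) grab(traces$nii, tc), numeric(length(rel))))
    an <- agg(ni)
    tab$mean_nii <- an$mean; tab$sem_nii <- an$sem
    out_traces$nii <- ni
  }
  structure(list(table = tab, traces = out_traces, mode = mode, t0 = t0),
            class = "aligned_ensemble")
}

# first time the trajectory crosses the pore line, linearly interpolated
# and snapped to the nearest sample time
pore_crossing_time <- function(traj, pore) {
  if (is.numeric(pore) && length(pore) == 1L) {
    s <- traj$x_um - pore
  } else {
    p1 <- pore$p1; p2 <- pore$p2
    # signed side of the line p1->p2
    s <- (p2[1] - p1[1]) * (traj$y_um - p1[2]) -
         (p2[2] - p1[2]) * (traj$x_um - p1[1])
  }
  sgn <- sign(s[1])
  if (sgn == 0) return(traj$time_min[1])
  cross <- which(sign(s) != sgn & sign(s) != 0)[1]
  if (is.na(cross)) stop("trajectory never crosses the pore line")
  i <- cross - 1L
  w <- abs(s[i]) / (abs(s[i]) + abs(s[cross]))
  tc <- traj$time_min[i] + w * (traj$time_min[cross] - traj$time_min[i])
  traj$time_min[which.min(abs(traj$time_min - tc))]
}

#' Partition track steps into recoil vs remaining
#'
#' Steps falling inside any detected event window (`onset_frame` to
#' `end_frame`) are labelled phase IV; every other valid step is labelled
#' remaining. Per-group medians and quartiles are reported for each
#' metric.
#'
#' @param steps data.frame with one row per step: `cell_id`, `frame` (step
#'   index), `speed`, and optionally `delta_nii`, `fluctuation`.
#' @param events a `phase4_events` data.frame (possibly from several
#'   cells).
#' @return A list of class `step_partition`: `phase4_steps`,
#'   `remaining_steps` (disjoint, exhaustive), and `summary` (group x
#'   metric medians and quartiles).
#' @export
partition_steps <- function(steps, events) {
  in_event <- rep(FALSE, nrow(steps))
  if (nrow(events) > 0) {
    for (k in seq_len(nrow(events))) {
      in_event <- in_event |
        (steps$cell_id == events$cell_id[k] &
         steps$frame >= events$onset_frame[k] &
         steps$frame <= events$end_frame[k])
    }
  }
  metrics <- intersect(c("speed", "delta_nii", "fluctuation"), names(steps))
  summ <- do.call(rbind, lapply(metrics, function(mname) {
    do.call(rbind, lapply(c(phase4 = TRUE, remaining = FALSE), function(ph) {
      v <- steps[[mname]][in_event == ph]
      v <- v[is.finite(v)]
      data.frame(group = if (ph) "phase4" else "remaining", metric = mname,
                 n = length(v),
                 q25 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA,
                 median = if (length(v)) stats::median(v) else NA,
                 q75 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(phase4_steps = steps[in_event, , drop = FALSE],
                 remaining_steps = steps[!in_event, , drop = FALSE],
                 summary = summ),
            class = "step_partition")
}

#' Nonparametric two-group comparison
#'
#' Two-tailed unpaired Mann-Whitney (Wilcoxon rank-sum) test and
#' two-sample Kolmogorov-Smirnov test, as appropriate for independent
#' non-Gaussian samples.
#'
#' @param sample_a,sample_b numeric vectors, each n >= 3.
#' @return List with `mw_p`, `ks_p`, `mw_method`, `ks_method` (exact vs
#'   asymptotic, as chosen by the underlying tests).
#' @export
compare_groups <- function(sample_a, sample_b) {
  if (length(sample_a) < 3L || length(sample_b) < 3L) {
    stop("each sample needs at least 3 observations")
  }
  mw <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            alternative = "two.sided"))
  ks <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                        alternative = "two.sided"))
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  list(mw_p = mw$p.value, ks_p = ks$p.value,
       mw_method = if (grepl("exact", mw$method, ignore.case = TRUE))
         "exact" else "asymptotic",
       # stats::ks.test uses the exact two-sample null when the product of
       # the sample sizes is below 10^4 and there are no ties
       ks_method = if (!ties &&
                       length(sample_a) * length(sample_b) < 1e4)
         "exact" else "asymptotic")
}

#' Write events / ensemble tables to CSV
#'
#' @param x a `phase4_events` data.frame or an `aligned_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  tab <- if (inherits(x, "aligned_ensemble")) x$table else as.data.frame(x)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
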