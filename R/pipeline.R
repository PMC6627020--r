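#' Pipeline configuration
#'
#' Nested list of all tunable parameters of the end-to-end analysis, with
#' physical units attached to names. Round-trips unchanged through YAML
#' ([read_config()] / [write_config()]).
#'
#' @param pixel_size_um,frame_interval_min spatial / temporal calibration.
#' @param channel TIFF channel holding the nuclear label.
#' @param method segmentation threshold: `"otsu"`, `"auto"` (Otsu, but
#'   fixed 0.5 threshold for binary mask stacks) or a number.
#' @param min_area,fill_holes,smooth_sigma,max_gap segmentation parameters
#'   (see [segment_frame()], [track_single_nucleus()]).
#' @param step_deg fluctuation rotation step, degrees.
#' @param beeline_window_min beeline window, minutes.
#' @param baseline_factor,min_prominence,min_separation_frames,rounding_window
#'   event-detection parameters (see [detect_phase4()]).
#' @param align_mode event alignment point (`"onset"` or `"peak"`).
#' @param align_window_min ensemble half-window, minutes.
#' @param afs_setpoint_nN,afs_poisson_ratio,afs_fit_fraction AFS parameters.
#' @param seed integer seed for any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_size_um = 0.5,
                            frame_interval_min = 5,
                            channel = 1L,
                            method = "auto",
                            min_area = 200,
                            fill_holes = TRUE,
                            smooth_sigma = 0,
                            max_gap = 2L,
                            step_deg = 1,
                            beeline_window_min = 55,
                            baseline_factor = 2,
                            min_prominence = 0.1,
                            min_separation_frames = 3L,
                            rounding_window = 1L,
                            align_mode = "onset",
                            align_window_min = 30,
                            afs_setpoint_nN = 2,
                            afs_poisson_ratio = 0.5,
                            afs_fit_fraction = c(0.1, 0.9),
                            seed = 1L) {
  stopifnot(pixel_size_um > 0, frame_interval_min > 0, min_area >= 0,
            step_deg > 0, beeline_window_min > 0, baseline_factor > 0)
  structure(mget(names(formals())), class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full shape-dynamics pipeline
#'
#' Executes segmentation, shape metrics, fluctuation, kinematics and event
#' detection in order on one movie, writing every result table as CSV, a
#' run manifest (config, package version, seed, file checksums) and
#' summary plots into `outdir`.
#'
#' @param config a `pipeline_config`.
#' @param input a TIFF path or a `frame_stack`. Binary mask stacks (all
#'   values 0/1) skip thresholding when `method = "auto"`.
#' @param outdir output directory, created if needed.
#' @param cell_id identifier used in all tables.
#' @param plots write summary plots (default `TRUE`).
#' @return A list of class `pipeline_result` with `sequence`, `metrics`,
#'   `fluctuation`, `kinematics`, `events`, `ensemble` (NULL when no
#'   events), `partition`, and `manifest_path`.
#' @export
run_pipeline <- function(config, input, outdir, cell_id = "cell1",
                        plots = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stack <- stage("load", {
    if (inherits(input, "frame_stack")) input
    else load_stack(input, channel = config$channel,
                    pixel_size_um = config$pixel_size_um,
                    frame_interval_min = config$frame_interval_min)
  })
  method <- config$method
  if (identical(method, "auto")) {
    vals <- unique(as.vector(stack$frames[[1]]))
    method <- if (all(vals %in% c(0, 1))) 0.5 else "otsu"
  }
  seq_ <- stage("segment", segment_stack(
    stack, method = method, min_area = config$min_area,
    fill_holes = config$fill_holes, smooth_sigma = config$smooth_sigma,
    max_gap = config$max_gap))
  metrics <- stage("metrics", shape_metrics_track(seq_, cell_id = cell_id))
  fluct <- stage("fluctuation", fluctuation_track(
    seq_, step_deg = config$step_deg, cell_id = cell_id))
  traj <- trajectory(seq_$centroids_um[, 1], seq_$centroids_um[, 2],
                     seq_$times_min, label = "nucleus")
  kin <- stage("kinematics", kinematics_track(
    traj, beeline_window = config$beeline_window_min, cell_id = cell_id))
  events <- stage("events", detect_phase4(
    kin$step_speeds, metrics$table$nii,
    baseline_factor = config$baseline_factor,
    min_prominence = config$min_prominence,
    min_separation_frames = config$min_separation_frames,
    rounding_window = config$rounding_window, cell_id = cell_id))
  traces <- data.frame(time_min = seq_$times_min,
                       speed = c(kin$step_speeds, NA),
                       nii = metrics$table$nii)
  ensemble <- if (nrow(events) > 0) {
    stage("events", align_events(events, traces, mode = config$align_mode,
                                 window = config$align_window_min,
                                 frame_interval_min = stack$frame_interval_min))
  }
  steps <- data.frame(cell_id = cell_id,
                      frame = seq_len(length(seq_$times_min) - 1L),
                      speed = kin$step_speeds,
                      delta_nii = metrics$table$delta_nii[-1],
                      fluctuation = fluct$table$fluctuation)
  part <- stage("events", partition_steps(steps, events))
  files <- c(outlines = "outlines.csv", metrics = "shape_metrics.csv",
             fluctuation = "fluctuation.csv", kinematics = "kinematics.csv",
             events = "events.csv")
  write_outlines(seq_, file.path(outdir, files["outlines"]))
  write_shape_metrics(metrics, file.path(outdir, files["metrics"]))
  write_fluctuation(fluct, file.path(outdir, files["fluctuation"]))
  write_kinematics(kin, file.path(outdir, files["kinematics"]))
  write_events(events, file.path(outdir, files["events"]))
  if (!is.null(ensemble)) {
    files <- c(files, ensemble = "ensemble.csv")
    write_events(ensemble, file.path(outdir, "ensemble.csv"))
  }
  if (plots) {
    files <- c(files, plot_timeseries = "speed_nii_time.png",
               plot_scatter = "speed_vs_delta_nii.png")
    plot_speed_nii(kin, metrics, events,
                   file.path(outdir, "speed_nii_time.png"))
    plot_speed_scatter(steps, part,
                       file.path(outdir, "speed_vs_delta_nii.png"))
    if (!is.null(ensemble)) {
      files <- c(files, plot_ensemble = "ensemble.png")
      plot_ensemble(ensemble, file.path(outdir, "ensemble.png"))
    }
  }
  manifest <- list(
    package = "nucmorph",
    version = as.character(utils::packageVersion("nucmorph")),
    seed = config$seed,
    config = unclass(config),
    files = as.list(files),
    md5 = as.list(tools::md5sum(file.path(outdir, unname(files))))
  )
  manifest_path <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  structure(list(sequence = seq_, metrics = metrics, fluctuation = fluct,
                 kinematics = kin, events = events, ensemble = ensemble,
                 partition = part, manifest_path = manifest_path),
            class = "pipeline_result")
}

plot_speed_nii <- function(kin, metrics, events, path) {
  d <- data.frame(time = metrics$table$time_min,
                  speed = c(NA, kin$step_speeds),
                  nii = metrics$table$nii)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = time)) +
    ggplot2::geom_line(ggplot2::aes(y = speed, colour = "speed (um/min)"),
                       na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = nii, colour = "NII")) +
    ggplot2::labs(x = "time (min)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(events) > 0) {
    g <- g + ggplot2::geom_vline(
      xintercept = metrics$table$time_min[events$peak_frame],
      linetype = "dashed", colour = "grey40")
  }
  ggplot2::ggsave(path, g, width = 7, height = 4, dpi = 120)
}

plot_speed_scatter <- function(steps, part, path) {
  steps$group <- ifelse(seq_len(nrow(steps)) %in%
                          as.integer(rownames(part$phase4_steps)),
                        "phase IV", "remaining")
  g <- ggplot2::ggplot(steps,
                       ggplot2::aes(x = delta_nii, y = speed, colour = group)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "delta NII", y = "speed (um/min)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, g, width = 5, height = 4, dpi = 120)
}

plot_ensemble <- function(ensemble, path) {
  d <- ensemble$table
  g <- ggplot2::ggplot(d, ggplot2::aes(x = rel_time_min, y = mean_speed))
  if (any(is.finite(d$sem_speed))) {
    g <- g + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = mean_speed - sem_speed,
                   ymax = mean_speed + sem_speed),
      alpha = 0.3, na.rm = TRUE)
  }
  g <- g + ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time from alignment point (min)",
                  y = "speed (um/min)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, g, width = 5, height = 4, dpi = 120)
}
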