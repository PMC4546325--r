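#' Pipeline configuration
#'
#' Nested parameter set for the full analysis chain, with every default taken
#' from the study conventions where one exists (15 s frames, 10 min duration
#' filter, 90-degree turn-angle rule, n<40 test rule) and declared package
#' defaults elsewhere. `max_disp = NULL` resolves to
#' `4 * speed_expect * frame_interval` — four times the expected per-frame
#' displacement, so reversing cells are never gated out.
#'
#' @param pixel_size um/px; `frame_interval` seconds.
#' @param min_area segmentation minimum area, um^2.
#' @param seg_method `"otsu"` or `"fixed"` (+ `seg_threshold`).
#' @param max_disp linking gate, um (NULL = auto).
#' @param speed_expect expected cell speed (um/min) used only for the auto
#'   gate.
#' @param min_duration track duration filter, s.
#' @param angle_threshold degrees, strict.
#' @param min_step displacement gate for angle vertices, um; `NULL` resolves
#'   to `2 * pixel_size`. Set 0 for noise-free data.
#' @param refractory,corr_window,smoothing,min_persistence frames.
#' @param mode `"confirmed"` (fluorescence stick-slip filter) or `"all"`.
#' @param pole_radius,pole_annulus px, for pole photometry.
#' @param seg_threshold fixed threshold when `seg_method = "fixed"`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(pixel_size = 0.1, frame_interval = 15,
                            min_area = 1, seg_method = "otsu",
                            seg_threshold = NULL,
                            max_disp = NULL, speed_expect = 1.7,
                            min_duration = 600,
                            angle_threshold = 90, min_step = NULL,
                            refractory = 2, corr_window = 2, smoothing = 3,
                            min_persistence = 2,
                            mode = c("confirmed", "all"),
                            pole_radius = 3, pole_annulus = c(5, 7)) {
  mode <- match.arg(mode)
  if (is.null(max_disp)) max_disp <- 4 * speed_expect * frame_interval / 60
  if (is.null(min_step)) min_step <- 2 * pixel_size
  cfg <- list(pixel_size = pixel_size, frame_interval = frame_interval,
              min_area = min_area, seg_method = seg_method,
              seg_threshold = seg_threshold, max_disp = max_disp,
              speed_expect = speed_expect, min_duration = min_duration,
              angle_threshold = angle_threshold, min_step = min_step,
              refractory = refractory, corr_window = corr_window,
              smoothing = smoothing, min_persistence = min_persistence,
              mode = mode, pole_radius = pole_radius,
              pole_annulus = pole_annulus)
  num <- cfg[vapply(cfg, is.numeric, logical(1))]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite pipeline config value")
  stopifnot(pixel_size > 0, frame_interval > 0, max_disp > 0, min_area >= 0,
            min_duration >= 0, angle_threshold > 0, angle_threshold <= 180,
            min_step >= 0, refractory >= 0, corr_window >= 0,
            smoothing >= 1, min_persistence >= 1, pole_radius > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#' @param path file path; `config` a `"pipeline_config"`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' Build tracks directly from simulated ground truth (trajectory mode)
#'
#' Bypasses rendering and imaging: each simulated cell becomes one track with
#' its true centroids, poles and pole fluorescence. Used for large benchmarks
#' where rendering a movie would dominate the cost, and for isolating the
#' event-calling stages from imaging error.
#'
#' @param truth a `"ground_truth"`.
#' @return a `"track_set"` with persistent pole labels already assigned.
#' @export
tracks_from_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  dt <- truth$config$frame_interval
  rows <- lapply(truth$cells, function(cl) {
    tr <- cl$traj
    data.frame(track_id = cl$id, frame = tr$frame, time_s = tr$time_s,
               x_um = tr$x_um, y_um = tr$y_um,
               degenerate = FALSE,
               pole1_x = tr$pole1_x, pole1_y = tr$pole1_y,
               pole2_x = tr$pole2_x, pole2_y = tr$pole2_y,
               pole1_int = tr$fluor1, pole2_int = tr$fluor2,
               speed_um_min = c(NA, sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)) /
                 dt * 60,
               cumdist_um = cumsum(c(0, sqrt(diff(tr$x_um)^2 +
                                               diff(tr$y_um)^2))))
  })
  tracks <- do.call(rbind, rows)
  rownames(tracks) <- NULL
  structure(list(tracks = tracks,
                 log = list(n_detections = nrow(tracks),
                            n_conflict_dropped = 0L,
                            n_tracks = length(truth$cells),
                            frame_interval = dt,
                            trajectory_mode = TRUE)),
            class = "track_set")
}

#' Run the full reversal-analysis pipeline
#'
#' stabilize -> segment -> track -> duration filter -> pole identity ->
#' directional changes -> fluorescence switches -> classification ->
#' per-cell statistics. The input is either a `"frame_stack"` (movie mode) or
#' a `"ground_truth"` (trajectory mode, see [tracks_from_truth()]).
#'
#' @param input `"frame_stack"` or `"ground_truth"`.
#' @param config a [pipeline_config()].
#' @param out_dir if non-NULL, writes `tracks.csv`, `events.csv`,
#'   `per_cell.csv`, `group_stats.json` and `config.yaml` there.
#' @param group_label label for the group summary.
#' @return list of class `"pipeline_result"`: `tracks` (data frame), `events`,
#'   `per_cell`, `group` (a `"group_stats"` row or NULL), `offsets`
#'   (stabilization), `log` (stage counts), `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         out_dir = NULL, group_label = "group") {
  log <- list()
  offsets <- NULL
  if (inherits(input, "frame_stack")) {
    stab <- stabilize_stack(input)
    offsets <- stab$offsets
    detections <- detect_cells(stab$stack, min_area = config$min_area,
                               method = config$seg_method,
                               threshold = config$seg_threshold,
                               pole_radius = config$pole_radius,
                               pole_annulus = config$pole_annulus)
    log$n_detections <- nrow(detections)
    ts <- build_tracks(detections, config$frame_interval, config$max_disp)
    ts <- filter_tracks(ts, config$min_duration)
    ts <- assign_pole_identity(ts)
    has_fluor <- !is.null(input$fluor)
  } else if (inherits(input, "ground_truth")) {
    ts <- tracks_from_truth(input)
    ts <- filter_tracks(ts, config$min_duration)
    log$n_detections <- ts$log$n_detections
    has_fluor <- TRUE
  } else {
    stop("input must be a frame_stack or a ground_truth")
  }
  log <- c(log, ts$log)
  tracks <- ts$tracks
  ev_list <- list(); pc_list <- list()
  if (nrow(tracks) > 0) {
    for (df in split(tracks, tracks$track_id)) {
      ev <- call_directional_changes(df, config$angle_threshold,
                                     config$min_step, config$refractory)
      sw <- if (has_fluor && "pole1_int" %in% names(df) &&
                any(!is.na(df$pole1_int))) {
        dfi <- df
        dfi$pole1_int[is.na(dfi$pole1_int)] <- 0
        dfi$pole2_int[is.na(dfi$pole2_int)] <- 0
        withCallingHandlers(
          detect_fluor_switches(dfi, config$smoothing, config$min_persistence),
          warning = function(w) invokeRestart("muffleWarning"))
      } else NULL
      ev <- classify_events(ev, sw, config$corr_window)
      ev_list[[length(ev_list) + 1L]] <- ev
      pc_list[[length(pc_list) + 1L]] <-
        reversal_statistics(df, ev, mode = if (config$mode == "confirmed" &&
                                               !is.null(sw)) "confirmed" else "all")
    }
  }
  events <- if (length(ev_list) > 0) do.call(rbind, ev_list) else
    classify_events(call_directional_changes(tracks[0, ]), NULL)
  per_cell <- if (length(pc_list) > 0) do.call(rbind, pc_list) else
    data.frame(track_id = integer(0), duration_min = numeric(0),
               n_events = integer(0), freq_per_10min = numeric(0),
               mean_interreversal_min = numeric(0))
  rownames(events) <- NULL; rownames(per_cell) <- NULL
  log$n_events <- nrow(events)
  log$n_confirmed <- sum(events$classification == "confirmed")
  log$n_stick_slip <- sum(events$classification == "stick_slip")
  log$n_unconfirmed <- sum(events$classification == "unconfirmed")
  group <- if (nrow(per_cell) > 0)
    summarize_group(per_cell$freq_per_10min, label = group_label) else NULL
  res <- structure(list(tracks = tracks, events = events, per_cell = per_cell,
                        group = group, offsets = offsets, log = log,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' Write pipeline outputs as CSV/JSON/YAML
#'
#' CSV is RFC-4180 (UTF-8, '.' decimal); units are carried in the column
#' names (`_um`, `_s`, `per_10min`).
#'
#' @param res a `"pipeline_result"`; `out_dir` output directory.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  keep <- intersect(c("track_id", "frame", "time_s", "x_um", "y_um",
                      "area_um2", "orientation_deg", "length_um",
                      "pole1_x", "pole1_y", "pole2_x", "pole2_y",
                      "pole1_int", "pole2_int", "speed_um_min", "cumdist_um"),
                    names(res$tracks))
  utils::write.csv(res$tracks[, keep, drop = FALSE],
                   file.path(out_dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(res$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(res$per_cell, file.path(out_dir, "per_cell.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(group = res$group, log = res$log),
    file.path(out_dir, "group_stats.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", null = "null")
  write_pipeline_config(res$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$log$n_tracks, "tracks;",
      x$log$n_events, "directional changes (",
      x$log$n_confirmed, "confirmed,", x$log$n_stick_slip, "stick-slip,",
      x$log$n_unconfirmed, "unconfirmed )\n")
  invisible(x)
}
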