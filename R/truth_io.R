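#' Write / read ground truth as JSON
#'
#' Lossless round trip of the full [simulate_trajectories()] result (config,
#' per-cell trajectories, event list). Each cell's trajectory is stored as
#' named column arrays; numbers are serialized at full precision.
#'
#' @param truth a `"ground_truth"` object.
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(
    format = "myxotrack-ground-truth-1",
    config = unclass(truth$config),
    cells = lapply(truth$cells, function(cl) {
      list(id = cl$id, speed_um_min = cl$speed_um_min,
           axis_deg = cl$axis_deg, clipped = cl$clipped,
           traj = as.list(cl$traj))
    }),
    events = as.list(truth$events)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @return `read_ground_truth`: the reconstructed `"ground_truth"`.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed ground-truth file '", path, "': ",
                             conditionMessage(e)))
  if (!identical(payload$format, "myxotrack-ground-truth-1"))
    stop("malformed ground-truth file '", path, "': missing/unknown format tag")
  cfg <- lapply(payload$config, function(v)
    if (length(v) > 1) unlist(v) else v)
  cfg$field_size <- as.integer(cfg$field_size)
  cfg <- do.call(simulation_config, cfg[names(cfg) %in%
                                          names(formals(simulation_config))])
  cell_list <- lapply(payload$cells, function(cl) {
    traj <- as.data.frame(lapply(cl$traj, function(col)
      unlist(col, use.names = FALSE)))
    check_traj(traj, cl$id)
    list(id = as.integer(cl$id), speed_um_min = as.numeric(cl$speed_um_min),
         axis_deg = as.numeric(cl$axis_deg), clipped = isTRUE(cl$clipped),
         traj = traj)
  })
  ev_cols <- lapply(payload$events, function(col)
    unlist(col, use.names = FALSE))
  events <- if (length(ev_cols$cell) > 0) as.data.frame(ev_cols) else
    data.frame(cell = integer(0), type = character(0),
               frame = integer(0), time_s = numeric(0),
               time_exact_s = numeric(0))
  if (any(events$time_s < 0) || any(events$frame < 0))
    stop("malformed ground-truth file '", path,
         "': negative event time/frame (event record ",
         which(events$time_s < 0 | events$frame < 0)[1], ")")
  structure(list(config = cfg, cells = cell_list, events = events),
            class = "ground_truth")
}

check_traj <- function(traj, cell_id) {
  need <- c("frame", "time_s", "x_um", "y_um", "fluor1", "fluor2")
  miss <- setdiff(need, names(traj))
  if (length(miss) > 0)
    stop("malformed ground-truth trajectory for cell ", cell_id,
         ": missing column(s) ", paste(miss, collapse = ", "))
  if (any(traj$time_s < 0))
    stop("malformed ground-truth trajectory for cell ", cell_id,
         ": negative time at row ", which(traj$time_s < 0)[1])
  if (any(diff(traj$frame) != 1))
    stop("malformed ground-truth trajectory for cell ", cell_id,
         ": frames not consecutive at row ", which(diff(traj$frame) != 1)[1])
  invisible(traj)
}
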