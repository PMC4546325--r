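#' Simulation configuration for synthetic run-and-reverse movies
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' Defaults emulate the acquisition regime of single-cell Tfp-motility assays
#' on carboxymethylcellulose: 15 s frame interval, per-cell speeds drawn around
#' 1.7 +/- 0.8 um/min, Poisson-like reversal events accompanied by pole-to-pole
#' exchange of a polarity reporter, and short stick-slip excursions with no
#' fluorescence exchange.
#'
#' Event waiting times are drawn as `event_refractory` seconds plus an
#' exponential whose rate is set so the long-run mean event rate equals the
#' nominal `reversal_rate` (resp. `stickslip_rate`). The dead time models the
#' refractory period of the reversal switch and keeps successive events
#' resolvable at the frame interval; it requires
#' `(reversal_rate + stickslip_rate) * event_refractory/60 < 1`.
#'
#' @param n_cells number of simulated cells.
#' @param duration total movie duration in seconds.
#' @param frame_interval time between frames in seconds.
#' @param pixel_size physical pixel size in um/px.
#' @param field_size field dimensions in pixels, `c(width, height)`.
#' @param speed_mean,speed_sd per-cell speed distribution (um/min); speeds are
#'   drawn from a normal truncated at > 0 and held constant per cell.
#' @param reversal_rate mean reversal rate per cell, events/min.
#' @param stickslip_rate mean stick-slip rate per cell, events/min.
#' @param stickslip_excursion back-and-forth displacement of a stick-slip, um.
#' @param cell_length,cell_width cell geometry in um (tip-to-tip length).
#' @param fluor_relocalization_frames frames over which the polarity reporter
#'   exchanges poles after a reversal.
#' @param drift_per_frame global stage drift, px/frame, `c(dx, dy)`.
#' @param noise_sd additive Gaussian noise sd on rendered intensities
#'   (intensity units on the [0, 1] scale).
#' @param texture_amp sd of the static background texture rendered into the
#'   transmitted channel (intensity units). Real phase-contrast fields carry
#'   stationary features (debris, chamber texture) that drift with the stage;
#'   registration depends on them. 0 disables.
#' @param event_refractory minimum time between successive events of one cell
#'   (seconds); see Details.
#' @param angle_jitter_deg sd of the iid frame-to-frame heading jitter about
#'   each cell's body axis, degrees.
#' @param layout `"lanes"` places one cell per parallel lane (collision-free,
#'   the default; cell-cell interactions are out of scope), `"isotropic"`
#'   places cells at random positions and orientations.
#' @param lane_spacing distance between adjacent lanes, um.
#' @param fluor_high,fluor_low reporter levels at the leading / lagging pole
#'   (arbitrary units on the [0, 1] scale).
#' @param rng_seed integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_cells = 20,
                              duration = 1800,
                              frame_interval = 15,
                              pixel_size = 0.1,
                              field_size = c(512L, 512L),
                              speed_mean = 1.7,
                              speed_sd = 0.8,
                              reversal_rate = 0.1,
                              stickslip_rate = 0.1,
                              stickslip_excursion = 0.7,
                              cell_length = 5,
                              cell_width = 0.7,
                              fluor_relocalization_frames = 1,
                              drift_per_frame = c(0, 0),
                              noise_sd = 0,
                              texture_amp = 0.05,
                              event_refractory = 60,
                              angle_jitter_deg = 5,
                              layout = c("lanes", "isotropic"),
                              lane_spacing = 3,
                              fluor_high = 1.0,
                              fluor_low = 0.3,
                              rng_seed = 1L) {
  layout <- match.arg(layout)
  cfg <- list(
    n_cells = as.integer(n_cells), duration = duration,
    frame_interval = frame_interval, pixel_size = pixel_size,
    field_size = as.integer(field_size), speed_mean = speed_mean,
    speed_sd = speed_sd, reversal_rate = reversal_rate,
    stickslip_rate = stickslip_rate, stickslip_excursion = stickslip_excursion,
    cell_length = cell_length, cell_width = cell_width,
    fluor_relocalization_frames = as.integer(fluor_relocalization_frames),
    drift_per_frame = as.numeric(drift_per_frame), noise_sd = noise_sd,
    texture_amp = texture_amp,
    event_refractory = event_refractory, angle_jitter_deg = angle_jitter_deg,
    layout = layout, lane_spacing = lane_spacing,
    fluor_high = fluor_high, fluor_low = fluor_low,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num <- cfg[setdiff(names(cfg), "layout")]
  bad <- names(num)[!vapply(num, function(v) all(is.finite(v)), logical(1))]
  if (length(bad) > 0)
    stop("non-finite simulation config value(s): ", paste(bad, collapse = ", "))
  stopifnot(
    "n_cells must be >= 0" = cfg$n_cells >= 0,
    "duration must be > 0" = cfg$duration > 0,
    "frame_interval must be > 0" = cfg$frame_interval > 0,
    "pixel_size must be > 0" = cfg$pixel_size > 0,
    "field_size must be positive" = all(cfg$field_size > 0),
    "rates must be >= 0" = cfg$reversal_rate >= 0 && cfg$stickslip_rate >= 0,
    "speed_mean must be > 0" = cfg$speed_mean > 0,
    "speed_sd must be >= 0" = cfg$speed_sd >= 0,
    "cell geometry must be positive" = cfg$cell_length > 0 && cfg$cell_width > 0,
    "noise_sd must be >= 0" = cfg$noise_sd >= 0,
    "texture_amp must be >= 0" = cfg$texture_amp >= 0,
    "event_refractory must be >= 0" = cfg$event_refractory >= 0,
    "stickslip_excursion must be > 0" = cfg$stickslip_excursion > 0,
    "fluor levels must satisfy 0 <= low < high" =
      cfg$fluor_low >= 0 && cfg$fluor_high > cfg$fluor_low
  )
  total_rate <- cfg$reversal_rate + cfg$stickslip_rate
  if (total_rate > 0 && total_rate * cfg$event_refractory / 60 >= 1)
    stop("event_refractory too long for the requested total event rate: ",
         "need (reversal_rate + stickslip_rate) * event_refractory/60 < 1")
  invisible(cfg)
}

## one draw from normal(mean, sd) truncated at > 0 (rejection; sd may be 0)
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] <= 0]
  }
  out
}

## inter-event gaps (minutes): dead time + exponential, mean gap = 1/rate_total.
## The first waiting time is drawn from the equilibrium (stationary) delay
## distribution of the renewal process, so observation starts at a random
## phase of each cell's cycle and E[N(T)] = rate_total * T exactly.
draw_event_times <- function(duration_min, rate_total, dead_min) {
  if (rate_total <= 0) return(numeric(0))
  mean_gap <- 1 / rate_total
  exp_mean <- mean_gap - dead_min
  t_cur <- if (stats::runif(1) < dead_min / mean_gap) {
    stats::runif(1, 0, dead_min)
  } else {
    dead_min + stats::rexp(1, rate = 1 / exp_mean)
  }
  tt <- numeric(0)
  while (t_cur < duration_min) {
    tt <- c(tt, t_cur)
    t_cur <- t_cur + dead_min + stats::rexp(1, rate = 1 / exp_mean)
  }
  tt
}

#' Simulate ground-truthed run-and-reverse trajectories
#'
#' Generates per-cell trajectories sampled exactly at the frame times. Each
#' cell moves along its body axis at a constant per-cell speed; reversals flip
#' the direction of motion 180 degrees (modulo heading jitter) and exchange the
#' leading/lagging pole fluorescence within
#' `config$fluor_relocalization_frames`; stick-slips are back-and-forth
#' excursions of `config$stickslip_excursion` completed within two frames with
#' no fluorescence exchange. Deterministic given `config$rng_seed`.
#'
#' Events are snapped to the nearest frame; events falling too close to the
#' first/last frames to form a trajectory vertex are not generated. Trajectory
#' coordinates are in sample space (um); the `in_view` flag accounts for the
#' configured stage drift and marks frames where the whole cell lies inside
#' the field with a 3-pixel clearance.
#'
#' @param config a [simulation_config()].
#' @return An object of class `"ground_truth"`: a list with elements `config`,
#'   `cells` (per-cell list with `id`, `speed_um_min`, `axis_deg`, and a
#'   trajectory data frame) and `events` (data frame with `cell`, `type`
#'   (`"reversal"` or `"stickslip"`), `frame` (0-based), `time_s` (frame
#'   time) and `time_exact_s` (continuous event time before frame snapping)).
#' @export
simulate_trajectories <- function(config) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  dt <- config$frame_interval
  n_frames <- floor(config$duration / dt) + 1L
  if (n_frames < 3) stop("duration too short: need at least 3 frames")
  times <- (seq_len(n_frames) - 1L) * dt
  ps <- config$pixel_size
  w_um <- config$field_size[1] * ps
  h_um <- config$field_size[2] * ps
  step_min <- dt / 60                      # frame interval in minutes
  total_rate <- config$reversal_rate + config$stickslip_rate
  dead_min <- config$event_refractory / 60
  halflen <- config$cell_length / 2
  cum_drift_um <- cbind(
    (seq_len(n_frames) - 1L) * config$drift_per_frame[1] * ps,
    (seq_len(n_frames) - 1L) * config$drift_per_frame[2] * ps
  )
  clear_um <- config$cell_width / 2 + 3 * ps   # in-view clearance

  cells <- vector("list", config$n_cells)
  ev_all <- list()
  for (i in seq_len(config$n_cells)) {
    speed <- rtruncnorm_pos(1, config$speed_mean, config$speed_sd)
    if (config$layout == "lanes") {
      n_lanes <- config$n_cells
      lane_block <- n_lanes * config$lane_spacing
      y0 <- (h_um - lane_block) / 2 + (i - 0.5) * config$lane_spacing
      x0 <- w_um / 2 + stats::runif(1, -1, 1) * min(5, w_um / 10)
      axis0 <- 0
    } else {
      x0 <- stats::runif(1, 0.15 * w_um, 0.85 * w_um)
      y0 <- stats::runif(1, 0.15 * h_um, 0.85 * h_um)
      axis0 <- stats::runif(1, 0, 180)
    }

    ## event stream: combined renewal process, then label each event
    t_ev_min <- draw_event_times(config$duration / 60, total_rate, dead_min)
    f_ev <- as.integer(round(t_ev_min * 60 / dt))
    type_ev <- if (length(t_ev_min) > 0 && total_rate > 0) {
      ifelse(stats::runif(length(t_ev_min)) <
               config$reversal_rate / total_rate, "reversal", "stickslip")
    } else character(0)
    ## keep events whose vertex (and stick-slip return) fits inside the movie
    keep <- f_ev >= 1L & ifelse(type_ev == "stickslip",
                                f_ev <= n_frames - 3L, f_ev <= n_frames - 2L)
    f_ev <- f_ev[keep]; type_ev <- type_ev[keep]
    t_exact_s <- t_ev_min[keep] * 60

    jit <- stats::rnorm(n_frames, 0, config$angle_jitter_deg)
    axis_deg <- axis0 + jit                 # per-frame body axis
    u <- cbind(cos(axis_deg * pi / 180), sin(axis_deg * pi / 180))

    ## direction sign per interval-start frame; reversal at frame f flips the
    ## sign for intervals >= f, so the trajectory vertex falls exactly at f
    sgn <- rep(sample(c(-1, 1), 1), n_frames)
    for (f in f_ev[type_ev == "reversal"])
      sgn[(f + 1L):n_frames] <- -sgn[(f + 1L):n_frames]

    pos <- matrix(0, n_frames, 2)
    pos[1, ] <- c(x0, y0)
    ss_back <- rep(0, n_frames)   # stick-slip displacement modifier per interval
    for (f in f_ev[type_ev == "stickslip"]) {
      ss_back[f + 1L] <- -1       # interval f -> f+1: backward excursion only
      ss_back[f + 2L] <- +1       # interval f+1 -> f+2: return + resume
    }
    for (k in seq_len(n_frames - 1L)) {
      if (ss_back[k] == -1) {
        disp <- -sgn[k] * config$stickslip_excursion * u[k, ]
      } else if (ss_back[k] == 1) {
        disp <- sgn[k] * (config$stickslip_excursion + speed * step_min) * u[k, ]
      } else {
        disp <- sgn[k] * speed * step_min * u[k, ]
      }
      pos[k + 1L, ] <- pos[k, ] + disp
    }

    pole1 <- pos + halflen * u              # +axis end, fixed body polarity
    pole2 <- pos - halflen * u
    ## leading pole follows the direction of motion
    lead1 <- sgn > 0
    target1 <- ifelse(lead1, config$fluor_high, config$fluor_low)
    target2 <- ifelse(lead1, config$fluor_low, config$fluor_high)
    k_rel <- max(1L, config$fluor_relocalization_frames)
    fluor1 <- relocalize(target1, k_rel)
    fluor2 <- relocalize(target2, k_rel)

    tipmax <- pmax(pole1[, 1], pole2[, 1]) + cum_drift_um[, 1]
    tipmin <- pmin(pole1[, 1], pole2[, 1]) + cum_drift_um[, 1]
    tipmax_y <- pmax(pole1[, 2], pole2[, 2]) + cum_drift_um[, 2]
    tipmin_y <- pmin(pole1[, 2], pole2[, 2]) + cum_drift_um[, 2]
    in_view <- tipmin >= clear_um & tipmax <= w_um - clear_um &
      tipmin_y >= clear_um & tipmax_y <= h_um - clear_um

    traj <- data.frame(
      frame = seq_len(n_frames) - 1L, time_s = times,
      x_um = pos[, 1], y_um = pos[, 2], axis_deg = axis_deg,
      direction = sgn,
      pole1_x = pole1[, 1], pole1_y = pole1[, 2],
      pole2_x = pole2[, 1], pole2_y = pole2[, 2],
      fluor1 = fluor1, fluor2 = fluor2, in_view = in_view
    )
    cells[[i]] <- list(id = i, speed_um_min = speed, axis_deg = axis0,
                       clipped = any(!in_view), traj = traj)
    if (length(f_ev) > 0)
      ev_all[[length(ev_all) + 1L]] <- data.frame(
        cell = i, type = type_ev, frame = f_ev, time_s = f_ev * dt,
        time_exact_s = t_exact_s)
  }
  events <- if (length(ev_all) > 0) {
    ev <- do.call(rbind, ev_all)
    ev[order(ev$cell, ev$frame), , drop = FALSE]
  } else {
    data.frame(cell = integer(0), type = character(0),
               frame = integer(0), time_s = numeric(0),
               time_exact_s = numeric(0))
  }
  rownames(events) <- NULL
  structure(list(config = config, cells = cells, events = events),
            class = "ground_truth")
}

## linear crossfade of a step series over k frames after each level change
relocalize <- function(target, k) {
  if (k <= 1) return(target)
  n <- length(target)
  out <- target
  chg <- which(diff(target) != 0)
  for (f in chg) {
    span <- seq_len(k - 1L)
    idx <- f + span
    idx <- idx[idx <= n]
    out[idx] <- target[f] + (target[f + 1L] - target[f]) * span[seq_along(idx)] / k
  }
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$cells), "cells,",
      nrow(x$events), "events (",
      sum(x$events$type == "reversal"), "reversals,",
      sum(x$events$type == "stickslip"), "stick-slips )\n")
  invisible(x)
}
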