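#' Turn angle at a trajectory vertex
#'
#' Vertex angle at `p` between the segments to the previous and next centroid:
#' `acos` of the normalized dot product of `(p_prev - p)` and `(p_next - p)`.
#' Straight motion gives 180 degrees, an exact retrace 0 degrees. Invariant
#' under rotation, translation and uniform scaling.
#'
#' @param p_prev,p,p_next centroids `c(x, y)` in um at times t-1, t, t+1.
#' @return angle in degrees, or `NA` if either segment has zero length.
#' @export
compute_turn_angle <- function(p_prev, p, p_next) {
  u <- p_prev - p
  v <- p_next - p
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

#' Call directional-change events on one track
#'
#' Scores a candidate event at every vertex whose turn angle is strictly below
#' `angle_threshold` (the "< 90 degrees" rule) and whose two adjacent steps
#' are both at least `min_step` (a jitter guard; vertices with a sub-threshold
#' step have an undefined angle and are skipped). Candidates within
#' `refractory` frames of the first vertex of the previous retained event are
#' merged into it (earliest vertex kept), so one physical reversal spanning
#' two vertices is counted once.
#'
#' @param track data frame for a single track with `frame`, `x_um`, `y_um`.
#' @param angle_threshold degrees; strict inequality, 90 exactly is not an
#'   event.
#' @param min_step um; minimum adjacent step length.
#' @param refractory frames.
#' @return data frame with `track_id`, `frame` (vertex, 0-based),
#'   `turn_angle_deg`, `step_before_um`, `step_after_um`, `n_merged`.
#' @export
call_directional_changes <- function(track, angle_threshold = 90,
                                     min_step = 0.2, refractory = 2) {
  n <- nrow(track)
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      turn_angle_deg = numeric(0), step_before_um = numeric(0),
                      step_after_um = numeric(0), n_merged = integer(0))
  if (n < 3) return(empty)
  tid <- if ("track_id" %in% names(track)) track$track_id[1] else NA_integer_
  xs <- track$x_um; ys <- track$y_um
  cand <- list()
  for (t in 2:(n - 1)) {
    s1 <- sqrt((xs[t] - xs[t - 1])^2 + (ys[t] - ys[t - 1])^2)
    s2 <- sqrt((xs[t + 1] - xs[t])^2 + (ys[t + 1] - ys[t])^2)
    if (s1 < min_step || s2 < min_step) next
    ang <- compute_turn_angle(c(xs[t - 1], ys[t - 1]), c(xs[t], ys[t]),
                              c(xs[t + 1], ys[t + 1]))
    if (is.na(ang) || ang >= angle_threshold) next
    cand[[length(cand) + 1L]] <- data.frame(
      track_id = tid, frame = track$frame[t], turn_angle_deg = ang,
      step_before_um = s1, step_after_um = s2, n_merged = 1L)
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  keep <- integer(0)
  last_kept <- -Inf
  for (r in seq_len(nrow(cand))) {
    if (cand$frame[r] - last_kept <= refractory) {
      cand$n_merged[keep[length(keep)]] <- cand$n_merged[keep[length(keep)]] + 1L
    } else {
      keep <- c(keep, r)
      last_kept <- cand$frame[r]
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect pole-fluorescence switches on one track
#'
#' Both persistent-pole intensity series are smoothed by a centered moving
#' average (window truncated at the track ends); a switch is recorded at each
#' sign change of `pole1 - pole2` whose new sign persists for at least
#' `min_persistence` frames. Zero differences carry the preceding sign.
#' The reported `frame` is the first frame carrying the new sign — the point
#' where the two pole traces cross.
#'
#' @param track single-track data frame with `frame`, `pole1_int`,
#'   `pole2_int` (see [assign_pole_identity()]).
#' @param smoothing moving-average window, frames (odd; 1 = none).
#' @param min_persistence frames the new dominance must last.
#' @return data frame with `track_id`, `frame`, `pre_dominant`,
#'   `post_dominant` (`"pole1"`/`"pole2"`), `persistence` (frames).
#' @export
detect_fluor_switches <- function(track, smoothing = 3, min_persistence = 2) {
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      pre_dominant = character(0), post_dominant = character(0),
                      persistence = integer(0))
  if (!all(c("pole1_int", "pole2_int") %in% names(track))) return(empty)
  n <- nrow(track)
  if (n < 2) return(empty)
  tid <- if ("track_id" %in% names(track)) track$track_id[1] else NA_integer_
  d <- smooth_ma(track$pole1_int, smoothing) - smooth_ma(track$pole2_int, smoothing)
  if (all(track$pole1_int == 0) && all(track$pole2_int == 0)) {
    warning("all-zero fluorescence: no switches")
    return(empty)
  }
  s <- sign(d)
  for (t in seq_len(n)[-1]) if (s[t] == 0) s[t] <- s[t - 1]  # carry last sign
  first_nz <- which(s != 0)[1]
  if (is.na(first_nz)) return(empty)
  if (first_nz > 1) s[seq_len(first_nz - 1)] <- s[first_nz]
  out <- list()
  t <- 2
  while (t <= n) {
    if (s[t] != s[t - 1]) {
      run_end <- t
      while (run_end < n && s[run_end + 1] == s[t]) run_end <- run_end + 1
      persist <- run_end - t + 1
      if (persist >= min_persistence) {
        out[[length(out) + 1L]] <- data.frame(
          track_id = tid, frame = track$frame[t],
          pre_dominant = if (s[t - 1] > 0) "pole1" else "pole2",
          post_dominant = if (s[t] > 0) "pole1" else "pole2",
          persistence = as.integer(persist))
        t <- run_end + 1
        next
      } else {
        ## transient flicker: treat as noise, restore previous sign
        s[t:run_end] <- s[t - 1]
        t <- run_end + 1
        next
      }
    }
    t <- t + 1
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## centered moving average with truncated windows at the edges
smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  half <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Classify directional changes against fluorescence switches
#'
#' Each directional change (in frame order) is matched to the nearest
#' unconsumed switch within `window` frames: matched events are `confirmed`
#' reversals (the switch is consumed); unmatched events are `stick_slip` when
#' fluorescence data exist, `unconfirmed` otherwise (pure-motion mode).
#'
#' @param events from [call_directional_changes()].
#' @param switches from [detect_fluor_switches()]; `NULL` for pure-motion
#'   mode.
#' @param window frames.
#' @return `events` with `classification` and `matched_switch_frame` columns.
#' @export
classify_events <- function(events, switches, window = 2) {
  events$classification <- rep(if (is.null(switches)) "unconfirmed"
                               else "stick_slip", nrow(events))
  events$matched_switch_frame <- rep(NA_integer_, nrow(events))
  if (is.null(switches) || nrow(switches) == 0 || nrow(events) == 0)
    return(events)
  consumed <- logical(nrow(switches))
  for (r in order(events$frame)) {
    gap <- abs(switches$frame - events$frame[r])
    gap[consumed] <- Inf
    j <- which.min(gap)
    if (gap[j] <= window) {
      events$classification[r] <- "confirmed"
      events$matched_switch_frame[r] <- switches$frame[j]
      consumed[j] <- TRUE
    }
  }
  events
}

#' Per-cell reversal frequency and inter-reversal time
#'
#' Frequency is the event count divided by the track duration, in reversals
#' per 10 min; the mean inter-reversal time (min) is reported for tracks with
#' at least two events. `mode = "confirmed"` counts fluorescence-confirmed
#' reversals only (the stick-slip filter); `mode = "all"` counts every
#' directional change (pure-motion counts, no filter).
#'
#' @param track single-track data frame (`frame`, `time_s`).
#' @param events classified events for that track.
#' @param mode `"confirmed"` or `"all"`.
#' @return one-row data frame: `track_id`, `duration_min`, `n_events`,
#'   `freq_per_10min`, `mean_interreversal_min` (NA with < 2 events).
#' @export
reversal_statistics <- function(track, events, mode = c("confirmed", "all")) {
  mode <- match.arg(mode)
  duration_s <- max(track$time_s) - min(track$time_s)
  if (duration_s <= 0) stop("zero-duration track")
  ev <- if (mode == "confirmed")
    events[events$classification == "confirmed", , drop = FALSE]
  else events
  n_ev <- nrow(ev)
  dt_s <- duration_s / (nrow(track) - 1)
  mit <- if (n_ev >= 2) mean(diff(sort(ev$frame)) * dt_s) / 60 else NA_real_
  data.frame(
    track_id = if ("track_id" %in% names(track)) track$track_id[1] else NA_integer_,
    duration_min = duration_s / 60,
    n_events = n_ev,
    freq_per_10min = n_ev / (duration_s / 600),
    mean_interreversal_min = mit)
}
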