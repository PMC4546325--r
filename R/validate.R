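#' Observable ground-truth events
#'
#' An event is observable when its cell is continuously in view for a run that
#' satisfies the tracking duration filter, with an `edge` frame cushion around
#' the event (vertex geometry, fluorescence smoothing and the switch
#' correlation window all need neighboring frames). Events of cells that
#' wander out of the field are untrackable under the study's own rules and are
#' excluded from the recall denominator (raw recall over all events is also
#' reported by [validate_events()]).
#'
#' @param truth a `"ground_truth"`.
#' @param min_duration seconds the in-view run must last.
#' @param edge frames of cushion around the event inside the run.
#' @return `truth$events` with a logical `observable` column.
#' @export
observable_events <- function(truth, min_duration = 600, edge = 3) {
  ev <- truth$events
  dt <- truth$config$frame_interval
  if (nrow(ev) == 0) {
    ev$observable <- logical(0)
    return(ev)
  }
  obs <- logical(nrow(ev))
  for (r in seq_len(nrow(ev))) {
    tr <- truth$cells[[ev$cell[r]]]$traj
    iv <- tr$in_view
    i <- match(ev$frame[r], tr$frame)
    if (is.na(i) || !iv[i]) next
    run_start <- i; while (run_start > 1 && iv[run_start - 1]) run_start <- run_start - 1
    run_end <- i; while (run_end < length(iv) && iv[run_end + 1]) run_end <- run_end + 1
    dur_ok <- (run_end - run_start) * dt >= min_duration
    edge_ok <- (i - run_start) >= edge && (run_end - i) >= edge
    obs[r] <- dur_ok && edge_ok
  }
  ev$observable <- obs
  ev
}

#' Map tracks to ground-truth cells by trajectory proximity
#'
#' For each track, the candidate cell minimizing the mean centroid distance
#' over overlapping frames; assignments are greedy by ascending distance and
#' one-to-many (several track fragments may cover one cell), with a distance
#' ceiling.
#'
#' @param tracks track data frame.
#' @param truth a `"ground_truth"`.
#' @param max_mean_dist um; tracks farther from every cell stay unmapped.
#' @return data frame `track_id`, `cell`, `mean_dist_um`.
#' @export
map_tracks_to_truth <- function(tracks, truth, max_mean_dist = 2) {
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    df <- tracks[tracks$track_id == id, ]
    best <- NA_integer_; best_d <- Inf
    for (cl in truth$cells) {
      m <- match(df$frame, cl$traj$frame)
      ok <- !is.na(m)
      if (!any(ok)) next
      d <- mean(sqrt((df$x_um[ok] - cl$traj$x_um[m[ok]])^2 +
                       (df$y_um[ok] - cl$traj$y_um[m[ok]])^2))
      if (d < best_d) { best_d <- d; best <- cl$id }
    }
    data.frame(track_id = id, cell = if (best_d <= max_mean_dist) best else
      NA_integer_, mean_dist_um = best_d)
  })
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(track_id = integer(0), cell = integer(0),
               mean_dist_um = numeric(0))
  rownames(res) <- NULL
  res
}

#' Event-level validation against ground truth
#'
#' One-to-one greedy matching (ascending frame distance) of called events to
#' true events of the same cell within `frame_tolerance`. Confirmed calls are
#' scored against true reversals; stick-slip calls against true stick-slips.
#' Precision matches calls against all truth; recall is reported both over
#' observable events (see [observable_events()]) and over all events.
#' With zero calls, precision is reported as 1 and flagged.
#'
#' @param events classified event table (from [run_pipeline()]).
#' @param truth the generating `"ground_truth"`.
#' @param tracks the track table the events were called on (for the
#'   track-to-cell mapping).
#' @param frame_tolerance frames.
#' @param min_duration seconds, for observability (match the pipeline's
#'   duration filter).
#' @return list of class `"validation_report"`: `precision`, `recall`
#'   (observable), `recall_all`, `n_called`, `n_true_observable`, `n_true`,
#'   `stickslip_confirmed` (true stick-slips matched by confirmed calls —
#'   leakage through the fluorescence filter), `stickslip_recall`,
#'   `tracking_identity_accuracy`, `flags`.
#' @export
validate_events <- function(events, truth, tracks, frame_tolerance = 1,
                            min_duration = 600) {
  stopifnot(inherits(truth, "ground_truth"))
  mapping <- map_tracks_to_truth(tracks, truth)
  if (any(is.na(mapping$cell)) && nrow(mapping) > 0)
    warning("unmapped track(s): ",
            paste(mapping$track_id[is.na(mapping$cell)], collapse = ", "))
  ev <- merge(events, mapping[, c("track_id", "cell")], by = "track_id")
  tru <- observable_events(truth, min_duration = min_duration)
  flags <- character(0)

  score <- function(calls, truth_ev) {
    matched_call <- logical(nrow(calls))
    matched_true <- logical(nrow(truth_ev))
    if (nrow(calls) > 0 && nrow(truth_ev) > 0) {
      cand <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
        j <- which(truth_ev$cell == calls$cell[i] &
                     abs(truth_ev$frame - calls$frame[i]) <= frame_tolerance)
        if (length(j) == 0) return(NULL)
        data.frame(i = i, j = j, gap = abs(truth_ev$frame[j] - calls$frame[i]))
      }))
      if (!is.null(cand) && nrow(cand) > 0) {
        cand <- cand[order(cand$gap, cand$i, cand$j), ]
        for (r in seq_len(nrow(cand))) {
          if (!matched_call[cand$i[r]] && !matched_true[cand$j[r]]) {
            matched_call[cand$i[r]] <- TRUE
            matched_true[cand$j[r]] <- TRUE
          }
        }
      }
    }
    list(call = matched_call, true = matched_true)
  }

  conf <- ev[ev$classification == "confirmed" & !is.na(ev$cell), , drop = FALSE]
  tru_rev <- tru[tru$type == "reversal", , drop = FALSE]
  m_rev <- score(conf, tru_rev)
  precision <- if (nrow(conf) == 0) {
    flags <- c(flags, "zero confirmed calls: precision reported as 1")
    1
  } else mean(m_rev$call)
  obs_rev <- tru_rev$observable
  recall <- if (sum(obs_rev) == 0) NA_real_ else
    sum(m_rev$true & obs_rev) / sum(obs_rev)
  recall_all <- if (nrow(tru_rev) == 0) NA_real_ else mean(m_rev$true)

  ss_calls <- ev[ev$classification == "stick_slip" & !is.na(ev$cell), ,
                 drop = FALSE]
  tru_ss <- tru[tru$type == "stickslip", , drop = FALSE]
  m_ss_conf <- score(conf, tru_ss)
  m_ss <- score(ss_calls, tru_ss)
  ss_recall <- if (sum(tru_ss$observable) == 0) NA_real_ else
    sum(m_ss$true & tru_ss$observable) / sum(tru_ss$observable)

  ## identity accuracy: fraction of track points within 1 um of the mapped
  ## cell's true position
  acc <- NA_real_
  if (nrow(tracks) > 0) {
    ok <- 0L; tot <- 0L
    for (id in unique(tracks$track_id)) {
      cell <- mapping$cell[mapping$track_id == id]
      if (is.na(cell)) next
      df <- tracks[tracks$track_id == id, ]
      traj <- truth$cells[[cell]]$traj
      m <- match(df$frame, traj$frame)
      okm <- !is.na(m)
      d <- sqrt((df$x_um[okm] - traj$x_um[m[okm]])^2 +
                  (df$y_um[okm] - traj$y_um[m[okm]])^2)
      ok <- ok + sum(d <= 1); tot <- tot + sum(okm)
    }
    acc <- if (tot > 0) ok / tot else NA_real_
  }

  structure(list(precision = precision, recall = recall,
                 recall_all = recall_all,
                 n_called = nrow(conf),
                 n_true_observable = sum(obs_rev), n_true = nrow(tru_rev),
                 stickslip_confirmed = sum(m_ss_conf$true),
                 stickslip_recall = ss_recall,
                 tracking_identity_accuracy = acc,
                 frame_tolerance = frame_tolerance, flags = flags),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "validation (tolerance +/- %d frame(s)):\n",
    "  confirmed reversals: precision %.3f, recall %.3f ",
    "(%d called, %d/%d true observable; recall over all true: %.3f)\n",
    "  stick-slips confirmed as reversals: %d; stick-slip recall %.3f\n",
    "  tracking identity accuracy: %.3f\n"),
    x$frame_tolerance, x$precision, x$recall, x$n_called,
    x$n_true_observable, x$n_true, x$recall_all,
    x$stickslip_confirmed, x$stickslip_recall,
    x$tracking_identity_accuracy))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}
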