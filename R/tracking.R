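#' Link detections between two consecutive frames
#'
#' Greedy mutual-nearest matching in ascending distance order, the
#' nearest-object rule: candidate pairs are sorted by centroid distance and
#' accepted while both endpoints are free; pairs farther than `max_disp` are
#' rejected. If two candidate pairs at exactly equal distance claim the same
#' detection, all pairs involved in the tie are dropped (ambiguity is
#' conservatively discarded). Deterministic and symmetric in input order.
#'
#' @param det_a,det_b detection data frames (from [segment_frame()]) for
#'   frames t and t+1; rows are identified by position.
#' @param max_disp gate distance in um.
#' @return list with `pairs` (data frame `i`, `j`, `dist`), `unmatched_a`,
#'   `unmatched_b` (row indices).
#' @export
link_frames <- function(det_a, det_b, max_disp) {
  na <- nrow(det_a); nb <- nrow(det_b)
  no_pairs <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (na == 0 || nb == 0)
    return(list(pairs = no_pairs, unmatched_a = seq_len(na),
                unmatched_b = seq_len(nb)))
  dmat <- outer(seq_len(na), seq_len(nb), function(i, j) {
    sqrt((det_a$x_um[i] - det_b$x_um[j])^2 + (det_a$y_um[i] - det_b$y_um[j])^2)
  })
  cand <- which(dmat <= max_disp, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(list(pairs = no_pairs, unmatched_a = seq_len(na),
                unmatched_b = seq_len(nb)))
  dd <- dmat[cand]
  ord <- order(dd, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  dd <- dd[ord]
  used_a <- logical(na); used_b <- logical(nb)
  acc <- matrix(0L, 0, 2); accd <- numeric(0)
  k <- 1
  while (k <= length(dd)) {
    ## block of candidates at exactly equal distance
    kk <- k
    while (kk < length(dd) && dd[kk + 1] == dd[k]) kk <- kk + 1
    block <- cand[k:kk, , drop = FALSE]
    block_d <- dd[k:kk]
    free <- !used_a[block[, 1]] & !used_b[block[, 2]]
    block <- block[free, , drop = FALSE]; block_d <- block_d[free]
    if (nrow(block) > 0) {
      ## within an equal-distance block, drop every pair sharing an endpoint
      dup_a <- block[, 1] %in% block[duplicated(block[, 1]) |
                                       duplicated(block[, 1], fromLast = TRUE), 1]
      dup_b <- block[, 2] %in% block[duplicated(block[, 2]) |
                                       duplicated(block[, 2], fromLast = TRUE), 2]
      amb <- dup_a | dup_b
      keep <- block[!amb, , drop = FALSE]; keep_d <- block_d[!amb]
      ## ambiguous detections are consumed (their links are discarded)
      used_a[block[, 1]] <- TRUE; used_b[block[, 2]] <- TRUE
      if (nrow(keep) > 0) {
        acc <- rbind(acc, keep); accd <- c(accd, keep_d)
      }
    }
    k <- kk + 1
  }
  pairs <- data.frame(i = acc[, 1], j = acc[, 2], dist = accd)
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(na), pairs$i),
       unmatched_b = setdiff(seq_len(nb), pairs$j))
}

#' Build tracks from per-frame detections
#'
#' Chains [link_frames()] assignments across the movie. Automated QC replaces
#' manual trajectory verification: detections closer than `conflict_dist` to
#' another detection in the same frame are treated as conflicts — they are
#' excluded from linking, so the tracks of crossing cells terminate at the
#' conflict frame; gate violations terminate tracks; no gap closing (a missed
#' detection terminates the track).
#'
#' @param detections data frame from [detect_cells()] (needs a 0-based
#'   `frame` column).
#' @param frame_interval seconds between frames.
#' @param max_disp linking gate in um.
#' @param conflict_dist same-frame proximity below which detections are
#'   dropped as conflicts; defaults to `max_disp`.
#' @return list of class `"track_set"`: `tracks` data frame (one row per
#'   track point: `track_id`, `frame`, `time_s`, `x_um`, `y_um`, geometry,
#'   per-frame `speed_um_min` and `cumdist_um`) and `log` (QC counts).
#' @export
build_tracks <- function(detections, frame_interval, max_disp,
                         conflict_dist = max_disp) {
  stopifnot(!is.null(detections$frame))
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections, detections$frame)
  n_conflict <- 0L
  for (f in names(by_frame)) {
    d <- by_frame[[f]]
    if (nrow(d) > 1 && conflict_dist > 0) {
      dm <- as.matrix(stats::dist(d[, c("x_um", "y_um")]))
      diag(dm) <- Inf
      bad <- apply(dm < conflict_dist, 1, any)
      n_conflict <- n_conflict + sum(bad)
      by_frame[[f]] <- d[!bad, , drop = FALSE]
    }
  }
  next_id <- 1L
  open <- list()    # track_id -> list(rows = list of detection rows)
  closed <- list()
  start_track <- function(row) {
    open[[as.character(next_id)]] <<- list(id = next_id, rows = list(row))
    next_id <<- next_id + 1L
  }
  if (length(frames) > 0)
    for (i in seq_len(nrow(by_frame[[1]]))) start_track(by_frame[[1]][i, ])
  for (fi in seq_along(frames)[-1]) {
    d_prev <- if (length(open) > 0)
      do.call(rbind, lapply(open, function(tr) tr$rows[[length(tr$rows)]]))
    else NULL
    d_cur <- by_frame[[fi]]
    prev_ids <- vapply(open, function(tr) tr$id, integer(1))
    if (is.null(d_prev) || nrow(d_prev) == 0) {
      lk <- list(pairs = data.frame(i = integer(0), j = integer(0)),
                 unmatched_a = integer(0), unmatched_b = seq_len(nrow(d_cur)))
    } else {
      lk <- link_frames(d_prev, d_cur, max_disp)
    }
    ## a one-frame gap: frames are consecutive integers or the link is void
    gap <- frames[fi] - frames[fi - 1] != 1L
    if (gap) lk <- list(pairs = data.frame(i = integer(0), j = integer(0)),
                        unmatched_a = seq_len(NROW(d_prev)),
                        unmatched_b = seq_len(nrow(d_cur)))
    new_open <- list()
    if (nrow(lk$pairs) > 0)
      for (r in seq_len(nrow(lk$pairs))) {
        id <- prev_ids[lk$pairs$i[r]]
        tr <- open[[as.character(id)]]
        tr$rows[[length(tr$rows) + 1L]] <- d_cur[lk$pairs$j[r], ]
        new_open[[as.character(id)]] <- tr
      }
    for (i in lk$unmatched_a) {
      id <- prev_ids[i]
      closed[[length(closed) + 1L]] <- open[[as.character(id)]]
    }
    open <- new_open
    for (j in lk$unmatched_b) start_track(d_cur[j, ])
  }
  closed <- c(closed, unname(open))
  rows <- lapply(closed, function(tr) {
    df <- do.call(rbind, tr$rows)
    df$track_id <- tr$id
    df
  })
  tracks <- if (length(rows) > 0) do.call(rbind, rows) else detections[0, ]
  if (nrow(tracks) > 0) {
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
    tracks$time_s <- tracks$frame * frame_interval
    sp <- unlist(lapply(split(tracks, tracks$track_id), function(df) {
      st <- c(NA, sqrt(diff(df$x_um)^2 + diff(df$y_um)^2))
      st / frame_interval * 60
    }), use.names = FALSE)
    tracks$speed_um_min <- sp
    tracks$cumdist_um <- unlist(lapply(split(tracks, tracks$track_id),
      function(df) cumsum(c(0, sqrt(diff(df$x_um)^2 + diff(df$y_um)^2)))),
      use.names = FALSE)
    rownames(tracks) <- NULL
  }
  structure(list(tracks = tracks,
                 log = list(n_detections = nrow(detections),
                            n_conflict_dropped = n_conflict,
                            n_tracks = length(closed),
                            frame_interval = frame_interval)),
            class = "track_set")
}

#' Keep tracks at least `min_duration` seconds long
#'
#' Duration is `(n_frames - 1) * frame_interval`; the threshold is inclusive
#' (a 10-min track passes a 10-min filter).
#'
#' @param track_set from [build_tracks()].
#' @param min_duration seconds (default 600, the 10-min rule).
#' @return a filtered `"track_set"`; the number of removed tracks is added to
#'   the log.
#' @export
filter_tracks <- function(track_set, min_duration = 600) {
  stopifnot(inherits(track_set, "track_set"))
  tr <- track_set$tracks
  if (nrow(tr) == 0) return(track_set)
  dt <- track_set$log$frame_interval
  n_by <- table(tr$track_id)
  keep_ids <- as.integer(names(n_by))[(as.integer(n_by) - 1) * dt >= min_duration]
  removed <- length(n_by) - length(keep_ids)
  track_set$tracks <- tr[tr$track_id %in% keep_ids, , drop = FALSE]
  track_set$log$n_tracks_removed_short <- removed
  track_set$log$n_tracks <- length(keep_ids)
  track_set
}

#' Assign persistent pole identities along each track
#'
#' Frame-0 labels are positional (`pole1` = lexicographically smaller pole);
#' at every later frame the (a, b) poles are assigned to (pole1, pole2) so as
#' to minimize the summed distance to the previous labeled poles. Frames
#' flagged axis-degenerate inherit the previous assignment positionally.
#'
#' @param track_set a `"track_set"`.
#' @return the `"track_set"` with added columns `pole1_x/y`, `pole2_x/y` and,
#'   when pole intensities are present, `pole1_int`, `pole2_int`, plus
#'   `pole_swapped` (whether the labeling swapped a/b at that frame).
#' @export
assign_pole_identity <- function(track_set) {
  stopifnot(inherits(track_set, "track_set"))
  tr <- track_set$tracks
  if (nrow(tr) == 0) return(track_set)
  has_int <- "pa_int" %in% names(tr) && any(!is.na(tr$pa_int))
  out <- lapply(split(tr, tr$track_id), function(df) {
    n <- nrow(df)
    swap <- logical(n)   # TRUE: pole1 <- b
    for (t in seq_len(n)[-1]) {
      if (isTRUE(df$degenerate[t])) {
        swap[t] <- swap[t - 1]
        next
      }
      p1 <- if (swap[t - 1]) c(df$pb_x[t - 1], df$pb_y[t - 1]) else
        c(df$pa_x[t - 1], df$pa_y[t - 1])
      p2 <- if (swap[t - 1]) c(df$pa_x[t - 1], df$pa_y[t - 1]) else
        c(df$pb_x[t - 1], df$pb_y[t - 1])
      d_keep <- sum((c(df$pa_x[t], df$pa_y[t]) - p1)^2) +
        sum((c(df$pb_x[t], df$pb_y[t]) - p2)^2)
      d_swap <- sum((c(df$pb_x[t], df$pb_y[t]) - p1)^2) +
        sum((c(df$pa_x[t], df$pa_y[t]) - p2)^2)
      swap[t] <- if (d_swap < d_keep) TRUE else FALSE
    }
    df$pole_swapped <- swap
    df$pole1_x <- ifelse(swap, df$pb_x, df$pa_x)
    df$pole1_y <- ifelse(swap, df$pb_y, df$pa_y)
    df$pole2_x <- ifelse(swap, df$pa_x, df$pb_x)
    df$pole2_y <- ifelse(swap, df$pa_y, df$pb_y)
    if (has_int) {
      df$pole1_int <- ifelse(swap, df$pb_int, df$pa_int)
      df$pole2_int <- ifelse(swap, df$pa_int, df$pb_int)
    }
    df
  })
  track_set$tracks <- do.call(rbind, out)
  rownames(track_set$tracks) <- NULL
  track_set
}

#' @export
print.track_set <- function(x, ...) {
  cat("track_set:", x$log$n_tracks, "tracks,", nrow(x$tracks),
      "track points\n")
  invisible(x)
}
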