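#' Stabilize a stack against stage drift
#'
#' Registers every frame of the transmitted channel to the first frame by
#' translation, estimated by FFT cross-correlation with optional parabolic
#' sub-pixel refinement; the fluorescence channel is shifted by the same
#' offsets. Frames are shifted by the rounded offset (no interpolation);
#' the sub-pixel estimates are reported.
#'
#' @param stack a `"frame_stack"`.
#' @param subpixel refine the correlation peak by parabolic interpolation.
#' @param smooth_window running-median window (frames, odd) applied to the
#'   offset series; stage drift is smooth in time, so isolated mis-locks of
#'   the correlation (e.g. onto a coherently moving cell group) are repaired.
#'   0 or 1 disables.
#' @return list with `stack` (registered) and `offsets`, a data frame with
#'   0-based `frame` and the applied translation `dx`, `dy` in px (the
#'   translation that moves frame content back onto frame 0; a scene drifting
#'   by +1 px/frame in x yields `dx = -t`).
#' @export
stabilize_stack <- function(stack, subpixel = TRUE, smooth_window = 5) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$transmitted)
  n_frames <- d[3]
  ref <- stack$transmitted[, , 1]
  ref_c <- ref - mean(ref)
  fr <- stats::fft(ref_c)
  off <- matrix(0, n_frames, 2)  # dx, dy applied
  warned <- FALSE
  for (t in seq_len(n_frames)[-1]) {
    cur <- stack$transmitted[, , t]
    if (stats::sd(cur) == 0) {
      if (!warned) warning("featureless frame(s): identity offset used")
      warned <- TRUE
      next
    }
    sh <- xcorr_shift(fr, cur - mean(cur), subpixel)  # displacement of t vs 0
    off[t, ] <- -sh
  }
  if (smooth_window > 1 && n_frames >= smooth_window) {
    k <- smooth_window + (1 - smooth_window %% 2)  # force odd
    off[, 1] <- stats::runmed(off[, 1], k, endrule = "median")
    off[, 2] <- stats::runmed(off[, 2], k, endrule = "median")
    off[1, ] <- 0
  }
  out <- stack
  for (t in seq_len(n_frames)[-1]) {
    sx <- round(off[t, 1]); sy <- round(off[t, 2])
    if (sx == 0 && sy == 0) next
    out$transmitted[, , t] <- shift_int(stack$transmitted[, , t], sx, sy)
    if (!is.null(stack$fluor))
      out$fluor[, , t] <- shift_int(stack$fluor[, , t], sx, sy)
  }
  list(stack = out,
       offsets = data.frame(frame = seq_len(n_frames) - 1L,
                            dx = off[, 1], dy = off[, 2]))
}

## displacement (dx, dy) of image `cur` relative to the reference whose fft is
## `fref`: cur(x) ~= ref(x - s); returns s
xcorr_shift <- function(fref, cur, subpixel) {
  d <- dim(cur)
  cc <- Re(stats::fft(fref * Conj(stats::fft(cur)), inverse = TRUE)) / length(cur)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ## circular index -> signed shift; cc[i+1, j+1] corresponds to shift (-i, -j)
  iy <- pk[1] - 1L; ix <- pk[2] - 1L
  sy <- -(if (iy > d[1] / 2) iy - d[1] else iy)
  sx <- -(if (ix > d[2] / 2) ix - d[2] else ix)
  if (subpixel) {
    sy <- sy - parab_offset(cc[wrap(pk[1] - 1L, d[1]), pk[2]],
                            cc[pk[1], pk[2]],
                            cc[wrap(pk[1] + 1L, d[1]), pk[2]])
    sx <- sx - parab_offset(cc[pk[1], wrap(pk[2] - 1L, d[2])],
                            cc[pk[1], pk[2]],
                            cc[pk[1], wrap(pk[2] + 1L, d[2])])
  }
  c(sx, sy)
}

wrap <- function(i, n) ((i - 1L) %% n) + 1L

parab_offset <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (den == 0) return(0)
  delta <- 0.5 * (cm - cp) / den
  max(-0.5, min(0.5, delta))
}

## integer translation with median fill
shift_int <- function(m, sx, sy) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(stats::median(m), h, w)
  src_x <- seq_len(w) - sx; src_y <- seq_len(h) - sy
  ok_x <- src_x >= 1 & src_x <= w; ok_y <- src_y >= 1 & src_y <= h
  if (any(ok_x) && any(ok_y))
    out[which(ok_y), which(ok_x)] <- m[src_y[ok_y], src_x[ok_x]]
  out
}

#' Segment one transmitted-channel frame into cell detections
#'
#' Global threshold (Otsu by default) on the inverted transmitted image,
#' connected-component labeling, then geometric features per component:
#' intensity-weighted sub-pixel centroid, principal-axis orientation and
#' length, and the two pole positions (extreme points of the mask along the
#' principal axis, ordered lexicographically). Components smaller than
#' `min_area` or touching the image border are removed.
#'
#' Coordinates are 0-based pixels, x = column, y = row; physical coordinates
#' are `pixel * pixel_size`.
#'
#' @param img `H x W` matrix on [0, 1] (bright background, dark cells).
#' @param pixel_size um/px.
#' @param min_area minimum component area in um^2.
#' @param method `"otsu"` or `"fixed"` (then `threshold` applies, on the
#'   inverted image).
#' @param threshold fixed threshold for `method = "fixed"`.
#' @param min_aspect major/minor axis ratio below which a component is flagged
#'   axis-degenerate (poles then set to centroid +/- length/2 along x).
#' @return data frame of detections: `det`, `x_um`, `y_um`, `area_um2`,
#'   `orientation_deg`, `length_um`, `pa_x`, `pa_y`, `pb_x`, `pb_y`,
#'   `degenerate`. Empty (with a warning) for a constant image.
#' @export
segment_frame <- function(img, pixel_size, min_area = 1,
                          method = c("otsu", "fixed"), threshold = NULL,
                          min_aspect = 1.3) {
  method <- match.arg(method)
  empty <- data.frame(det = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), orientation_deg = numeric(0),
                      length_um = numeric(0), pa_x = numeric(0),
                      pa_y = numeric(0), pb_x = numeric(0), pb_y = numeric(0),
                      degenerate = logical(0))
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("constant image: no detections")
    return(empty)
  }
  inv <- max(img) - img
  thr <- if (method == "otsu") {
    ## Otsu can mis-split a structured background when cells cover a tiny
    ## fraction of the field; never threshold inside the background bulk,
    ## whose level and upper spread are estimated robustly from quantiles
    qs <- stats::quantile(inv, c(0.5, 0.84), names = FALSE)
    max(otsu_sparse(inv), qs[1] + 6 * (qs[2] - qs[1]))
  } else {
    stopifnot(!is.null(threshold))
    threshold
  }
  mask <- inv > thr
  if (!any(mask)) return(empty)
  lab_img <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))  # dims: (x, y)
  lab <- t(EBImage::imageData(lab_img))                 # back to (row=y, col=x)
  h <- nrow(img); w <- ncol(img)
  idx <- which(lab > 0)
  comp <- lab[idx]
  ys <- ((idx - 1L) %% h)        # 0-based row
  xs <- ((idx - 1L) %/% h)       # 0-based col
  wt <- inv[idx]
  rows <- vector("list", 0L)
  min_area_px <- min_area / pixel_size^2
  for (k in sort(unique(comp))) {
    sel <- comp == k
    x <- xs[sel]; y <- ys[sel]; wk <- wt[sel]
    if (length(x) < min_area_px) next
    if (any(x == 0L | x == w - 1L | y == 0L | y == h - 1L)) next  # border
    sw <- sum(wk)
    cx <- sum(wk * x) / sw; cy <- sum(wk * y) / sw
    mxx <- sum(wk * (x - cx)^2) / sw
    myy <- sum(wk * (y - cy)^2) / sw
    mxy <- sum(wk * (x - cx) * (y - cy)) / sw
    ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)
    aspect <- sqrt(max(ev$values[1], 1e-12) / max(ev$values[2], 1e-12))
    degenerate <- aspect < min_aspect
    if (degenerate) {
      ux <- 1; uy <- 0
    } else {
      ux <- ev$vectors[1, 1]; uy <- ev$vectors[2, 1]
    }
    theta <- atan2(uy, ux) * 180 / pi
    if (theta < 0) theta <- theta + 180
    if (theta >= 180) theta <- theta - 180
    proj <- (x - cx) * ux + (y - cy) * uy
    len_px <- max(proj) - min(proj) + 1
    tipA <- proj >= max(proj) - 1
    tipB <- proj <= min(proj) + 1
    pa <- c(sum(wk[tipA] * x[tipA]) / sum(wk[tipA]),
            sum(wk[tipA] * y[tipA]) / sum(wk[tipA]))
    pb <- c(sum(wk[tipB] * x[tipB]) / sum(wk[tipB]),
            sum(wk[tipB] * y[tipB]) / sum(wk[tipB]))
    if (degenerate) {
      pa <- c(cx + len_px / 2, cy); pb <- c(cx - len_px / 2, cy)
    }
    ## lexicographic order (x, then y) before identity assignment by tracking
    if (pa[1] > pb[1] || (pa[1] == pb[1] && pa[2] > pb[2])) {
      tmp <- pa; pa <- pb; pb <- tmp
    }
    rows[[length(rows) + 1L]] <- data.frame(
      det = length(rows) + 1L,
      x_um = cx * pixel_size, y_um = cy * pixel_size,
      area_um2 = length(x) * pixel_size^2,
      orientation_deg = theta, length_um = len_px * pixel_size,
      pa_x = pa[1] * pixel_size, pa_y = pa[2] * pixel_size,
      pb_x = pb[1] * pixel_size, pb_y = pb[2] * pixel_size,
      degenerate = degenerate)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Otsu threshold with sparse-foreground refinement: plain Otsu assumes a
## roughly balanced bimodal histogram and mis-splits the background when cells
## cover a small fraction of the field; while the foreground fraction is
## implausibly large, re-run Otsu on the above-threshold tail only.
otsu_sparse <- function(inv, max_fg = 0.2, max_iter = 3) {
  thr <- as.numeric(EBImage::otsu(EBImage::Image(t(inv)),
                                  range = c(0, max(inv))))
  for (k in seq_len(max_iter)) {
    fg <- inv[inv > thr]
    if (length(fg) / length(inv) <= max_fg || length(fg) < 16) break
    thr2 <- as.numeric(EBImage::otsu(EBImage::Image(matrix(fg)),
                                     range = range(fg)))
    if (thr2 <= thr) break
    thr <- thr2
  }
  thr
}

#' Background-subtracted fluorescence at a pole
#'
#' Mean intensity in a disc of radius `radius` px centered on the pole, minus
#' the median of a surrounding annulus, clamped at 0. Pixels outside the field
#' are ignored; a partially in-field disc sets the `partial` attribute.
#'
#' @param img fluorescence frame (`H x W` matrix).
#' @param pole_um pole position `c(x, y)` in um.
#' @param pixel_size um/px.
#' @param radius disc radius in px.
#' @param annulus inner/outer background annulus radii in px.
#' @return numeric intensity (a.u., >= 0) with attribute `partial`.
#' @export
measure_pole_intensity <- function(img, pole_um, pixel_size, radius = 3,
                                   annulus = c(5, 7)) {
  h <- nrow(img); w <- ncol(img)
  px <- pole_um[1] / pixel_size; py <- pole_um[2] / pixel_size
  ext <- ceiling(annulus[2]) + 1L
  xs <- floor(px - ext):ceiling(px + ext)
  ys <- floor(py - ext):ceiling(py + ext)
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  r <- sqrt((gx - px)^2 + (gy - py)^2)
  inside <- gx >= 0 & gx <= w - 1 & gy >= 0 & gy <= h - 1
  disc <- r <= radius
  ann <- r >= annulus[1] & r <= annulus[2]
  partial <- any(disc & !inside)
  disc_v <- img[cbind(gy[disc & inside] + 1L, gx[disc & inside] + 1L)]
  ann_v <- img[cbind(gy[ann & inside] + 1L, gx[ann & inside] + 1L)]
  if (length(disc_v) == 0) {
    out <- 0
    partial <- TRUE
  } else {
    bg <- if (length(ann_v) > 0) stats::median(ann_v) else 0
    out <- max(0, mean(disc_v) - bg)
  }
  attr(out, "partial") <- partial
  out
}

#' Detect cells with pole fluorescence across a whole stack
#'
#' Runs [segment_frame()] on every frame of the transmitted channel and, when
#' a fluorescence channel is present, measures both pole intensities with
#' [measure_pole_intensity()].
#'
#' @param stack a (stabilized) `"frame_stack"`.
#' @inheritParams segment_frame
#' @param pole_radius,pole_annulus passed to [measure_pole_intensity()].
#' @return data frame of per-frame detections with 0-based `frame` column and
#'   `pa_int` / `pb_int` columns (NA without a fluorescence channel).
#' @export
detect_cells <- function(stack, min_area = 1, method = "otsu",
                         threshold = NULL, pole_radius = 3,
                         pole_annulus = c(5, 7)) {
  stopifnot(inherits(stack, "frame_stack"))
  n_frames <- dim(stack$transmitted)[3]
  out <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    det <- withCallingHandlers(
      segment_frame(stack$transmitted[, , t], stack$pixel_size,
                    min_area = min_area, method = method,
                    threshold = threshold),
      warning = function(w) invokeRestart("muffleWarning"))
    det$frame <- rep(t - 1L, nrow(det))
    det$pa_int <- rep(NA_real_, nrow(det))
    det$pb_int <- rep(NA_real_, nrow(det))
    if (!is.null(stack$fluor) && nrow(det) > 0) {
      fl <- stack$fluor[, , t]
      for (i in seq_len(nrow(det))) {
        det$pa_int[i] <- as.numeric(measure_pole_intensity(
          fl, c(det$pa_x[i], det$pa_y[i]), stack$pixel_size,
          pole_radius, pole_annulus))
        det$pb_int[i] <- as.numeric(measure_pole_intensity(
          fl, c(det$pb_x[i], det$pb_y[i]), stack$pixel_size,
          pole_radius, pole_annulus))
      }
    }
    out[[t]] <- det
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
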