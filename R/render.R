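#' Render a ground truth into a two-channel synthetic movie
#'
#' Channel 1 (transmitted, phase-contrast-like): dark capsules (rods with
#' hemispherical caps) of `cell_length` x `cell_width` on a bright background,
#' drawn with one-pixel anti-aliasing so sub-pixel centroids are recoverable.
#' Channel 2 (fluorescence): a Gaussian spot at each pole with amplitude
#' proportional to the per-pole reporter level, over a low uniform background.
#' The configured stage drift is applied globally to both channels; Gaussian
#' noise of sd `config$noise_sd` is added and intensities are clipped to
#' [0, 1] (written as 16-bit when saved). Deterministic given the seed.
#'
#' @param truth a [simulate_trajectories()] result.
#' @param config the matching [simulation_config()]; defaults to the one
#'   stored in `truth`.
#' @return A `"frame_stack"`: list with `transmitted` and `fluor` arrays of
#'   dimension `c(H, W, T)` (row = y, col = x, 0-based physical convention
#'   `x_um = col_px * pixel_size`), plus `pixel_size` and `frame_interval`.
#' @export
render_movie <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  n_frames <- if (length(truth$cells) > 0) nrow(truth$cells[[1]]$traj) else
    floor(config$duration / config$frame_interval) + 1L
  w <- config$field_size[1]; h <- config$field_size[2]
  ps <- config$pixel_size
  bg_trans <- 0.75; depth <- 0.55
  bg_fluor <- 0.05; spot_gain <- 0.6; spot_sigma <- 2  # px
  half_w_px <- config$cell_width / 2 / ps
  seg_half <- max(config$cell_length / 2 - config$cell_width / 2, 0)  # um

  trans <- array(bg_trans, dim = c(h, w, n_frames))
  fluor <- array(bg_fluor, dim = c(h, w, n_frames))
  if (config$texture_amp > 0) {
    ## static background features, fixed in sample coordinates, drifting with
    ## the stage like everything else on the slide
    pad <- ceiling(max(abs((n_frames - 1) * config$drift_per_frame))) + 8L
    set.seed(config$rng_seed + 31L)
    canvas <- texture_canvas(h + 2L * pad, w + 2L * pad, config$texture_amp,
                             sigma = 3)
    for (t in seq_len(n_frames)) {
      dft <- (t - 1L) * config$drift_per_frame
      trans[, , t] <- trans[, , t] +
        sample_window(canvas, pad - dft[2], pad - dft[1], h, w)
    }
  }
  for (cell in truth$cells) {
    tr <- cell$traj
    u <- cbind(cos(tr$axis_deg * pi / 180), sin(tr$axis_deg * pi / 180))
    for (t in seq_len(n_frames)) {
      dft <- (t - 1L) * config$drift_per_frame
      cx <- tr$x_um[t] / ps + dft[1]; cy <- tr$y_um[t] / ps + dft[2]
      ax <- u[t, 1] * seg_half / ps; ay <- u[t, 2] * seg_half / ps
      trans[, , t] <- draw_capsule(trans[, , t], cx - ax, cy - ay,
                                   cx + ax, cy + ay, half_w_px,
                                   bg_trans, depth)
      for (p in 1:2) {
        px <- tr[[paste0("pole", p, "_x")]][t] / ps + dft[1]
        py <- tr[[paste0("pole", p, "_y")]][t] / ps + dft[2]
        amp <- spot_gain * tr[[paste0("fluor", p)]][t]
        fluor[, , t] <- draw_spot(fluor[, , t], px, py, amp, spot_sigma)
      }
    }
  }
  if (config$noise_sd > 0) {
    set.seed(config$rng_seed + 104729L)  # decouple render noise from sim draws
    trans <- trans + stats::rnorm(length(trans), 0, config$noise_sd)
    fluor <- fluor + stats::rnorm(length(fluor), 0, config$noise_sd)
  }
  trans[trans < 0] <- 0; trans[trans > 1] <- 1
  fluor[fluor < 0] <- 0; fluor[fluor > 1] <- 1
  frame_stack(trans, fluor, ps, config$frame_interval)
}

#' Construct a two-channel frame stack
#'
#' @param transmitted,fluor `c(H, W, T)` arrays on [0, 1]; `fluor` may be NULL
#'   for transmitted-only (pure-motion) analyses.
#' @param pixel_size um/px; `frame_interval` seconds.
#' @return list of class `"frame_stack"`.
#' @export
frame_stack <- function(transmitted, fluor = NULL, pixel_size, frame_interval) {
  stopifnot(length(dim(transmitted)) == 3, pixel_size > 0, frame_interval > 0)
  if (!is.null(fluor)) stopifnot(all(dim(fluor) == dim(transmitted)))
  structure(list(transmitted = transmitted, fluor = fluor,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$transmitted)
  cat("frame_stack:", d[3], "frames of", d[2], "x", d[1], "px,",
      x$pixel_size, "um/px,", x$frame_interval, "s/frame,",
      if (is.null(x$fluor)) "transmitted only\n" else "2 channels\n")
  invisible(x)
}

## anti-aliased capsule: darkening proportional to coverage of the stadium
## around segment (x1,y1)-(x2,y2) with half-width r (all in px, 0-based)
draw_capsule <- function(img, x1, y1, x2, y2, r, bg, depth) {
  h <- nrow(img); w <- ncol(img)
  xmin <- max(0L, floor(min(x1, x2) - r - 2)); xmax <- min(w - 1L, ceiling(max(x1, x2) + r + 2))
  ymin <- max(0L, floor(min(y1, y2) - r - 2)); ymax <- min(h - 1L, ceiling(max(y1, y2) + r + 2))
  if (xmin > xmax || ymin > ymax) return(img)
  xs <- xmin:xmax; ys <- ymin:ymax
  gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  tt <- if (len2 == 0) 0 else pmin(1, pmax(0, ((gx - x1) * dx + (gy - y1) * dy) / len2))
  dist <- sqrt((gx - (x1 + tt * dx))^2 + (gy - (y1 + tt * dy))^2)
  cov <- pmin(1, pmax(0, r - dist + 0.5))
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  img[ys + 1L, xs + 1L] <- pmin(sub, bg - depth * cov)
  img
}

## smooth random field with pointwise sd `amp`: white noise blurred by a
## Gaussian of the given sigma (px) via FFT, rescaled
texture_canvas <- function(h, w, amp, sigma = 3) {
  z <- matrix(stats::rnorm(h * w), h, w)
  gy <- stats::dnorm(c(0:(h %/% 2), -((h - h %/% 2 - 1):1)), sd = sigma)
  gx <- stats::dnorm(c(0:(w %/% 2), -((w - w %/% 2 - 1):1)), sd = sigma)
  k <- outer(gy, gx)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k / sum(k)), inverse = TRUE)) /
    length(z)
  sm * (amp / stats::sd(sm))
}

## bilinear-sampled h x w window of `canvas` with top-left corner at
## fractional 0-based (y0, x0)
sample_window <- function(canvas, y0, x0, h, w) {
  iy <- floor(y0); ix <- floor(x0)
  fy <- y0 - iy; fx <- x0 - ix
  ys <- iy + seq_len(h); xs <- ix + seq_len(w)
  a <- canvas[ys, xs, drop = FALSE]
  b <- canvas[ys, xs + 1L, drop = FALSE]
  cc <- canvas[ys + 1L, xs, drop = FALSE]
  d <- canvas[ys + 1L, xs + 1L, drop = FALSE]
  (1 - fy) * ((1 - fx) * a + fx * b) + fy * ((1 - fx) * cc + fx * d)
}

## additive Gaussian spot at (x, y) px with given amplitude and sigma (px)
draw_spot <- function(img, x, y, amp, sigma) {
  if (amp <= 0) return(img)
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(4 * sigma)
  xmin <- max(0L, floor(x - ext)); xmax <- min(w - 1L, ceiling(x + ext))
  ymin <- max(0L, floor(y - ext)); ymax <- min(h - 1L, ceiling(y + ext))
  if (xmin > xmax || ymin > ymax) return(img)
  xs <- xmin:xmax; ys <- ymin:ymax
  gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
  g <- amp * exp(-((gx - x)^2 + (gy - y)^2) / (2 * sigma^2))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + g
  img
}

#' Write / read a frame stack as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per channel (`<prefix>_transmitted.tif`,
#' `<prefix>_fluor.tif`). Calibration is not stored in the TIFF; supply it on
#' read (it travels in the pipeline config).
#'
#' @param stack a `"frame_stack"`.
#' @param prefix output path prefix.
#' @return `write_stack`: the file paths, invisibly. `read_stack`: a
#'   `"frame_stack"`.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "frame_stack"))
  paths <- character(0)
  for (ch in c("transmitted", "fluor")) {
    if (is.null(stack[[ch]])) next
    fn <- paste0(prefix, "_", ch, ".tif")
    pages <- lapply(seq_len(dim(stack[[ch]])[3]), function(t) stack[[ch]][, , t])
    tiff::writeTIFF(pages, fn, bits.per.sample = 16L, compression = "none")
    paths <- c(paths, fn)
  }
  invisible(paths)
}

#' @rdname write_stack
#' @param prefix path prefix used by [write_stack()].
#' @param pixel_size,frame_interval calibration to attach (um/px, s).
#' @export
read_stack <- function(prefix, pixel_size, frame_interval) {
  fn_t <- paste0(prefix, "_transmitted.tif")
  if (!file.exists(fn_t)) stop("no such stack: ", fn_t)
  pages <- tiff::readTIFF(fn_t, all = TRUE)
  trans <- simplify2array(pages)
  fn_f <- paste0(prefix, "_fluor.tif")
  fluor <- if (file.exists(fn_f)) simplify2array(tiff::readTIFF(fn_f, all = TRUE))
  frame_stack(trans, fluor, pixel_size, frame_interval)
}
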