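# static-cell stack with optional drift, used by the stabilization tests
drifted_stack <- function(drift, n_cells = 3, duration = 300, seed = 8,
                          field = c(512, 192)) {
  cfg <- simulation_config(n_cells = n_cells, duration = duration,
                           speed_mean = 1e-6, speed_sd = 0,
                           reversal_rate = 0, stickslip_rate = 0,
                           noise_sd = 0, angle_jitter_deg = 0,
                           drift_per_frame = drift, field_size = field,
                           pixel_size = 0.2, layout = "isotropic",
                           rng_seed = seed)
  render_movie(simulate_trajectories(cfg))
}

test_that("stabilization recovers injected drift", {
  st <- drifted_stack(c(1, 0))
  sb <- stabilize_stack(st)
  tt <- sb$offsets$frame
  expect_true(all(abs(sb$offsets$dx - (-tt)) < 0.5))
  expect_true(all(abs(sb$offsets$dy) < 0.5))
})

test_that("zero-drift stacks get identity offsets", {
  st <- drifted_stack(c(0, 0))
  sb <- stabilize_stack(st)
  expect_true(all(abs(sb$offsets$dx) < 0.5))
  expect_true(all(abs(sb$offsets$dy) < 0.5))
})

test_that("post-stabilization centroid scatter is sub-pixel under 3 px/frame drift", {
  st <- drifted_stack(c(3, 0), n_cells = 1, duration = 285)  # 20 frames
  sb <- stabilize_stack(st)
  cx <- vapply(seq_len(dim(st$transmitted)[3]), function(t)
    segment_frame(sb$stack$transmitted[, , t], 0.2)$x_um / 0.2, numeric(1))
  cy <- vapply(seq_len(dim(st$transmitted)[3]), function(t)
    segment_frame(sb$stack$transmitted[, , t], 0.2)$y_um / 0.2, numeric(1))
  expect_lt(stats::sd(cx), 0.5)
  expect_lt(stats::sd(cy), 0.5)
})

test_that("featureless frames stabilize to identity with a warning", {
  st <- frame_stack(array(0.5, dim = c(32, 32, 4)), NULL, 0.1, 15)
  st$transmitted[10:12, 10:14, 1] <- 0.1   # reference frame has features
  expect_warning(sb <- stabilize_stack(st, smooth_window = 0), "featureless")
  expect_equal(sb$offsets$dx, rep(0, 4))
})

test_that("segmentation finds nothing in blank or over-filtered frames", {
  expect_warning(d <- segment_frame(matrix(0.7, 64, 64), 0.1), "constant")
  expect_equal(nrow(d), 0)
  # two cells of area A each, min_area = 1.5 A -> zero detections
  cfg <- simulation_config(n_cells = 2, duration = 60, noise_sd = 0,
                           texture_amp = 0, field_size = c(128, 96),
                           pixel_size = 0.2, rng_seed = 3)
  st <- render_movie(simulate_trajectories(cfg))
  d0 <- segment_frame(st$transmitted[, , 1], 0.2)
  expect_equal(nrow(d0), 2)
  d2 <- segment_frame(st$transmitted[, , 1], 0.2,
                      min_area = 1.5 * mean(d0$area_um2))
  expect_equal(nrow(d2), 0)
})

test_that("a rendered rod is measured with correct length, poles and angle", {
  for (angle in c(0, 30)) {
    cfg <- simulation_config(n_cells = 1, duration = 60, speed_mean = 1e-6,
                             speed_sd = 0, reversal_rate = 0,
                             stickslip_rate = 0, noise_sd = 0,
                             texture_amp = 0, angle_jitter_deg = 0,
                             field_size = c(96, 96), pixel_size = 0.2,
                             layout = "isotropic", rng_seed = 12)
    tr <- simulate_trajectories(cfg)
    tr$cells[[1]]$traj$axis_deg[] <- angle
    u <- c(cos(angle * pi / 180), sin(angle * pi / 180))
    tr$cells[[1]]$traj$pole1_x <- tr$cells[[1]]$traj$x_um + 2.5 * u[1]
    tr$cells[[1]]$traj$pole1_y <- tr$cells[[1]]$traj$y_um + 2.5 * u[2]
    tr$cells[[1]]$traj$pole2_x <- tr$cells[[1]]$traj$x_um - 2.5 * u[1]
    tr$cells[[1]]$traj$pole2_y <- tr$cells[[1]]$traj$y_um - 2.5 * u[2]
    st <- render_movie(tr)
    d <- segment_frame(st$transmitted[, , 1], 0.2)
    expect_equal(nrow(d), 1)
    expect_lt(abs(d$length_um - 5) / 5, 0.10)
    expect_lt(min(abs(d$orientation_deg - angle),
                  abs(d$orientation_deg - angle - 180)), 3)
    pole_dist <- sqrt((d$pa_x - d$pb_x)^2 + (d$pa_y - d$pb_y)^2)
    expect_lt(abs(pole_dist - 5) / 5, 0.10)
    # poles sit near the true tips (either labeling)
    tips <- rbind(c(tr$cells[[1]]$traj$pole1_x[1], tr$cells[[1]]$traj$pole1_y[1]),
                  c(tr$cells[[1]]$traj$pole2_x[1], tr$cells[[1]]$traj$pole2_y[1]))
    d_a <- min(sqrt(rowSums(sweep(tips, 2, c(d$pa_x, d$pa_y))^2)))
    expect_lt(d_a, 0.5)
  }
})

test_that("axis-degenerate components are flagged", {
  img <- matrix(0.8, 64, 64)
  img[20:35, 20:35] <- 0.1       # square blob
  d <- segment_frame(img, 0.1)
  expect_equal(nrow(d), 1)
  expect_true(d$degenerate)
})

test_that("pole photometry subtracts background and flags partial discs", {
  flat <- matrix(0.3, 64, 64)
  v <- measure_pole_intensity(flat, c(3, 3), 0.1)
  expect_equal(as.numeric(v), 0)
  # two spots with 2:1 amplitude ratio recovered within 10%
  img <- matrix(0.05, 96, 96)
  img <- myxotrack:::draw_spot(img, 30, 48, 0.4, 2)
  img <- myxotrack:::draw_spot(img, 70, 48, 0.2, 2)
  v1 <- measure_pole_intensity(img, c(3.0, 4.8), 0.1)
  v2 <- measure_pole_intensity(img, c(7.0, 4.8), 0.1)
  expect_lt(abs(v1 / v2 - 2) / 2, 0.10)
  expect_false(attr(v1, "partial"))
  # invariance under adding a constant to the whole frame
  v1b <- measure_pole_intensity(img + 0.17, c(3.0, 4.8), 0.1)
  expect_equal(as.numeric(v1b), as.numeric(v1), tolerance = 1e-12)
  # disc crossing the field corner
  vc <- measure_pole_intensity(img, c(0.05, 0.05), 0.1)
  expect_true(attr(vc, "partial"))
})

test_that("segmentation recovers the true cell count and conserves area under stabilization", {
  cfg <- simulation_config(n_cells = 8, duration = 150, noise_sd = 0,
                           drift_per_frame = c(2, 1), field_size = c(320, 256),
                           pixel_size = 0.2, rng_seed = 21)
  tr <- simulate_trajectories(cfg)
  st <- render_movie(tr)
  sb <- stabilize_stack(st)
  for (t in seq_len(dim(st$transmitted)[3])) {
    raw <- segment_frame(st$transmitted[, , t], 0.2)
    stab <- segment_frame(sb$stack$transmitted[, , t], 0.2)
    expect_equal(nrow(raw), 8)
    expect_equal(nrow(stab), 8)
    # threshold is re-estimated on the shifted frame, so allow a small slack
    expect_equal(sum(stab$area_um2), sum(raw$area_um2), tolerance = 0.05)
  }
})
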