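test_that("degenerate rates give straight constant-velocity trajectories", {
  cfg <- simulation_config(n_cells = 3, duration = 600, reversal_rate = 0,
                           stickslip_rate = 0, noise_sd = 0,
                           angle_jitter_deg = 0, speed_sd = 0,
                           field_size = c(2000, 2000), rng_seed = 5)
  tr <- simulate_trajectories(cfg)
  expect_equal(nrow(tr$events), 0)
  for (cl in tr$cells) {
    dx <- diff(cl$traj$x_um); dy <- diff(cl$traj$y_um)
    step <- sqrt(dx^2 + dy^2)
    expect_equal(step, rep(1.7 * 15 / 60, length(step)), tolerance = 1e-12)
    # collinear: all displacement vectors parallel to the first
    expect_true(all(abs(dx * dy[1] - dy * dx[1]) < 1e-9))
  }
})

test_that("mean per-frame displacement equals speed times frame interval", {
  # 10 cells x 60 min = 2400 steps; heading jitter preserves step magnitude
  cfg <- simulation_config(n_cells = 10, duration = 3600, reversal_rate = 0,
                           stickslip_rate = 0, speed_sd = 0,
                           field_size = c(4000, 4000), rng_seed = 11)
  tr <- simulate_trajectories(cfg)
  steps <- unlist(lapply(tr$cells, function(cl)
    sqrt(diff(cl$traj$x_um)^2 + diff(cl$traj$y_um)^2)))
  expect_gt(length(steps), 1000)
  expect_equal(mean(steps), 1.7 * 15 / 60, tolerance = 1e-9)
})

test_that("reversal counts over many cells match the Poisson rate", {
  # 0.1/min x 100 cells x 30 min -> about 300, within 3 * sqrt(300)
  cfg <- simulation_config(n_cells = 100, duration = 1800,
                           reversal_rate = 0.1, stickslip_rate = 0,
                           field_size = c(4000, 4000), rng_seed = 3)
  tr <- simulate_trajectories(cfg)
  n_rev <- sum(tr$events$type == "reversal")
  expect_lt(abs(n_rev - 300), 3 * sqrt(300))
})

test_that("inter-event gaps beyond the dead time are exponential", {
  cfg <- simulation_config(n_cells = 150, duration = 3600,
                           reversal_rate = 0.1, stickslip_rate = 0,
                           field_size = c(4000, 4000), rng_seed = 17)
  tr <- simulate_trajectories(cfg)
  gaps_min <- unlist(lapply(split(tr$events$time_exact_s, tr$events$cell),
                            function(tt) diff(sort(tt)) / 60))
  dead <- cfg$event_refractory / 60
  expect_gt(length(gaps_min), 150)
  expect_true(all(gaps_min > dead))
  # independent renewal oracle observed through the same time window (fully
  # contained gaps are length-biased, so an iid reference would be wrong)
  set.seed(4242)
  oracle_gaps <- unlist(replicate(150, {
    tt <- c()
    t_cur <- stats::rexp(1, 0.1)   # first-arrival law hardly matters here
    while (t_cur < 60) {
      tt <- c(tt, t_cur)
      t_cur <- t_cur + dead + stats::rexp(1, 1 / (1 / 0.1 - dead))
    }
    diff(tt)
  }, simplify = FALSE))
  ks <- suppressWarnings(stats::ks.test(gaps_min, oracle_gaps))
  expect_gt(ks$p.value, 0.01)
})

test_that("pole fluorescence exchanges exactly at reversals", {
  cfg <- simulation_config(n_cells = 30, duration = 1800,
                           reversal_rate = 0.15, stickslip_rate = 0.15,
                           field_size = c(4000, 4000), rng_seed = 23)
  tr <- simulate_trajectories(cfg)
  k <- cfg$fluor_relocalization_frames
  for (i in seq_along(tr$cells)) {
    traj <- tr$cells[[i]]$traj
    dom <- sign(traj$fluor1 - traj$fluor2)
    flips <- which(diff(dom) != 0 & dom[-1] != 0 & dom[-length(dom)] != 0)
    ev <- tr$events[tr$events$cell == i, ]
    rev_frames <- ev$frame[ev$type == "reversal"]
    ss_frames <- ev$frame[ev$type == "stickslip"]
    # every dominance flip lies within k frames of a true reversal
    for (f in flips)
      expect_true(min(abs(rev_frames - traj$frame[f])) <= k,
                  label = sprintf("flip at frame %d matches a reversal",
                                  traj$frame[f]))
    # every reversal produces a flip; no stick-slip does
    for (rf in rev_frames)
      expect_true(any(abs(traj$frame[flips] - rf) <= k))
    for (sf in ss_frames)
      expect_false(any(abs(traj$frame[flips] - sf) == 0))
  }
})

test_that("simulation and rendering are reproducible under a fixed seed", {
  cfg <- simulation_config(n_cells = 3, duration = 300, noise_sd = 0.02,
                           field_size = c(128, 96), pixel_size = 0.2,
                           rng_seed = 9)
  tr1 <- simulate_trajectories(cfg)
  tr2 <- simulate_trajectories(cfg)
  expect_identical(tr1, tr2)
  expect_identical(render_movie(tr1), render_movie(tr2))
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(reversal_rate = -1), "rates")
  expect_error(simulation_config(pixel_size = 0), "pixel_size")
  expect_error(simulation_config(frame_interval = NaN), "non-finite")
  expect_error(simulation_config(speed_mean = 0), "speed_mean")
  # dead time incompatible with the requested rate
  expect_error(simulation_config(reversal_rate = 0.6, stickslip_rate = 0.5,
                                 event_refractory = 60), "event_refractory")
})

test_that("ground truth JSON round trip is lossless", {
  cfg <- simulation_config(n_cells = 4, duration = 600, rng_seed = 13,
                           field_size = c(256, 256), pixel_size = 0.2)
  tr <- simulate_trajectories(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(tr, path)
  back <- read_ground_truth(path)
  expect_equal(length(back$cells), 4)
  for (i in 1:4) {
    expect_equal(back$cells[[i]]$traj, tr$cells[[i]]$traj)
    expect_equal(back$cells[[i]]$speed_um_min, tr$cells[[i]]$speed_um_min)
  }
  expect_equal(back$events$frame, tr$events$frame)
  expect_equal(back$events$type, tr$events$type)
  expect_equal(back$config$speed_mean, tr$config$speed_mean)
})

test_that("ground truth files enumerate every cell and reject bad records", {
  cfg <- simulation_config(n_cells = 20, duration = 300, rng_seed = 2,
                           field_size = c(1000, 1000))
  tr <- simulate_trajectories(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(tr, path)
  raw <- jsonlite::read_json(path)
  expect_length(raw$cells, 20)

  # tamper: negative event time must be rejected with context
  raw$events$time_s[[1]] <- -15
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_ground_truth(bad), "negative event time")
  expect_error(read_ground_truth("/nonexistent/truth.json"), "no such file")
})
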