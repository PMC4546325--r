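test_that("turn angles at canonical triplets are exact", {
  expect_equal(compute_turn_angle(c(0, 0), c(1, 0), c(2, 0)), 180)
  expect_equal(compute_turn_angle(c(0, 0), c(1, 0), c(0, 0)), 0)
  expect_equal(compute_turn_angle(c(0, 0), c(1, 0), c(1, 1)), 90)
  expect_true(is.na(compute_turn_angle(c(1, 0), c(1, 0), c(2, 0))))
})

test_that("turn angle is invariant under rotation, translation and scaling", {
  set.seed(19)
  for (k in 1:50) {
    p <- matrix(stats::rnorm(6), 3, 2)
    ang0 <- compute_turn_angle(p[1, ], p[2, ], p[3, ])
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    s <- stats::runif(1, 0.1, 10)
    shift <- stats::rnorm(2, 0, 50)
    q <- s * p %*% R + rep(shift, each = 3)
    expect_equal(compute_turn_angle(q[1, ], q[2, ], q[3, ]), ang0,
                 tolerance = 1e-9)
  }
})

test_that("the strict 90-degree rule calls reversal vertices", {
  # straight track: no events
  tr <- make_track(0.5 * (0:20), rep(0, 21))
  expect_equal(nrow(call_directional_changes(tr, min_step = 0)), 0)
  # one scripted retrace
  x <- c(0:5, 4:0) * 0.5
  tr <- make_track(x, rep(0, 11))
  ev <- call_directional_changes(tr, min_step = 0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 5)
  expect_equal(ev$turn_angle_deg, 0)
  # a vertex at exactly the threshold is NOT an event
  tr90 <- make_track(c(0, 1, 1), c(0, 0, 1))
  expect_equal(nrow(call_directional_changes(tr90, min_step = 0)), 0)
  expect_equal(nrow(call_directional_changes(tr90, angle_threshold = 90.01,
                                             min_step = 0)), 1)
})

test_that("zig-zag vertices match brute-force enumeration", {
  # 20 segments; heading changes alternate 150 and 10 degrees, so vertex
  # angles alternate 30 (event) and 170 (no event): 10 events expected
  delta <- rep(c(150, 10), length.out = 19)
  heads <- cumsum(c(0, delta)) * pi / 180
  x <- cumsum(c(0, cos(heads)))
  y <- cumsum(c(0, sin(heads)))
  tr <- make_track(x, y)
  # brute-force: count interior vertices with angle < 90
  angles <- vapply(2:(length(x) - 1), function(t)
    compute_turn_angle(c(x[t - 1], y[t - 1]), c(x[t], y[t]),
                       c(x[t + 1], y[t + 1])), numeric(1))
  expect_equal(sum(angles < 90), 10)
  ev <- call_directional_changes(tr, min_step = 0, refractory = 0)
  expect_equal(nrow(ev), 10)
  expect_equal(ev$frame, which(angles < 90))
})

test_that("the refractory window merges multi-vertex events", {
  # stick-slip-like double vertex at frames 5 and 6: forward, 0.7 um back,
  # then return and resume
  x <- c(0, 0.5, 1, 1.5, 2, 2.5, 1.8, 3.0, 3.5, 4.0, 4.5)
  tr <- make_track(x, rep(0, 11))
  ev0 <- call_directional_changes(tr, min_step = 0, refractory = 0)
  expect_equal(nrow(ev0), 2)
  ev2 <- call_directional_changes(tr, min_step = 0, refractory = 2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$frame, min(ev0$frame))
  expect_equal(ev2$n_merged, 2L)
})

test_that("the displacement gate suppresses sub-step vertices", {
  x <- c(0, 0.5, 0.55, 1.05, 1.6)   # tiny middle step with sharp pseudo-angle
  y <- c(0, 0, 0.04, 0.04, 0.04)
  tr <- make_track(x, y)
  ev <- call_directional_changes(tr, min_step = 0.2)
  expect_equal(nrow(ev), 0)
})

test_that("fluorescence switches are found at trace crossings only", {
  base <- make_track(0.5 * (0:29), rep(0, 30))
  # constant dominance: no switch
  t1 <- transform(base, pole1_int = 1, pole2_int = 0.3)
  expect_equal(nrow(detect_fluor_switches(t1)), 0)
  # step exchange at frame 15, persistent
  t2 <- transform(base, pole1_int = c(rep(1, 15), rep(0.3, 15)),
                  pole2_int = c(rep(0.3, 15), rep(1, 15)))
  sw <- detect_fluor_switches(t2, smoothing = 3, min_persistence = 2)
  expect_equal(nrow(sw), 1)
  expect_lte(abs(sw$frame - 15), 1)
  expect_equal(sw$pre_dominant, "pole1")
  expect_equal(sw$post_dominant, "pole2")
  # one-frame flicker rejected by the persistence filter
  p1 <- rep(1, 30); p1[10] <- 0.1
  p2 <- rep(0.3, 30); p2[10] <- 0.9
  t3 <- transform(base, pole1_int = p1, pole2_int = p2)
  expect_equal(nrow(detect_fluor_switches(t3, smoothing = 1,
                                          min_persistence = 3)), 0)
  # all-zero fluorescence warns
  t4 <- transform(base, pole1_int = 0, pole2_int = 0)
  expect_warning(sw4 <- detect_fluor_switches(t4), "all-zero")
  expect_equal(nrow(sw4), 0)
})

test_that("events are classified by switch coincidence", {
  ev <- data.frame(track_id = 1L, frame = 10L, turn_angle_deg = 20,
                   step_before_um = 0.4, step_after_um = 0.4, n_merged = 1L)
  sw <- data.frame(track_id = 1L, frame = 11L, pre_dominant = "pole1",
                   post_dominant = "pole2", persistence = 5L)
  out <- classify_events(ev, sw, window = 2)
  expect_equal(out$classification, "confirmed")
  expect_equal(out$matched_switch_frame, 11L)
  out2 <- classify_events(ev, sw[0, ], window = 2)
  expect_equal(out2$classification, "stick_slip")
  out3 <- classify_events(ev, NULL, window = 2)
  expect_equal(out3$classification, "unconfirmed")
  # far-away switch is not consumed
  sw_far <- transform(sw, frame = 20L)
  expect_equal(classify_events(ev, sw_far, 2)$classification, "stick_slip")
})

test_that("a mixed population separates reversals from stick-slips perfectly at zero noise", {
  cfg <- simulation_config(n_cells = 40, duration = 1800,
                           reversal_rate = 0.1, stickslip_rate = 0.1,
                           field_size = c(4000, 4000), rng_seed = 29)
  tr <- simulate_trajectories(cfg)
  res <- run_pipeline(tr, pipeline_config(min_step = 0))
  v <- validate_events(res$events, tr, res$tracks)
  expect_equal(v$precision, 1)
  expect_equal(v$recall, 1)
  expect_equal(v$stickslip_confirmed, 0)
  expect_equal(v$stickslip_recall, 1)
  # event-count ordering invariant
  expect_lte(res$log$n_confirmed, res$log$n_events)
})

test_that("per-cell reversal statistics follow the arithmetic definition", {
  tr <- make_track(0.5 * (0:120), rep(0, 121))  # 30 min at 15 s
  ev <- data.frame(track_id = 1L, frame = c(10, 30, 50, 70, 90, 110),
                   classification = "confirmed")
  st <- reversal_statistics(tr, ev, mode = "confirmed")
  expect_equal(st$freq_per_10min, 2)
  expect_equal(st$mean_interreversal_min, mean(diff(c(10, 30, 50, 70, 90, 110)) * 15) / 60)
  st0 <- reversal_statistics(tr, ev[0, ], mode = "confirmed")
  expect_equal(st0$freq_per_10min, 0)
  expect_true(is.na(st0$mean_interreversal_min))
})

test_that("the frequency estimator is unbiased on renewal truth", {
  cfg <- simulation_config(n_cells = 100, duration = 1800,
                           reversal_rate = 0.1, stickslip_rate = 0,
                           field_size = c(4000, 4000), rng_seed = 37)
  tr <- simulate_trajectories(cfg)
  res <- run_pipeline(tr, pipeline_config(min_step = 0))
  est <- mean(res$per_cell$freq_per_10min)
  se <- stats::sd(res$per_cell$freq_per_10min) / sqrt(nrow(res$per_cell))
  expect_lt(abs(est - 1.0), 2 * se + 1e-12)
})

test_that("precision degrades monotonically as fluorescence noise grows", {
  cfg <- simulation_config(n_cells = 60, duration = 1800,
                           reversal_rate = 0.08, stickslip_rate = 0.15,
                           field_size = c(4000, 4000), rng_seed = 41)
  tr <- simulate_trajectories(cfg)
  prec <- vapply(c(0, 0.18, 0.5), function(noise) {
    tr_n <- tr
    set.seed(77)
    for (i in seq_along(tr_n$cells)) {
      n <- nrow(tr_n$cells[[i]]$traj)
      tr_n$cells[[i]]$traj$fluor1 <- tr_n$cells[[i]]$traj$fluor1 +
        stats::rnorm(n, 0, noise)
      tr_n$cells[[i]]$traj$fluor2 <- tr_n$cells[[i]]$traj$fluor2 +
        stats::rnorm(n, 0, noise)
    }
    res <- run_pipeline(tr_n, pipeline_config(min_step = 0))
    validate_events(res$events, tr, res$tracks)$precision
  }, numeric(1))
  expect_equal(prec[1], 1)
  expect_true(all(diff(prec) <= 1e-9))
  expect_lt(prec[3], 1)
})
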