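test_that("the noiseless driver follows the centerline at the geometric yaw rate", {
  tr <- build_track(track_spec(n_turns = 3))
  tel <- simulate_driver(tr, kmh_to_ms(47), 30, lateral_noise_sd = 0)
  expect_lt(max(abs(tel$lateral)), 1e-12)
  yaw <- mean(abs(diff(tel$heading))) * 60 * 180 / pi
  expect_equal(yaw, yaw_rate(47, 50), tolerance = 1e-3)
})

test_that("lateral wander has the configured stationary SD and same-seed runs are identical", {
  tr <- build_track(track_spec(n_turns = 52))
  tel <- simulate_driver(tr, kmh_to_ms(47), 600, lateral_noise_sd = 0.35,
                         seed = 21)
  expect_lt(abs(sd(tel$lateral) - 0.35) / 0.35, 0.2)
  tel_b <- simulate_driver(tr, kmh_to_ms(47), 600, lateral_noise_sd = 0.35,
                           seed = 21)
  expect_identical(tel, tel_b)
  gz <- simulate_gaze_exp1(tel[tel$t <= 60, ], seed = 4)
  gz_b <- simulate_gaze_exp1(tel[tel$t <= 60, ], seed = 4)
  expect_identical(gz, gz_b)
})

test_that("open-loop gaze lands at the target time headway and launches a pursuit later", {
  tr <- build_track(track_spec(n_turns = 10))
  v <- kmh_to_ms(53)
  tel <- simulate_driver(tr, v, 90, lateral_noise_sd = 0.35, seed = 31)
  gz <- simulate_gaze_exp1(tel, target_th = 2, pursuit_duration = 0.4,
                           gaze_noise_sd = 0, landing_sd = 0, seed = 32)
  ev <- gaze_events(gz)
  # generator-true landing targets sit exactly at TH 2; measure via the
  # time-headway machinery on the true landing points
  sac <- ev[seq(5, nrow(ev) - 5, by = 4), ]
  sac <- tibble::tibble(launch_t = sac$launch_t, launch_px = sac$launch_px,
                        launch_py = sac$launch_py, landing_t = sac$landing_t,
                        landing_px = sac$landing_px,
                        landing_py = sac$landing_py)
  rec <- compute_th_records(sac, tel)
  land <- rec$th[rec$kind == "saccade_landing"]
  laun <- rec$th[rec$kind == "saccade_launch"]
  expect_equal(median(land, na.rm = TRUE), 2, tolerance = 0.05)
  expect_equal(median(laun, na.rm = TRUE), 1.6, tolerance = 0.07)
  # zero-noise pursuit tracks the target's screen motion (gain 1)
  expect_lt(median(abs(diff(ev$launch_t) - 0.45)), 0.05)
})

test_that("a target time headway projecting off-screen is a parameter error", {
  tr <- build_track(track_spec(n_turns = 3))
  tel <- simulate_driver(tr, kmh_to_ms(47), 20, lateral_noise_sd = 0)
  expect_error(simulate_gaze_exp1(tel, target_th = 0.2), "below the screen")
})

test_that("predictive agents saccade into gaps; reactive agents stay on the last waypoint", {
  tr <- build_track(track_spec(n_turns = 5))
  v <- design_speed()
  sched <- schedule_waypoints(tr, v, seed = 9)
  tel <- simulate_driver(tr, v, 4 * tr$turn_length / v,
                         lateral_noise_sd = 0.25, seed = 10)
  cam <- camera_spec()
  gz_p <- simulate_gaze_exp2(tel, sched, cam,
                             gaze_strategy("predictive", gaze_noise_sd = 0),
                             seed = 11)
  ev_p <- gaze_events(gz_p)
  miss <- ev_p[ev_p$status == "missing", ]
  expect_gt(nrow(miss), 0)
  # each gap response lands within landing scatter of the missing
  # waypoint's projected location, before the next waypoint appears
  itp <- gazeway:::telemetry_interpolator(tel)
  vw <- viewing_geometry()
  for (i in seq_len(nrow(miss))) {
    slot <- sched[sched$turn == miss$turn[i] & sched$slot == miss$slot[i], ]
    pr <- gazeway:::proj_point_over_time(itp, cam, miss$landing_t[i],
                                         slot$x, slot$y)
    d <- screen_angular_distance(miss$landing_px[i], miss$landing_py[i],
                                 pr$px, pr$py, vw)
    expect_lt(d, 3 * 0.5 + 0.5)   # within landing scatter
    expect_lt(miss$landing_t[i], miss$appear_t[i] + 1.2)
  }
  # reactive: no saccade between a gap's nominal appearance and the next
  # real appearance
  gz_r <- simulate_gaze_exp2(tel, sched, cam, gaze_strategy("reactive"),
                             seed = 12)
  ev_r <- gaze_events(gz_r)
  expect_false(any(ev_r$status == "missing"))
  gaps <- sched[sched$status == "missing" & sched$slot < 16, ]
  for (i in seq_len(nrow(gaps))) {
    launches <- ev_r$launch_t
    expect_false(any(launches >= gaps$appear_t[i] &
                       launches < gaps$appear_t[i] + 0.75))
  }
})

test_that("degrade drops the configured fraction below the confidence threshold", {
  tr <- build_track(track_spec(n_turns = 3))
  tel <- simulate_driver(tr, kmh_to_ms(47), 25, lateral_noise_sd = 0)
  gz <- simulate_gaze_exp1(tel, seed = 1)
  expect_identical(degrade(gz, dropout_rate = 0), gz)
  dg <- degrade(gz, dropout_rate = 0.1, seed = 2)
  frac <- mean(dg$confidence < 0.6)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(gz)))
  # burst mode: contiguous low-confidence runs bounded by the cap
  db <- degrade(gz, dropout_rate = 0.1, burst = TRUE, burst_max = 2,
                seed = 3)
  runs <- rle(db$confidence < 0.6)
  max_run <- max(c(0, runs$lengths[runs$values]))
  expect_lte(max_run * median(diff(gz$t)), 2 + 0.2)
  expect_error(degrade(gz, dropout_rate = 1.5), "dropout")
})
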