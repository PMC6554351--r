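# Shared synthetic fixtures, built in code at test time.

default_vw <- viewing_geometry()
default_cam <- camera_spec()

# Fixation-saccade staircase with known event times: the canonical
# segmentation benchmark (stationary fixations separated by jumps of
# amp_lo..amp_hi degrees, transit 30-80 ms, isotropic sample noise).
make_staircase <- function(seed, n_sac = 80, hz = 30, noise = 0.5,
                           amp_lo = 2, amp_hi = 8, fix_dur = 0.35,
                           viewing = default_vw) {
  set.seed(seed)
  pos <- matrix(0, n_sac + 1, 2)
  amps <- numeric(n_sac)
  for (i in seq_len(n_sac)) {
    repeat {
      a <- runif(1, amp_lo, amp_hi)
      th <- runif(1, 0, 2 * pi)
      cand <- pos[i, ] + a * c(cos(th), sin(th))
      if (all(abs(cand) < 15)) break
    }
    pos[i + 1, ] <- cand
    amps[i] <- a
  }
  transit <- runif(n_sac, 0.03, 0.08)
  knot_t <- 0; knot_x <- pos[1, 1]; knot_y <- pos[1, 2]
  tcur <- 0.3
  for (i in seq_len(n_sac)) {
    knot_t <- c(knot_t, tcur, tcur + transit[i])
    knot_x <- c(knot_x, pos[i, 1], pos[i + 1, 1])
    knot_y <- c(knot_y, pos[i, 2], pos[i + 1, 2])
    tcur <- tcur + transit[i] + fix_dur
  }
  knot_t <- c(knot_t, tcur + 0.3)
  knot_x <- c(knot_x, pos[n_sac + 1, 1])
  knot_y <- c(knot_y, pos[n_sac + 1, 2])
  t <- seq(0, max(knot_t), by = 1 / hz)
  dx <- approx(knot_t, knot_x, t)$y + rnorm(length(t), 0, noise)
  dy <- approx(knot_t, knot_y, t)$y + rnorm(length(t), 0, noise)
  m <- viewing$distance / viewing$m_per_px
  list(
    gaze = tibble::tibble(
      t = t,
      px = viewing$cx + tan(dx * pi / 180) * m,
      py = viewing$cy + tan(dy * pi / 180) * m,
      confidence = 1),
    launch_t = knot_t[seq(2, 2 * n_sac, by = 2)],
    landing_t = knot_t[seq(3, 2 * n_sac + 1, by = 2)],
    amplitude = amps)
}

# One waypoint-steering agent: schedule, constant-speed telemetry, gaze
# under a strategy mode, and the full analysis products.
run_exp2_agent <- function(seed, mode, n_turns = 16, lateral_sd = 0.35,
                           strategy_args = list()) {
  track <- build_track(track_spec(n_turns = n_turns + 1))
  v <- design_speed()
  sched <- schedule_waypoints(track, v, seed = seed)
  telemetry <- simulate_driver(track, v, n_turns * track$turn_length / v,
                               lateral_noise_sd = lateral_sd,
                               seed = seed + 1000)
  strat <- do.call(gaze_strategy, c(list(mode = mode), strategy_args))
  gaze <- simulate_gaze_exp2(telemetry, sched, default_cam, strat,
                             seed = seed + 2000)
  saccades <- detect_saccades(filter_confidence(gaze), default_vw)
  aoi <- exp2_aoi_assignments(gaze, telemetry, sched, default_cam,
                              default_vw)
  late <- select_late_saccades(saccades, sched)
  vectors <- exp2_saccade_vectors(late, telemetry, sched, default_cam,
                                  default_vw)
  list(track = track, schedule = sched, telemetry = telemetry,
       gaze = gaze, saccades = saccades, aoi = aoi,
       curves = catch_curves(aoi), late = late, vectors = vectors)
}

# One rich-flow steering run at a target time headway.
run_exp1_trial <- function(seed, speed_kmh = 53, duration = 120,
                           target_th = 2, pursuit_duration = 0.4) {
  v <- kmh_to_ms(speed_kmh)
  n_turns <- ceiling(v * (duration + target_th + 1) /
                       (pi * 50)) + 1
  track <- build_track(track_spec(n_turns = n_turns))
  telemetry <- simulate_driver(track, v, duration, seed = seed)
  gaze <- simulate_gaze_exp1(telemetry, default_cam, target_th = target_th,
                             pursuit_duration = pursuit_duration,
                             seed = seed + 500)
  saccades <- detect_saccades(filter_confidence(gaze), default_vw)
  list(telemetry = telemetry, gaze = gaze, saccades = saccades,
       records = compute_th_records(saccades, telemetry, default_cam),
       intervals = pursuit_intervals(saccades))
}
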