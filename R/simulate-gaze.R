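#' Parameterize a synthetic gaze strategy
#'
#' The four modes operationalize competing hypotheses about gaze control at
#' waypoint gap events:
#' * `predictive`: saccade, after a latency, to every scheduled waypoint
#'   location — including missing ones (anticipatory saccades into the gap).
#' * `reactive`: saccade only to waypoints that actually appear; at a gap,
#'   keep pursuing the last visible waypoint until the next one appears.
#' * `fixed_screen_point`: pursuit drags gaze with the scene, but every
#'   saccade returns to one typical screen location.
#' * `constant_motor_program`: every saccade has the same screen vector
#'   (mirrored with turn direction), regardless of target location.
#'
#' @param mode Strategy mode (see above).
#' @param saccade_latency Mean saccade latency after a (nominal) waypoint
#'   appearance, seconds.
#' @param saccade_latency_sd SD of the per-event latency, seconds.
#' @param gap_latency_shift Extra mean latency for responses to missing
#'   waypoints, seconds (predictive mode; anticipatory saccades are slower
#'   than visually triggered ones).
#' @param latency_bounds Truncation bounds for latencies, seconds.
#' @param pursuit_gain Gain of pursuit relative to target screen motion.
#' @param pursuit_duration Slow-phase duration for the open-loop generator,
#'   seconds.
#' @param gaze_noise_sd Per-sample isotropic gaze noise, degrees.
#' @param landing_sd Saccade landing scatter, degrees.
#' @param transit_range Saccade transit duration range, seconds.
#' @param gap_response_prob Probability that a predictive agent responds
#'   to a missing-waypoint event at all (1 by default; humans saccade into
#'   only a subset of gaps, which sub-unit values emulate).
#' @param dropout_rate Fraction of low-confidence samples for [degrade()].
#' @param fixed_point Screen point (px) for `fixed_screen_point` mode;
#'   `NULL` computes a typical FAR-waypoint location from the geometry.
#' @param seed Optional RNG seed.
#' @return A `gw_strategy` list.
#' @export
gaze_strategy <- function(mode = c("predictive", "reactive",
                                   "fixed_screen_point",
                                   "constant_motor_program"),
                          saccade_latency = 0.35, saccade_latency_sd = 0.15,
                          gap_latency_shift = 0.12,
                          latency_bounds = c(0.2, 1.2),
                          pursuit_gain = 1, pursuit_duration = 0.4,
                          gaze_noise_sd = 0.3, landing_sd = 0.5,
                          transit_range = c(0.03, 0.08),
                          gap_response_prob = 1,
                          dropout_rate = 0, fixed_point = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (saccade_latency <= 0 || pursuit_duration <= 0) {
    abort("latencies and durations must be > 0")
  }
  if (gaze_noise_sd < 0 || landing_sd < 0) abort("noise SDs must be >= 0")
  structure(
    list(mode = mode, saccade_latency = saccade_latency,
         saccade_latency_sd = saccade_latency_sd,
         gap_latency_shift = gap_latency_shift,
         latency_bounds = latency_bounds,
         pursuit_gain = pursuit_gain, pursuit_duration = pursuit_duration,
         gaze_noise_sd = gaze_noise_sd, landing_sd = landing_sd,
         transit_range = transit_range,
         gap_response_prob = gap_response_prob, dropout_rate = dropout_rate,
         fixed_point = fixed_point, seed = seed),
    class = "gw_strategy"
  )
}

# vectorized pinhole projection of one ground point seen from interpolated
# poses at `times` (level camera; generators do not model roll)
proj_point_over_time <- function(itp, camera, times, pwx, pwy) {
  h <- itp$heading(times)
  vx <- pwx - itp$x(times); vy <- pwy - itp$y(times)
  f_comp <- vx * cos(h) + vy * sin(h)
  r_comp <- vx * sin(h) - vy * cos(h)
  px <- camera$cx + camera$f * r_comp / f_comp
  py <- camera$cy + camera$f * camera$eye_height / f_comp
  bad <- f_comp <= camera$near
  px[bad] <- NA_real_; py[bad] <- NA_real_
  list(px = px, py = py, depth = f_comp)
}

deg_to_px <- function(deg, camera) camera$f * tan(deg2rad(deg))

fill_forward <- function(v, first = NA_real_) {
  if (all(is.na(v))) return(rep(first, length(v)))
  i <- which(!is.na(v))
  if (i[1] > 1 && !is.na(first)) { v[1] <- first; i <- c(1L, i) }
  idx <- findInterval(seq_along(v), i)
  idx[idx == 0] <- 1
  v[i][idx]
}

r_trunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

finalize_gaze <- function(t, px, py, camera, noise_sd) {
  keep <- !is.na(px) & !is.na(py)
  t <- t[keep]; px <- px[keep]; py <- py[keep]
  n <- length(t)
  if (noise_sd > 0) {
    px <- px + rnorm(n, 0, deg_to_px(noise_sd, camera))
    py <- py + rnorm(n, 0, deg_to_px(noise_sd, camera))
  }
  tibble::tibble(t = t, px = px, py = py, confidence = rep(1, n))
}

#' Simulate open-loop waypoint-tracking gaze (rich-flow steering)
#'
#' Emulates the optokinetic pursue-then-saccade cycle observed when humans
#' steer a textured winding path: gaze picks a world-fixed ground point at
#' `target_th` seconds of travel ahead on the driver's future trajectory,
#' pursues its screen projection for `pursuit_duration` seconds (during
#' which its time headway shrinks), then saccades to a fresh point at
#' `target_th`. Landing time headways therefore cluster at `target_th` and
#' launch time headways at `target_th - pursuit_duration`.
#'
#' @param telemetry Telemetry tibble (see [simulate_driver()]).
#' @param camera A [camera_spec()].
#' @param target_th Time headway of new targets, seconds.
#' @param pursuit_duration Slow-phase duration, seconds.
#' @param pursuit_gain Pursuit gain (1 = perfect tracking).
#' @param gaze_noise_sd Per-sample gaze noise, degrees.
#' @param landing_sd Saccade landing scatter, degrees.
#' @param transit_range Saccade transit duration range, seconds.
#' @param hz Gaze sampling rate, Hz.
#' @param seed Optional RNG seed.
#' @return Gaze tibble `t`, `px`, `py`, `confidence`, with the true saccade
#'   events attached (see [gaze_events()]).
#' @export
simulate_gaze_exp1 <- function(telemetry, camera = camera_spec(),
                               target_th = 2, pursuit_duration = 0.4,
                               pursuit_gain = 1, gaze_noise_sd = 0.3,
                               landing_sd = 0.5,
                               transit_range = c(0.03, 0.08),
                               hz = 30, seed = NULL) {
  new_seeded_rng(seed)
  itp <- telemetry_interpolator(telemetry)
  t_end <- itp$t_max - target_th - 0.2
  if (t_end <= itp$t_min + 1) abort("telemetry too short for this target_th")
  # check the target is on screen at this speed
  v <- itp$speed(itp$t_min)
  depression <- rad2deg(atan(camera$eye_height / (v * target_th)))
  if (depression > camera$vfov / 2) {
    abort("`target_th` projects below the screen at this speed")
  }
  sample_t <- seq(itp$t_min, t_end, by = 1 / hz)
  px <- py <- rep(NA_real_, length(sample_t))
  traj_at <- function(t) c(itp$x(t), itp$y(t))
  events <- vector("list", 4096)
  n_ev <- 0
  landing_t <- itp$t_min
  pw <- traj_at(landing_t + target_th)
  offset <- c(0, 0)
  decay <- 0.15
  repeat {
    launch_t <- landing_t + pursuit_duration
    tau <- runif(1, transit_range[1], transit_range[2])
    if (launch_t + tau >= t_end) {
      idx <- which(sample_t >= landing_t)
    } else {
      idx <- which(sample_t >= landing_t & sample_t < launch_t)
    }
    if (length(idx)) {
      base <- proj_point_over_time(itp, camera, sample_t[idx], pw[1], pw[2])
      b0 <- proj_point_over_time(itp, camera, landing_t, pw[1], pw[2])
      dec <- exp(-(sample_t[idx] - landing_t) / decay)
      px[idx] <- b0$px + pursuit_gain * (base$px - b0$px) + offset[1] * dec
      py[idx] <- b0$py + pursuit_gain * (base$py - b0$py) + offset[2] * dec
    }
    if (launch_t + tau >= t_end) break
    bl <- proj_point_over_time(itp, camera, launch_t, pw[1], pw[2])
    b0 <- proj_point_over_time(itp, camera, landing_t, pw[1], pw[2])
    launch_pos <- c(
      b0$px + pursuit_gain * (bl$px - b0$px) +
        offset[1] * exp(-pursuit_duration / decay),
      b0$py + pursuit_gain * (bl$py - b0$py) +
        offset[2] * exp(-pursuit_duration / decay))
    landing2_t <- launch_t + tau
    pw2 <- traj_at(landing2_t + target_th)
    offset2 <- deg_to_px(rnorm(2, 0, landing_sd), camera)
    b2 <- proj_point_over_time(itp, camera, landing2_t, pw2[1], pw2[2])
    landing_pos <- c(b2$px + offset2[1], b2$py + offset2[2])
    idx2 <- which(sample_t >= launch_t & sample_t < landing2_t)
    if (length(idx2)) {
      frac <- (sample_t[idx2] - launch_t) / tau
      px[idx2] <- launch_pos[1] + frac * (landing_pos[1] - launch_pos[1])
      py[idx2] <- launch_pos[2] + frac * (landing_pos[2] - launch_pos[2])
    }
    n_ev <- n_ev + 1
    events[[n_ev]] <- tibble::tibble(
      launch_t = launch_t, landing_t = landing2_t,
      launch_px = launch_pos[1], launch_py = launch_pos[2],
      landing_px = landing_pos[1], landing_py = landing_pos[2],
      target_x = pw2[1], target_y = pw2[2])
    landing_t <- landing2_t
    pw <- pw2
    offset <- offset2
  }
  out <- finalize_gaze(sample_t, px, py, camera, gaze_noise_sd)
  attr(out, "events") <- dplyr::bind_rows(events[seq_len(n_ev)])
  out
}

#' True generator events attached to a synthetic gaze log
#'
#' @param gaze A gaze tibble from [simulate_gaze_exp1()] or
#'   [simulate_gaze_exp2()].
#' @return Tibble of the generator's true saccade events.
#' @export
gaze_events <- function(gaze) {
  ev <- attr(gaze, "events")
  if (is.null(ev)) abort("no generator events attached to this gaze log")
  ev
}

# typical screen location of a FAR-range waypoint, from steady-state
# geometry on the centerline (used by the null strategies)
typical_far_point <- function(camera, speed, th = 1.6) {
  d <- speed * th
  c(camera$cx, camera$cy + camera$f * camera$eye_height / d)
}

#' Simulate gaze during waypoint-only steering
#'
#' Event-driven generator: at each (nominal) waypoint appearance the agent
#' may respond with a saccade after a latency, then pursues a world-fixed
#' point until its next saccade, per the chosen [gaze_strategy()]. When a
#' pursued point leaves the screen, gaze holds its last position.
#'
#' @param telemetry Telemetry tibble (constant-speed run on the scheduled
#'   track).
#' @param schedule A [schedule_waypoints()] table.
#' @param camera A [camera_spec()].
#' @param strategy A [gaze_strategy()].
#' @param hz Gaze sampling rate, Hz.
#' @param seed RNG seed (overridden by `strategy$seed` if set).
#' @return Gaze tibble with true response events attached
#'   (see [gaze_events()]): one row per executed saccade with the slot it
#'   responded to.
#' @export
simulate_gaze_exp2 <- function(telemetry, schedule, camera = camera_spec(),
                               strategy = gaze_strategy("predictive"),
                               hz = 30, seed = NULL) {
  new_seeded_rng(strategy$seed %||% seed)
  itp <- telemetry_interpolator(telemetry)
  v <- attr(schedule, "nominal_speed")
  t0 <- itp$t_min; t_end <- itp$t_max - 0.2
  sample_t <- seq(t0, t_end, by = 1 / hz)
  px <- py <- rep(NA_real_, length(sample_t))
  decay <- 0.15

  sched <- dplyr::arrange(schedule, .data$appear_t)
  sched <- sched[sched$appear_t > t0 + 0.5 & sched$appear_t < t_end - 1, ]
  respond <- if (strategy$mode == "predictive") {
    sched$status == "visible" |
      runif(nrow(sched)) < strategy$gap_response_prob
  } else {
    sched$status == "visible"
  }
  ev <- sched[respond, ]
  lat_mean <- strategy$saccade_latency +
    ifelse(ev$status == "missing", strategy$gap_latency_shift, 0)
  latency <- r_trunc_norm(nrow(ev), lat_mean, strategy$saccade_latency_sd,
                          strategy$latency_bounds[1],
                          strategy$latency_bounds[2])
  ev$launch_t <- ev$appear_t + latency
  ev$tau <- runif(nrow(ev), strategy$transit_range[1],
                  strategy$transit_range[2])
  ev <- dplyr::arrange(ev, .data$launch_t)

  turn_dir <- function(turn) {
    d0 <- if (attr(schedule, "first_dir") %||% "left" == "left") 1 else -1
    d0 * (-1)^(turn - 1)
  }
  pf <- strategy$fixed_point %||% typical_far_point(camera, v)
  # constant motor vector: typical FAR-landing minus typical MID-launch
  motor_dy <- camera$f * camera$eye_height * (1 / (v * 1.9) - 1 / (v * 1.15))

  # initial pursuit target: nearest slot ahead with th ~ 1 s
  s0 <- v * t0
  first <- which(sched$arclength > s0 + v)[1]
  pw <- c(sched$x[first], sched$y[first])
  hold_pw <- TRUE
  offset <- c(0, 0)
  landing_prev <- t0
  events <- vector("list", nrow(ev))
  pursue_fill <- function(idx, t_ref, off) {
    base <- proj_point_over_time(itp, camera, sample_t[idx], pw[1], pw[2])
    b0 <- proj_point_over_time(itp, camera, t_ref, pw[1], pw[2])
    g <- strategy$pursuit_gain
    dec <- exp(-(sample_t[idx] - t_ref) / decay)
    x <- b0$px + g * (base$px - b0$px) + off[1] * dec
    y <- b0$py + g * (base$py - b0$py) + off[2] * dec
    # hold last position when the point is unprojectable / below the frame
    bad <- is.na(x) | y > camera$height + 5
    x[bad] <- NA; y[bad] <- NA
    list(x = fill_forward(x, px[max(1, idx[1] - 1)]),
         y = fill_forward(y, py[max(1, idx[1] - 1)]))
  }
  eval_at <- function(t, t_ref, off) {
    b <- proj_point_over_time(itp, camera, t, pw[1], pw[2])
    b0 <- proj_point_over_time(itp, camera, t_ref, pw[1], pw[2])
    g <- strategy$pursuit_gain
    dec <- exp(-(t - t_ref) / decay)
    c(b0$px + g * (b$px - b0$px) + off[1] * dec,
      b0$py + g * (b$py - b0$py) + off[2] * dec)
  }
  for (i in seq_len(nrow(ev))) {
    launch_t <- max(ev$launch_t[i], landing_prev + 1 / hz)
    landing_t <- launch_t + ev$tau[i]
    if (landing_t >= t_end) break
    idx <- which(sample_t >= landing_prev & sample_t < launch_t)
    if (length(idx)) {
      fp <- pursue_fill(idx, landing_prev, offset)
      px[idx] <- fp$x; py[idx] <- fp$y
    }
    launch_pos <- eval_at(launch_t, landing_prev, offset)
    if (any(is.na(launch_pos))) {
      li <- tail(which(!is.na(px) & seq_along(px) <= max(idx, 1)), 1)
      launch_pos <- c(px[li], py[li])
    }
    scatter <- deg_to_px(rnorm(2, 0, strategy$landing_sd), camera)
    if (strategy$mode %in% c("predictive", "reactive")) {
      pw_new <- c(ev$x[i], ev$y[i])
      b <- proj_point_over_time(itp, camera, landing_t, pw_new[1], pw_new[2])
      landing_pos <- c(b$px + scatter[1], b$py + scatter[2])
    } else if (strategy$mode == "fixed_screen_point") {
      landing_pos <- pf + scatter
      g <- screen_to_ground(list(x = itp$x(landing_t), y = itp$y(landing_t),
                                 heading = itp$heading(landing_t)),
                            landing_pos[1], landing_pos[2], camera)
      pw_new <- c(g$x[1], g$y[1])
    } else {
      dx <- turn_dir(ev$turn[i]) * abs(motor_dy) * 1.2
      landing_pos <- c(launch_pos[1] + dx + scatter[1],
                       launch_pos[2] + motor_dy + scatter[2])
      g <- screen_to_ground(list(x = itp$x(landing_t), y = itp$y(landing_t),
                                 heading = itp$heading(landing_t)),
                            landing_pos[1], landing_pos[2], camera)
      pw_new <- c(g$x[1], g$y[1])
    }
    if (any(is.na(pw_new))) pw_new <- pw  # ray missed the ground: keep target
    idx2 <- which(sample_t >= launch_t & sample_t < landing_t)
    if (length(idx2)) {
      frac <- (sample_t[idx2] - launch_t) / ev$tau[i]
      px[idx2] <- launch_pos[1] + frac * (landing_pos[1] - launch_pos[1])
      py[idx2] <- launch_pos[2] + frac * (landing_pos[2] - launch_pos[2])
    }
    events[[i]] <- tibble::tibble(
      turn = ev$turn[i], slot = ev$slot[i], status = ev$status[i],
      appear_t = ev$appear_t[i], launch_t = launch_t, landing_t = landing_t,
      launch_px = launch_pos[1], launch_py = launch_pos[2],
      landing_px = landing_pos[1], landing_py = landing_pos[2])
    b_land <- proj_point_over_time(itp, camera, landing_t,
                                   pw_new[1], pw_new[2])
    offset <- c(landing_pos[1] - b_land$px, landing_pos[2] - b_land$py)
    if (any(is.na(offset))) offset <- c(0, 0)
    pw <- pw_new
    landing_prev <- landing_t
  }
  idx <- which(sample_t >= landing_prev)
  if (length(idx)) {
    fp <- pursue_fill(idx, landing_prev, offset)
    px[idx] <- fp$x; py[idx] <- fp$y
  }
  out <- finalize_gaze(sample_t, px, py, camera, strategy$gaze_noise_sd)
  attr(out, "events") <- dplyr::bind_rows(events[!vapply(events, is.null,
                                                         logical(1))])
  out
}

#' Degrade a gaze log with tracker noise and dropout
#'
#' Assigns pupil-detection-style confidence ratings: a fraction of samples
#' (independently, or in bursts) fall below the 0.6 analysis threshold.
#'
#' @param gaze Gaze tibble.
#' @param dropout_rate Fraction of samples with confidence below 0.6.
#' @param burst If `TRUE`, dropouts occur in contiguous bursts.
#' @param burst_max Maximum burst duration, seconds.
#' @param seed Optional RNG seed.
#' @return The gaze tibble with updated `confidence`.
#' @export
degrade <- function(gaze, dropout_rate = 0.05, burst = FALSE, burst_max = 3,
                    seed = NULL) {
  if (dropout_rate < 0 || dropout_rate > 1) abort("`dropout_rate` in [0,1]")
  new_seeded_rng(seed)
  n <- nrow(gaze)
  if (dropout_rate == 0 || n == 0) return(gaze)
  low <- logical(n)
  if (!burst) {
    low <- runif(n) < dropout_rate
  } else {
    dt <- if (n > 1) median(diff(gaze$t)) else 1 / 30
    target <- dropout_rate * n
    got <- 0
    while (got < target) {
      len <- ceiling(runif(1, dt, burst_max) / dt)
      start <- sample.int(n, 1)
      idx <- start:min(n, start + len - 1)
      low[idx] <- TRUE
      got <- sum(low)
    }
  }
  gaze$confidence[low] <- runif(sum(low), 0, 0.59)
  gaze$confidence[!low] <- runif(sum(!low), 0.8, 1)
  gaze
}
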