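#' Simulate constant-speed telemetry along the track
#'
#' A kinematic path follower: the vehicle progresses along the centerline at
#' constant speed while its lateral position wanders as a mean-reverting
#' Ornstein-Uhlenbeck process (discretized exactly as an AR(1)), emulating
#' human steering variability. With `lateral_noise_sd = 0` the trajectory is
#' the exact centerline and the yaw rate equals `speed / radius`.
#'
#' @param track A [build_track()] object.
#' @param speed Constant speed, m/s.
#' @param duration Log duration, seconds (must fit on the track).
#' @param hz Sampling rate, Hz.
#' @param lateral_noise_sd Stationary SD of the lateral deviation, metres.
#' @param lateral_timescale OU mean-reversion timescale, seconds.
#' @param seed Optional RNG seed (same seed, identical log).
#' @return Telemetry tibble: `t`, `x`, `y`, `heading` (rad), `speed` (m/s),
#'   `s` (centerline arc length, m), `lateral` (m).
#' @export
simulate_driver <- function(track, speed, duration, hz = 60,
                            lateral_noise_sd = 0.35, lateral_timescale = 1.5,
                            seed = NULL) {
  stopifnot_scalar_pos(speed, "speed")
  stopifnot_scalar_pos(duration, "duration")
  new_seeded_rng(seed)
  t <- seq(0, duration, by = 1 / hz)
  s <- speed * t
  if (max(s) > track$total_length) {
    abort("`duration` exceeds the track length at this speed; build a longer track")
  }
  n <- length(t)
  if (lateral_noise_sd > 0) {
    # OU wander generated on a coarse grid and splined to the sample rate:
    # keeps the stationary SD while giving the smooth lateral velocity of
    # human steering (white-noise velocity would jitter the heading)
    dt_c <- 1 / 3
    tc <- seq(0, duration + dt_c, by = dt_c)
    a <- exp(-dt_c / lateral_timescale)
    innov_sd <- lateral_noise_sd * sqrt(1 - a^2)
    Lc <- numeric(length(tc))
    Lc[1] <- rnorm(1, 0, lateral_noise_sd)
    eps <- rnorm(length(tc) - 1, 0, innov_sd)
    for (i in 2:length(tc)) Lc[i] <- a * Lc[i - 1] + eps[i - 1]
    L <- stats::spline(tc, Lc, xout = t)$y
  } else {
    L <- numeric(n)
  }
  cl <- track_pose(track, s)
  # heading includes the slip implied by the lateral drift rate
  dL <- c(diff(L), 0) * hz
  dL[n] <- dL[n - 1]
  heading <- cl$heading + atan2(dL, speed)
  tibble::tibble(
    t = t,
    x = cl$x - sin(cl$heading) * L,
    y = cl$y + cos(cl$heading) * L,
    heading = heading,
    speed = speed,
    s = s,
    lateral = L
  )
}
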