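# core search: given a unit world direction from the eye at `at_t`, find the
# future trajectory point with minimal visual angle to it
th_core <- function(itp, camera, target_dir, at_t, max_angular_dist = 3,
                    lookahead = 6, resolution = 1 / 120) {
  t_hi <- min(at_t + lookahead, itp$t_max)
  times <- seq(at_t, t_hi, by = resolution)
  ex <- itp$x(at_t); ey <- itp$y(at_t)
  vx <- itp$x(times) - ex
  vy <- itp$y(times) - ey
  vz <- -camera$eye_height
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  cosang <- (vx * target_dir[1] + vy * target_dir[2] + vz * target_dir[3]) / nrm
  ang <- rad2deg(acos(pmin(1, pmax(-1, cosang))))
  i <- which.min(ang)
  min_ang <- ang[i]
  truncated <- i == length(times) && t_hi < at_t + lookahead - 1e-9
  th <- times[i] - at_t
  reason <- NA_character_
  if (truncated) {
    th <- NA_real_; reason <- "telemetry_truncated"
  } else if (min_ang > max_angular_dist) {
    th <- NA_real_; reason <- "angular_exclusion"
  }
  tibble::tibble(event_t = at_t, th = th, angular_distance = min_ang,
                 reason = reason)
}

dir_to_ground_point <- function(itp, camera, at_t, x, y) {
  d <- c(x - itp$x(at_t), y - itp$y(at_t), -camera$eye_height)
  d / sqrt(sum(d^2))
}

#' Time headway of a fixated point along the driver's future trajectory
#'
#' Finds the future point on the driver's trajectory closest, in visual
#' angle as seen from the eye at `at_t`, to the fixated point; the time
#' headway is how long it takes the driver to reach that point. If the
#' minimum angular distance exceeds `max_angular_dist` (default 3 degrees),
#' no time headway is returned (the gaze point is considered off the
#' trajectory).
#'
#' @param telemetry Telemetry tibble covering `[at_t, at_t + lookahead]`.
#' @param point Fixated point: ground `c(x, y)` metres, or screen
#'   `c(px, py)` pixels with `point_space = "screen"`.
#' @param at_t Fixation time, seconds.
#' @param max_angular_dist Exclusion threshold, degrees.
#' @param camera A [camera_spec()].
#' @param lookahead Future search window, seconds.
#' @param resolution Interpolation step of the trajectory scan, seconds.
#' @param point_space `"ground"` or `"screen"`.
#' @return One-row tibble: `event_t`, `th` (s, `NA` when excluded),
#'   `angular_distance` (deg, the attained minimum), `reason`
#'   (`NA`, `"angular_exclusion"`, `"telemetry_truncated"`,
#'   `"stationary"`).
#' @export
time_headway <- function(telemetry, point, at_t, max_angular_dist = 3,
                         camera = camera_spec(), lookahead = 6,
                         resolution = 1 / 120,
                         point_space = c("ground", "screen")) {
  point_space <- match.arg(point_space)
  if (!all(is.finite(point))) abort("`point` must be finite")
  itp <- telemetry_interpolator(telemetry)
  if (at_t < itp$t_min - 1e-9 || at_t > itp$t_max + 1e-9) {
    abort("`at_t` outside the telemetry time range")
  }
  if (itp$speed(at_t) < 0.1) {
    return(tibble::tibble(event_t = at_t, th = NA_real_,
                          angular_distance = NA_real_,
                          reason = "stationary"))
  }
  target_dir <- if (point_space == "ground") {
    dir_to_ground_point(itp, camera, at_t, point[1], point[2])
  } else {
    pose <- list(x = itp$x(at_t), y = itp$y(at_t),
                 heading = itp$heading(at_t))
    as.vector(screen_direction(pose, point[1], point[2], camera))
  }
  th_core(itp, camera, target_dir, at_t, max_angular_dist, lookahead,
          resolution)
}

#' Time-headway records for saccade landing and launch points
#'
#' For every detected saccade, the landing point opens a pursuit/fixation
#' episode and the launch point of the *following* saccade closes it; both
#' endpoints are assigned a time headway against the driver's future
#' trajectory, with the angular exclusion of [time_headway()].
#'
#' @param saccades Saccade tibble from [extract_saccades()].
#' @param telemetry Telemetry tibble (same clock as the gaze log).
#' @param camera A [camera_spec()].
#' @inheritParams time_headway
#' @return Tibble with one row per record: `fixation_id`, `kind`
#'   (`"saccade_landing"` / `"saccade_launch"`), `event_t`, `th`,
#'   `angular_distance`, `reason`.
#' @export
compute_th_records <- function(saccades, telemetry, camera = camera_spec(),
                               max_angular_dist = 3, lookahead = 6,
                               resolution = 1 / 120) {
  itp <- telemetry_interpolator(telemetry)
  n <- nrow(saccades)
  if (n == 0) {
    return(tibble::tibble(fixation_id = integer(), kind = character(),
                          event_t = numeric(), th = numeric(),
                          angular_distance = numeric(), reason = character()))
  }
  one <- function(t, px, py, kind, id) {
    if (t > itp$t_max) return(NULL)
    if (itp$speed(t) < 0.1) {
      return(tibble::tibble(fixation_id = id, kind = kind, event_t = t,
                            th = NA_real_, angular_distance = NA_real_,
                            reason = "stationary"))
    }
    pose <- list(x = itp$x(t), y = itp$y(t), heading = itp$heading(t))
    dir <- as.vector(screen_direction(pose, px, py, camera))
    r <- th_core(itp, camera, dir, t, max_angular_dist, lookahead, resolution)
    tibble::tibble(fixation_id = id, kind = kind, event_t = r$event_t,
                   th = r$th, angular_distance = r$angular_distance,
                   reason = r$reason)
  }
  out <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    out[[2 * i - 1]] <- one(saccades$landing_t[i], saccades$landing_px[i],
                            saccades$landing_py[i], "saccade_landing", i)
    if (i < n) {
      out[[2 * i]] <- one(saccades$launch_t[i + 1], saccades$launch_px[i + 1],
                          saccades$launch_py[i + 1], "saccade_launch", i)
    }
  }
  dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
}

#' Pursuit/fixation durations between saccades
#'
#' The time between each saccade's landing and the next saccade's launch
#' estimates how long the intervening pursuit or fixation lasted.
#'
#' @param saccades Time-ordered saccade tibble.
#' @return Tibble with `fixation_id`, `landing_t`, `launch_t`, `duration`.
#' @export
pursuit_intervals <- function(saccades) {
  n <- nrow(saccades)
  if (n < 2) {
    return(tibble::tibble(fixation_id = integer(), landing_t = numeric(),
                          launch_t = numeric(), duration = numeric()))
  }
  if (is.unsorted(saccades$launch_t)) abort("saccades must be time-ordered")
  landing <- saccades$landing_t[-n]
  launch <- saccades$launch_t[-1]
  if (any(launch < landing - 1e-9)) abort("overlapping saccades in input")
  tibble::tibble(fixation_id = seq_len(n - 1), landing_t = landing,
                 launch_t = launch, duration = launch - landing)
}
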