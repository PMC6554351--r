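#' Specify an alternating half-circle track
#'
#' The experimental track is a chain of constant-radius arcs whose curvature
#' sign alternates from one arc to the next (a "slalom" of half-circles).
#'
#' @param radius Arc radius in metres.
#' @param turn_arc Arc swept by each turn, in degrees.
#' @param n_turns Number of turns (arcs) in the track.
#' @param track_width Total path width in metres.
#' @param first_turn Direction of the first turn, `"left"` or `"right"`.
#' @return A `gw_track_spec` list.
#' @export
track_spec <- function(radius = 50, turn_arc = 180, n_turns = 10,
                       track_width = 3.5, first_turn = c("left", "right")) {
  first_turn <- match.arg(first_turn)
  stopifnot_scalar_pos(radius, "radius")
  if (!is.numeric(turn_arc) || turn_arc <= 0 || turn_arc > 360) {
    abort("`turn_arc` must be in (0, 360] degrees.")
  }
  if (!is.numeric(n_turns) || n_turns < 1 || n_turns != round(n_turns)) {
    abort("`n_turns` must be a positive integer.")
  }
  stopifnot_scalar_pos(track_width, "track_width")
  structure(
    list(radius = radius, turn_arc = turn_arc, n_turns = as.integer(n_turns),
         track_width = track_width, first_turn = first_turn),
    class = "gw_track_spec"
  )
}

#' Build track geometry from a specification
#'
#' Produces an arc-length-parameterized centerline. The ground plane is
#' right-handed with `x` forward at the track start and headings in radians
#' counter-clockwise; arc length 0 is the trial start. A left turn has
#' positive curvature `+1/radius`, a right turn `-1/radius`; the sign flips
#' exactly at multiples of the per-turn arc length and both position and
#' heading are continuous at the flips.
#'
#' @param spec A [track_spec()].
#' @return A `gw_track` object with fields `spec`, `turn_length`,
#'   `total_length` and per-turn start poses.
#' @export
build_track <- function(spec = track_spec()) {
  if (!inherits(spec, "gw_track_spec")) abort("`spec` must be a track_spec().")
  turn_length <- spec$radius * deg2rad(spec$turn_arc)
  n <- spec$n_turns
  dir0 <- if (spec$first_turn == "left") 1 else -1
  kappa <- dir0 * (-1)^(seq_len(n) - 1) / spec$radius
  x0 <- h0 <- y0 <- numeric(n)
  x0[1] <- 0; y0[1] <- 0; h0[1] <- 0
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      h1 <- h0[i] + kappa[i] * turn_length
      x0[i + 1] <- x0[i] + (sin(h1) - sin(h0[i])) / kappa[i]
      y0[i + 1] <- y0[i] - (cos(h1) - cos(h0[i])) / kappa[i]
      h0[i + 1] <- h1
    }
  }
  structure(
    list(spec = spec, turn_length = turn_length,
         total_length = n * turn_length,
         turns = tibble::tibble(turn = seq_len(n), s_start = (seq_len(n) - 1) * turn_length,
                                x0 = x0, y0 = y0, h0 = h0, kappa = kappa)),
    class = "gw_track"
  )
}

#' @export
print.gw_track <- function(x, ...) {
  cat(sprintf("<gw_track> %d x %g deg turns, R = %g m, total length %.2f m\n",
              x$spec$n_turns, x$spec$turn_arc, x$spec$radius, x$total_length))
  invisible(x)
}

#' Query centerline pose at given arc lengths
#'
#' @param track A [build_track()] object.
#' @param s Arc lengths in metres, each in `[0, total_length]`.
#' @return A tibble with columns `s`, `x`, `y`, `heading` (rad, continuous)
#'   and `curvature` (1/m, signed).
#' @export
track_pose <- function(track, s) {
  if (!inherits(track, "gw_track")) abort("`track` must be a gw_track.")
  if (any(!is.finite(s)) || any(s < -1e-9) || any(s > track$total_length + 1e-9)) {
    abort("`s` must lie within [0, total_length].")
  }
  s <- pmin(pmax(s, 0), track$total_length)
  i <- pmin(findInterval(s, track$turns$s_start), nrow(track$turns))
  u <- s - track$turns$s_start[i]
  k <- track$turns$kappa[i]
  h0 <- track$turns$h0[i]
  h <- h0 + k * u
  tibble::tibble(
    s = s,
    x = track$turns$x0[i] + (sin(h) - sin(h0)) / k,
    y = track$turns$y0[i] - (cos(h) - cos(h0)) / k,
    heading = h,
    curvature = k
  )
}

#' Yaw rate implied by speed on a circular arc
#'
#' @param speed Speed, by default in km/h (the units the experiment reports).
#' @param radius Arc radius in metres.
#' @param units `"kmh"` or `"ms"` for the speed argument.
#' @return Yaw rate in degrees per second.
#' @examples
#' yaw_rate(40, 50)  # ~12.7, printed as ~13
#' yaw_rate(47, 50)  # ~15
#' @export
yaw_rate <- function(speed, radius = 50, units = c("kmh", "ms")) {
  units <- match.arg(units)
  stopifnot_scalar_pos(radius, "radius")
  if (any(!is.finite(speed)) || any(speed < 0)) abort("`speed` must be >= 0.")
  v <- if (units == "kmh") kmh_to_ms(speed) else speed
  rad2deg(v / radius)
}

#' Signed lateral deviation of positions from the track centerline
#'
#' Projects each ground position onto the centerline by local search along
#' arc length (positions are assumed to progress along the track, as a
#' vehicle's do). Positive deviations are to the left of travel.
#'
#' @param track A [build_track()] object.
#' @param x,y Ground positions in metres.
#' @param search_halfwidth Arc-length half-window (m) for the local search.
#' @return A tibble with columns `s` (matched arc length) and `lateral` (m).
#' @export
track_lateral_deviation <- function(track, x, y, search_halfwidth = 30) {
  n <- length(x)
  ds <- 0.25
  s_out <- lat <- numeric(n)
  s_prev <- 0
  for (j in seq_len(n)) {
    lo <- max(0, s_prev - search_halfwidth)
    hi <- min(track$total_length, s_prev + search_halfwidth)
    cand <- seq(lo, hi, by = ds)
    cl <- track_pose(track, cand)
    d2 <- (cl$x - x[j])^2 + (cl$y - y[j])^2
    i <- which.min(d2)
    p <- cl[i, ]
    # signed offset along the left normal (-sin h, cos h)
    lat[j] <- -sin(p$heading) * (x[j] - p$x) + cos(p$heading) * (y[j] - p$y)
    s_out[j] <- p$s
    s_prev <- p$s
  }
  tibble::tibble(s = s_out, lateral = lat)
}

#' Off-track warning and restart events
#'
#' The simulator warns (beeps) while the vehicle is more than `warn_dist`
#' from the track centre and restarts the trial when it strays beyond
#' `restart_dist`.
#'
#' @param telemetry Telemetry tibble with `t`, `x`, `y`.
#' @param track A [build_track()] object.
#' @param warn_dist,restart_dist Lateral thresholds in metres.
#' @return Tibble of events with `kind` (`"warning"` or `"restart"`),
#'   `t_start`, `t_end` (equal for restarts) and `max_deviation`.
#' @export
off_track_events <- function(telemetry, track, warn_dist = 1.75,
                             restart_dist = 10) {
  dev <- track_lateral_deviation(track, telemetry$x, telemetry$y)
  a <- abs(dev$lateral)
  out <- list()
  over <- a > warn_dist
  if (any(over)) {
    r <- rle(over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      idx <- starts[i]:ends[i]
      out[[length(out) + 1]] <- tibble::tibble(
        kind = "warning", t_start = telemetry$t[starts[i]],
        t_end = telemetry$t[ends[i]], max_deviation = max(a[idx]))
    }
  }
  first_restart <- which(a > restart_dist)[1]
  if (!is.na(first_restart)) {
    out[[length(out) + 1]] <- tibble::tibble(
      kind = "restart", t_start = telemetry$t[first_restart],
      t_end = telemetry$t[first_restart], max_deviation = a[first_restart])
  }
  if (!length(out)) {
    return(tibble::tibble(kind = character(), t_start = numeric(),
                          t_end = numeric(), max_deviation = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$t_start)
}
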