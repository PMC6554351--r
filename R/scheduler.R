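#' Nominal design speed for a target yaw rate
#'
#' The waypoint experiment holds speed constant at the value that yields a
#' given yaw rate on the circular track (15 deg/s on the 50 m radius,
#' i.e. ~13.09 m/s, printed as "approximately 47 km/h"). Using this design
#' speed makes a 180-degree turn last exactly 12 s, so 16 slots at 0.75 s
#' intervals tile it exactly.
#'
#' @param yaw_rate_deg Target yaw rate, deg/s.
#' @param radius Track radius, metres.
#' @return Speed in m/s.
#' @export
design_speed <- function(yaw_rate_deg = 15, radius = 50) {
  radius * yaw_rate_deg * pi / 180
}

#' Generate waypoint slots along a track
#'
#' Waypoint slots are indexed 1-16 within each turn. Slot `k` lies
#' `(lead_th + (k - 1) * interval)` seconds of nominal travel past the
#' point where the curvature sign changes into that turn, so slot 1 appears
#' (at a `lead_th` time headway) exactly as the driver crosses the sign
#' change, and appearance events are spaced by `interval` seconds of travel.
#' Slots whose ground position would fall beyond the end of the built track
#' are dropped (the last slots of a turn physically lie in the next bend).
#'
#' @param track A [build_track()] object.
#' @param nominal_speed Nominal constant speed, m/s.
#' @param interval Travel-time spacing between slots, seconds.
#' @param lead_th Appearance time headway, seconds.
#' @param wp_radius Rendered waypoint radius, metres.
#' @return Tibble with `turn`, `slot`, `arclength`, `x`, `y`, `appear_arc`
#'   (driver arc position at appearance) and `radius`.
#' @export
generate_slots <- function(track, nominal_speed, interval = 0.75,
                           lead_th = 2, wp_radius = 0.7) {
  stopifnot_scalar_pos(nominal_speed, "nominal_speed")
  if (!is.numeric(interval) || interval <= 0) abort("`interval` must be > 0.")
  n_per_turn <- floor(track$turn_length / (nominal_speed * interval) + 1e-9)
  grid <- tidyr::expand_grid(turn = seq_len(track$spec$n_turns),
                             slot = seq_len(n_per_turn))
  arc <- (grid$turn - 1) * track$turn_length +
    (lead_th + (grid$slot - 1) * interval) * nominal_speed
  keep <- arc <= track$total_length
  grid <- grid[keep, ]; arc <- arc[keep]
  pose <- track_pose(track, arc)
  tibble::tibble(
    turn = grid$turn, slot = grid$slot, arclength = arc,
    x = pose$x, y = pose$y,
    appear_arc = arc - lead_th * nominal_speed,
    radius = wp_radius
  )
}

# all size-n_gaps subsets of 1:n_slots whose pairwise index separation is
# >= min_sep (i.e. at least min_sep - 1 visible slots between gaps)
feasible_gap_sets <- function(n_slots = 16, n_gaps = 4, min_sep = 3) {
  sets <- combn(n_slots, n_gaps)
  ok <- apply(sets, 2, function(s) all(diff(s) >= min_sep))
  if (!any(ok)) abort("gap constraints unsatisfiable for these counts")
  sets[, ok, drop = FALSE]
}

#' Sample missing-waypoint (gap) slots for each turn
#'
#' Each turn independently receives exactly `n_gaps` missing slots, with no
#' two gaps in succession and always at least two visible waypoints between
#' gaps (index separation >= 3). Configurations are drawn uniformly from
#' the feasible set.
#'
#' @param n_turns Number of turns to sample.
#' @param n_slots Slots per turn.
#' @param n_gaps Missing slots per turn.
#' @param min_sep Minimum index separation between gaps.
#' @param seed Optional RNG seed.
#' @return Tibble with `turn` and `slot` of each missing waypoint.
#' @export
sample_gaps <- function(n_turns, n_slots = 16, n_gaps = 4, min_sep = 3,
                        seed = NULL) {
  new_seeded_rng(seed)
  sets <- feasible_gap_sets(n_slots, n_gaps, min_sep)
  pick <- sample.int(ncol(sets), n_turns, replace = TRUE)
  tibble::tibble(
    turn = rep(seq_len(n_turns), each = n_gaps),
    slot = as.vector(sets[, pick])
  )
}

#' Build a full waypoint schedule
#'
#' Combines [generate_slots()] and [sample_gaps()] into the per-slot event
#' table used by the simulator and the analyses: ground position, status
#' (visible/missing), appearance and removal expressed both as driver arc
#' position and (for a constant-speed run starting at arc 0, t = 0) time.
#' Visible waypoints fade in linearly over `fade_in` seconds and leave the
#' display when the driver is within `remove_dist` of them (by default the
#' distance at which a ground point drops below the camera frustum).
#'
#' @inheritParams generate_slots
#' @param n_gaps Missing slots per turn (gap fraction 4/16 = 25%).
#' @param fade_in Opacity ramp duration, seconds.
#' @param remove_dist Removal distance ahead of the driver, metres;
#'   `NULL` uses [frustum_ground_cutoff()] of `camera`.
#' @param camera A [camera_spec()] (used only for the removal distance).
#' @param seed RNG seed for gap sampling.
#' @return Tibble: `turn`, `slot`, `status`, `x`, `y`, `arclength`,
#'   `appear_arc`, `appear_t`, `remove_arc`, `remove_t`, `radius`.
#' @export
schedule_waypoints <- function(track, nominal_speed, interval = 0.75,
                               lead_th = 2, n_gaps = 4, fade_in = 0.25,
                               remove_dist = NULL, camera = camera_spec(),
                               wp_radius = 0.7, seed = NULL) {
  slots <- generate_slots(track, nominal_speed, interval, lead_th, wp_radius)
  remove_dist <- remove_dist %||% frustum_ground_cutoff(camera)
  gaps <- sample_gaps(max(slots$turn), n_slots = max(slots$slot),
                      n_gaps = n_gaps, seed = seed)
  gaps$missing <- TRUE
  out <- dplyr::left_join(slots, gaps, by = c("turn", "slot"))
  out$status <- ifelse(is.na(out$missing), "visible", "missing")
  out$missing <- NULL
  out$appear_t <- out$appear_arc / nominal_speed
  out$remove_arc <- out$arclength - remove_dist
  out$remove_t <- out$remove_arc / nominal_speed
  attr(out, "nominal_speed") <- nominal_speed
  attr(out, "interval") <- interval
  attr(out, "lead_th") <- lead_th
  attr(out, "fade_in") <- fade_in
  attr(out, "first_dir") <- track$spec$first_turn
  out
}

#' Visibility state of a waypoint slot at a driver arc position
#'
#' @param schedule A row subset of [schedule_waypoints()] output.
#' @param driver_arc Driver arc position (m) along the track.
#' @param t Time (s) corresponding to `driver_arc` (for `appear_t` output).
#' @return Tibble with `visible`, `opacity` in `[0, 1]` and `th_now`
#'   (nominal time headway, s). Missing slots are never visible.
#' @export
visibility_at <- function(schedule, driver_arc, t = NULL) {
  v <- attr(schedule, "nominal_speed")
  fade <- attr(schedule, "fade_in") %||% 0.25
  th_now <- (schedule$arclength - driver_arc) / v
  appeared <- driver_arc >= schedule$appear_arc
  gone <- driver_arc > schedule$remove_arc
  visible <- appeared & !gone & schedule$status == "visible"
  since_appear <- (driver_arc - schedule$appear_arc) / v
  opacity <- pmin(1, pmax(0, since_appear / fade))
  opacity[!visible] <- 0
  tibble::tibble(turn = schedule$turn, slot = schedule$slot,
                 visible = visible, opacity = opacity, th_now = th_now)
}

#' Label a waypoint time headway with its range band
#'
#' FAR: 2.0 > TH > 1.25 s; MID: 1.25 > TH > 0.5 s; NEAR: TH < 0.5 s;
#' UPCOMING: TH >= 2.0 s. Boundary values go to the nearer (smaller-TH)
#' band.
#'
#' @param th Time headways, seconds (must be >= 0).
#' @return Factor with levels NEAR, MID, FAR, UPCOMING.
#' @export
range_label <- function(th) {
  if (any(th < 0, na.rm = TRUE)) abort("`th` must be >= 0.")
  lab <- dplyr::case_when(
    th <= 0.5 ~ "NEAR",
    th <= 1.25 ~ "MID",
    th <= 2.0 ~ "FAR",
    TRUE ~ "UPCOMING"
  )
  factor(lab, levels = c("NEAR", "MID", "FAR", "UPCOMING"))
}
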