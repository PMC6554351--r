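default_viewing_for <- function(camera) {
  viewing_geometry(hfov = camera$hfov, width_px = camera$width,
                   height_px = camera$height)
}

#' Assign gaze samples to waypoint areas of interest
#'
#' For each gaze sample within a waypoint event window, the nearest of the
#' predefined waypoint locations (the event's waypoint `WP` — its expected
#' location when missing — plus `WP-2`, `WP-1` and the upcoming `WP+1`),
#' in projected screen coordinates. Samples more than `threshold` degrees
#' from every location are `Other`; exact ties go to the nearer
#' (smaller time headway) waypoint.
#'
#' @param gaze Gaze tibble (confidence-filtered; all samples are used).
#' @param telemetry Telemetry tibble on the same clock.
#' @param schedule A [schedule_waypoints()] table.
#' @param camera A [camera_spec()].
#' @param viewing A [viewing_geometry()]; default derived from `camera`.
#' @param slots Slot indices analyzed (constant-curvature sections only;
#'   slots near the curvature changes are excluded).
#' @param window Event window length after (nominal) appearance, seconds.
#' @param threshold AOI angular threshold, degrees.
#' @return Tibble: `event_id`, `turn`, `slot`, `status`, `t`, `rel_t`,
#'   `label` (`WP-2`, `WP-1`, `WP`, `WP+1`, `Other`), `angular_distance`
#'   (deg, to the assigned AOI; `NA` for `Other` when no AOI projected).
#' @export
exp2_aoi_assignments <- function(gaze, telemetry, schedule,
                                 camera = camera_spec(), viewing = NULL,
                                 slots = 3:14, window = 1.5, threshold = 4) {
  viewing <- viewing %||% default_viewing_for(camera)
  itp <- telemetry_interpolator(telemetry)
  ev <- schedule[schedule$slot %in% slots, ]
  ev <- ev[ev$appear_t >= itp$t_min & ev$appear_t + window <= itp$t_max, ]
  ev <- dplyr::arrange(ev, .data$appear_t)
  labels <- c("WP-2", "WP-1", "WP", "WP+1")
  offsets <- c(-2, -1, 0, 1)
  out <- vector("list", nrow(ev))
  for (e in seq_len(nrow(ev))) {
    idx <- which(gaze$t >= ev$appear_t[e] & gaze$t < ev$appear_t[e] + window)
    if (!length(idx)) next
    ts <- gaze$t[idx]
    d <- matrix(Inf, length(idx), 4)
    for (a in seq_along(offsets)) {
      nb <- schedule[schedule$turn == ev$turn[e] &
                       schedule$slot == ev$slot[e] + offsets[a], ]
      if (!nrow(nb)) next
      pr <- proj_point_over_time(itp, camera, ts, nb$x[1], nb$y[1])
      ok <- !is.na(pr$px)
      d[ok, a] <- screen_angular_distance(gaze$px[idx][ok], gaze$py[idx][ok],
                                          pr$px[ok], pr$py[ok], viewing)
    }
    # column order WP-2, WP-1, WP, WP+1 is increasing TH; which.min takes
    # the first minimum, i.e. the smaller-TH waypoint on ties
    best <- apply(d, 1, which.min)
    bestd <- d[cbind(seq_along(best), best)]
    lab <- labels[best]
    lab[!is.finite(bestd) | bestd > threshold] <- "Other"
    out[[e]] <- tibble::tibble(
      event_id = e, turn = ev$turn[e], slot = ev$slot[e],
      status = ev$status[e], t = ts, rel_t = ts - ev$appear_t[e],
      label = lab,
      angular_distance = ifelse(is.finite(bestd), bestd, NA_real_))
  }
  res <- dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
  res$label <- factor(res$label, levels = c(labels, "Other"))
  res
}

#' Relative-frequency gaze-catch time courses
#'
#' Pools AOI assignments over events, separately for the visible and
#' missing conditions, into per-bin relative frequencies of each AOI label
#' (all samples in a bin form the denominator, so frequencies sum to one
#' wherever samples exist).
#'
#' @param assignments Output of [exp2_aoi_assignments()] (optionally with
#'   extra grouping columns already subset).
#' @param bin_width Bin width, seconds.
#' @param window Curve window, seconds.
#' @return A `gw_catch_curves` tibble: `condition`, `bin`, `t_mid`,
#'   `label`, `freq`, `n_bin`.
#' @export
catch_curves <- function(assignments, bin_width = 1 / 60, window = 1.5) {
  a <- assignments
  a$bin <- pmin(floor(a$rel_t / bin_width), ceiling(window / bin_width) - 1)
  counts <- a |>
    dplyr::count(.data$status, .data$bin, .data$label,
                 .drop = FALSE, name = "k") |>
    dplyr::group_by(.data$status, .data$bin) |>
    dplyr::mutate(n_bin = sum(.data$k),
                  freq = ifelse(.data$n_bin > 0, .data$k / .data$n_bin,
                                NA_real_)) |>
    dplyr::ungroup()
  out <- tibble::tibble(
    condition = counts$status, bin = counts$bin,
    t_mid = (counts$bin + 0.5) * bin_width,
    label = counts$label, freq = counts$freq, n_bin = counts$n_bin)
  class(out) <- c("gw_catch_curves", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "window") <- window
  out
}

#' Crossover point of gaze catch between WP and WP-1
#'
#' The earliest time from which the catch at the (possibly missing)
#' waypoint `WP` exceeds the catch at the preceding waypoint `WP-1` and
#' keeps doing so through the end of the window (a persistent, not
#' single-bin, crossing); bins in which neither waypoint catches any gaze
#' are uninformative and ignored. `NA` when dominance is never attained.
#'
#' @param curves A [catch_curves()] tibble.
#' @param condition `"visible"` or `"missing"`.
#' @param min_bins Minimal number of strictly dominant informative bins
#'   required after the crossing (guards against single-bin flukes).
#' @return Crossover time in seconds after (nominal) appearance, or `NA`.
#' @export
crossover_point <- function(curves, condition = c("missing", "visible"),
                            min_bins = 6) {
  condition <- match.arg(condition)
  cc <- curves[curves$condition == condition, ]
  if (!nrow(cc)) return(NA_real_)
  wide <- tidyr::pivot_wider(
    cc[cc$label %in% c("WP", "WP-1"), c("bin", "t_mid", "label", "freq")],
    names_from = "label", values_from = "freq")
  wide <- dplyr::arrange(wide, .data$bin)
  ok <- is.finite(wide$`WP`) & is.finite(wide$`WP-1`)
  wide <- wide[ok, ]
  if (!nrow(wide)) return(NA_real_)
  dom <- wide$`WP` > wide$`WP-1`
  # bins where neither AOI catches anything carry no information about
  # the ordering (e.g. after gaze has moved on to WP+1) and are ignored
  informative <- (wide$`WP` + wide$`WP-1`) > 0
  bad <- which(!dom & informative)
  cand <- which(dom & informative)
  if (length(bad)) cand <- cand[cand > max(bad)]
  if (length(cand) < min_bins) return(NA_real_)
  wide$t_mid[cand[1]]
}

#' Late-window AOI catch comparison (WP vs WP-1) with a binomial test
#'
#' In the last stretch before the next waypoint appears (by default
#' 0.5-0.75 s after the nominal appearance, i.e. waypoint time headway
#' 1.25-1.5 s), compares each participant's summed AOI catch at the
#' (missing) waypoint against the preceding waypoint and tests the number
#' of participants with the higher catch at `WP` against chance with an
#' exact two-sided binomial test.
#'
#' @param assignments AOI assignments with a `participant` column.
#' @param condition Condition analyzed (default `"missing"`).
#' @param window Relative-time window, seconds after nominal appearance.
#' @return List with `per_participant` tibble (`catch_wp`, `catch_prev`,
#'   `higher`), `n_higher`, `n`, `excluded` (participants without events)
#'   and `test` (a `gw_htest`).
#' @export
late_window_comparison <- function(assignments, condition = "missing",
                                   window = c(0.5, 0.75)) {
  if (!"participant" %in% names(assignments)) {
    abort("`assignments` needs a participant column")
  }
  a <- assignments[assignments$status == condition &
                     assignments$rel_t >= window[1] &
                     assignments$rel_t < window[2], ]
  all_p <- unique(assignments$participant)
  per <- a |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(catch_wp = mean(.data$label == "WP"),
                     catch_prev = mean(.data$label == "WP-1"),
                     n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(higher = .data$catch_wp > .data$catch_prev)
  excluded <- setdiff(all_p, per$participant)
  k <- sum(per$higher); n <- nrow(per)
  list(per_participant = per, n_higher = k, n = n, excluded = excluded,
       test = binomial_test(k, n, 0.5, "two.sided"))
}

#' Select saccades launched in the late pre-appearance window
#'
#' Keeps saccades launched while the event waypoint's (nominal) time
#' headway lay in `th_window` (default 1.25-1.5 s, the final 0.25 s of the
#' FAR range; earlier saccades are excluded to avoid counting corrective
#' saccades toward the preceding waypoint). Every analyzed event also
#' receives a saccade-presence indicator for frequency comparisons.
#'
#' @param saccades Saccade tibble from [extract_saccades()].
#' @param schedule A [schedule_waypoints()] table.
#' @param slots Analyzed slot indices.
#' @param th_window Waypoint time-headway window, seconds.
#' @return List of two tibbles: `saccades` (selected saccades with their
#'   event's `turn`, `slot`, `status`, `appear_t`) and `events` (per event:
#'   `turn`, `slot`, `status`, `n_saccades`, `any_saccade`).
#' @export
select_late_saccades <- function(saccades, schedule, slots = 3:14,
                                 th_window = c(1.25, 1.5)) {
  lead_th <- attr(schedule, "lead_th") %||% 2
  ev <- schedule[schedule$slot %in% slots, ]
  ev <- dplyr::arrange(ev, .data$appear_t)
  w0 <- lead_th - th_window[2]; w1 <- lead_th - th_window[1]
  picked <- vector("list", nrow(ev))
  n_sac <- integer(nrow(ev))
  for (e in seq_len(nrow(ev))) {
    lo <- ev$appear_t[e] + w0; hi <- ev$appear_t[e] + w1
    hit <- which(saccades$launch_t >= lo & saccades$launch_t < hi)
    n_sac[e] <- length(hit)
    if (length(hit)) {
      picked[[e]] <- dplyr::mutate(saccades[hit, ], turn = ev$turn[e],
                                   slot = ev$slot[e], status = ev$status[e],
                                   appear_t = ev$appear_t[e])
    }
  }
  events <- tibble::tibble(turn = ev$turn, slot = ev$slot,
                           status = ev$status, appear_t = ev$appear_t,
                           n_saccades = n_sac, any_saccade = n_sac > 0)
  list(saccades = dplyr::bind_rows(picked[!vapply(picked, is.null,
                                                  logical(1))]),
       events = events)
}

# similarity transform mapping p0 -> (0,0) and p1 -> (0,1); y up in the
# normalized frame
similarity_to_unit <- function(p0, p1) {
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 < 1e-12) abort("coincident waypoints: transform undefined")
  # rotation+scale taking d to (0,1): complex multiplication by (0,1)/dz
  fwd <- function(p) {
    q <- unname(p - p0)
    c(x = (d[1] * q[2] - d[2] * q[1]) / len2,
      y = (d[1] * q[1] + d[2] * q[2]) / len2)
  }
  inv <- function(q) {
    q <- unname(q)
    c(x = p0[1] + d[1] * q[2] - d[2] * q[1],
      y = p0[2] + d[2] * q[2] + d[1] * q[1])
  }
  list(fwd = fwd, inv = inv)
}

#' Normalize a saccade into waypoint-aligned coordinates
#'
#' Applies the similarity transform (translation, rotation, isotropic
#' scale) that maps the preceding (MID-range) waypoint to (0, 0) and the
#' (FAR-range, possibly missing) waypoint to (0, 1); left-turn events are
#' first mirrored about the screen's vertical centreline so all turns read
#' as right turns.
#'
#' @param launch,landing Screen points `c(px, py)`.
#' @param wp_prev,wp Screen points of WP-1 and WP.
#' @param turn_direction `"right"` or `"left"`.
#' @param screen_cx Horizontal screen centre (px), for mirroring.
#' @return Tibble with normalized `launch_x`, `launch_y`, `landing_x`,
#'   `landing_y` and the (possibly mirrored) screen coordinates used.
#' @export
normalize_saccade <- function(launch, landing, wp_prev, wp,
                              turn_direction = c("right", "left"),
                              screen_cx = 960) {
  turn_direction <- match.arg(turn_direction)
  mir <- function(p) if (turn_direction == "left")
    c(2 * screen_cx - p[1], p[2]) else p
  launch <- mir(launch); landing <- mir(landing)
  wp_prev <- mir(wp_prev); wp <- mir(wp)
  tr <- similarity_to_unit(wp_prev, wp)
  ln <- tr$fwd(launch); ld <- tr$fwd(landing)
  tibble::tibble(
    launch_x = ln[["x"]], launch_y = ln[["y"]],
    landing_x = ld[["x"]], landing_y = ld[["y"]],
    launch_px = launch[1], launch_py = launch[2],
    landing_px = landing[1], landing_py = landing[2],
    wp_prev_px = wp_prev[1], wp_prev_py = wp_prev[2],
    wp_px = wp[1], wp_py = wp[2])
}

#' Build normalized saccade-vector records for late-window saccades
#'
#' For each selected saccade, projects the event waypoint `WP` (its
#' expected location when missing) and the preceding `WP-1` at the saccade
#' landing time, mirrors left-turn events, normalizes launch/landing along
#' the WP-1 -> WP vector, and derives the horizontal amplitudes in visual
#' degrees: `required_amp_x` (launch to waypoint) and `actual_amp_x`
#' (launch to landing).
#'
#' @param late Output of [select_late_saccades()].
#' @param telemetry Telemetry tibble.
#' @param schedule A [schedule_waypoints()] table.
#' @param camera A [camera_spec()].
#' @param viewing A [viewing_geometry()]; default derived from `camera`.
#' @return A `gw_saccade_vectors` tibble, one row per saccade: normalized
#'   and screen coordinates, `wp_x_deg`, `launch_x_deg`, `landing_x_deg`,
#'   `required_amp_x`, `actual_amp_x`, distances (deg) of launch/landing
#'   to `WP` and `WP-1`, `turn_direction`, `status`.
#' @export
exp2_saccade_vectors <- function(late, telemetry, schedule,
                                 camera = camera_spec(), viewing = NULL) {
  viewing <- viewing %||% default_viewing_for(camera)
  itp <- telemetry_interpolator(telemetry)
  first_dir <- attr(schedule, "first_dir") %||% "left"
  sac <- late$saccades
  out <- vector("list", nrow(sac))
  for (i in seq_len(nrow(sac))) {
    wp_row <- schedule[schedule$turn == sac$turn[i] &
                         schedule$slot == sac$slot[i], ]
    prev_row <- schedule[schedule$turn == sac$turn[i] &
                           schedule$slot == sac$slot[i] - 1, ]
    if (!nrow(wp_row) || !nrow(prev_row)) next
    tt <- sac$landing_t[i]
    pw <- proj_point_over_time(itp, camera, tt, wp_row$x, wp_row$y)
    pp <- proj_point_over_time(itp, camera, tt, prev_row$x, prev_row$y)
    if (is.na(pw$px) || is.na(pp$px)) next
    dir0 <- if (first_dir == "left") 1 else -1
    is_left <- (dir0 * (-1)^(sac$turn[i] - 1)) > 0
    tdir <- if (is_left) "left" else "right"
    nr <- normalize_saccade(
      c(sac$launch_px[i], sac$launch_py[i]),
      c(sac$landing_px[i], sac$landing_py[i]),
      c(pp$px, pp$py), c(pw$px, pw$py),
      turn_direction = tdir, screen_cx = camera$cx)
    degs <- pixels_to_degrees(
      c(nr$launch_px, nr$landing_px, nr$wp_px),
      c(nr$launch_py, nr$landing_py, nr$wp_py), viewing)
    out[[i]] <- dplyr::mutate(
      nr,
      turn = sac$turn[i], slot = sac$slot[i], status = sac$status[i],
      turn_direction = tdir, launch_t = sac$launch_t[i],
      landing_t = sac$landing_t[i],
      launch_x_deg = degs$deg_x[1], landing_x_deg = degs$deg_x[2],
      wp_x_deg = degs$deg_x[3],
      required_amp_x = degs$deg_x[3] - degs$deg_x[1],
      actual_amp_x = degs$deg_x[2] - degs$deg_x[1],
      launch_dist_wp = screen_angular_distance(nr$launch_px, nr$launch_py,
                                               nr$wp_px, nr$wp_py, viewing),
      landing_dist_wp = screen_angular_distance(nr$landing_px, nr$landing_py,
                                                nr$wp_px, nr$wp_py, viewing),
      landing_dist_prev = screen_angular_distance(
        nr$landing_px, nr$landing_py, nr$wp_prev_px, nr$wp_prev_py, viewing))
  }
  res <- dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
  class(res) <- c("gw_saccade_vectors", class(res))
  res
}

#' Per-participant amplitude correlations pooled via Fisher's z
#'
#' For each participant, the Spearman correlation between the actual and
#' required horizontal saccade amplitudes (does the saccade size adapt to
#' what would hit the waypoint?) and between the landing and waypoint
#' horizontal screen positions (does the landing track where the waypoint
#' is?); pooled across participants on the Fisher z scale; plus a
#' Huber-loss line fit per participant for each relation.
#'
#' @param records A `gw_saccade_vectors` tibble with a `participant`
#'   column.
#' @param min_n Minimal saccades per participant for a correlation.
#' @return A `gw_cor_pool` object; see [tidy()]/[glance()].
#' @export
amplitude_correlations <- function(records, min_n = 3) {
  if (!"participant" %in% names(records)) {
    abort("`records` needs a participant column")
  }
  per <- records |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_n) {
        return(tibble::tibble(n = nrow(d), rho_amplitude = NA_real_,
                              rho_landing = NA_real_,
                              amp_slope = NA_real_, amp_intercept = NA_real_,
                              land_slope = NA_real_,
                              land_intercept = NA_real_))
      }
      fa <- tryCatch(huber_fit(d$required_amp_x, d$actual_amp_x),
                     error = function(e) list(slope = NA, intercept = NA))
      fl <- tryCatch(huber_fit(d$wp_x_deg, d$landing_x_deg),
                     error = function(e) list(slope = NA, intercept = NA))
      tibble::tibble(
        n = nrow(d),
        rho_amplitude = spearman_rho(d$required_amp_x, d$actual_amp_x),
        rho_landing = spearman_rho(d$wp_x_deg, d$landing_x_deg),
        amp_slope = fa$slope, amp_intercept = fa$intercept,
        land_slope = fl$slope, land_intercept = fl$intercept)
    }) |>
    dplyr::ungroup()
  pooled_amp <- fisher_z_mean(per$rho_amplitude)
  pooled_land <- fisher_z_mean(per$rho_landing)
  structure(list(per_participant = per,
                 pooled_rho_amplitude = as.numeric(pooled_amp),
                 pooled_rho_landing = as.numeric(pooled_land),
                 n_excluded = attr(pooled_amp, "n_excluded")),
            class = "gw_cor_pool")
}

#' @export
print.gw_cor_pool <- function(x, ...) {
  cat(sprintf(paste0("<gw_cor_pool> pooled rho (amplitude) = %.3f, ",
                     "pooled rho (landing) = %.3f, %d participants\n"),
              x$pooled_rho_amplitude, x$pooled_rho_landing,
              nrow(x$per_participant)))
  invisible(x)
}

#' Paired tests on saccade shifts toward the waypoint
#'
#' Per participant means of (a) launch-to-WP minus landing-to-WP angular
#' distance (positive = the saccade moved gaze toward the waypoint) and
#' (b) landing-to-WP-1 minus landing-to-WP distance (positive = landings
#' closer to WP than to the preceding waypoint); paired t-tests with
#' Cohen's d across participants, and the mean shift toward the waypoint
#' in degrees.
#'
#' @param records A `gw_saccade_vectors` tibble with `participant`.
#' @return List with `per_participant`, `toward_wp` (gw_htest),
#'   `closer_than_prev` (gw_htest) and `mean_shift_deg` (the mean shift
#'   toward the waypoint, degrees).
#' @export
saccade_shift_tests <- function(records) {
  if (!"participant" %in% names(records)) {
    abort("`records` needs a participant column")
  }
  per <- records |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      shift = mean(.data$launch_dist_wp - .data$landing_dist_wp),
      closer = mean(.data$landing_dist_prev - .data$landing_dist_wp),
      n = dplyr::n(), .groups = "drop")
  if (nrow(per) < 2) abort("need >= 2 participants")
  list(per_participant = per,
       toward_wp = paired_t(per$shift),
       closer_than_prev = paired_t(per$closer),
       mean_shift_deg = mean(per$shift))
}

#' Saccade-frequency difference between missing and visible events
#'
#' Per participant, the fraction of analyzed events with at least one
#' late-window saccade, compared between missing- and visible-waypoint
#' events with a paired t-test.
#'
#' @param events Per-event tables from [select_late_saccades()] with a
#'   `participant` column (bind rows across participants).
#' @return List with `per_participant` (`freq_missing`, `freq_visible`)
#'   and `test` (a `gw_htest` on the paired differences).
#' @export
saccade_frequency_test <- function(events) {
  per <- events |>
    dplyr::group_by(.data$participant, .data$status) |>
    dplyr::summarise(freq = mean(.data$any_saccade), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "status", values_from = "freq",
                       names_prefix = "freq_")
  list(per_participant = per,
       test = paired_t(per$freq_missing - per$freq_visible))
}
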