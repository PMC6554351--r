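test_that("AOI assignment matches a brute-force nearest-with-threshold oracle", {
  agent <- run_exp2_agent(71, "predictive", n_turns = 3)
  aoi <- agent$aoi
  expect_gt(nrow(aoi), 500)
  # frequencies per bin sum to one wherever samples exist
  cc <- agent$curves
  sums <- cc |>
    dplyr::group_by(condition, bin) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))

  # oracle: recompute a large subsample of labels directly
  itp <- gazeway:::telemetry_interpolator(agent$telemetry)
  cam <- default_cam; vwg <- default_vw
  gz <- agent$gaze
  set.seed(1)
  check <- aoi[sample(nrow(aoi), min(1500, nrow(aoi))), ]
  labels <- c("WP-2", "WP-1", "WP", "WP+1")
  for (i in seq_len(nrow(check))) {
    row <- check[i, ]
    g <- gz[which.min(abs(gz$t - row$t)), ]
    dists <- rep(Inf, 4)
    for (a in 1:4) {
      nb <- agent$schedule[agent$schedule$turn == row$turn &
                             agent$schedule$slot == row$slot + (a - 3), ]
      if (!nrow(nb)) next
      pr <- gazeway:::proj_point_over_time(itp, cam, row$t, nb$x, nb$y)
      if (is.na(pr$px)) next
      dists[a] <- screen_angular_distance(g$px, g$py, pr$px, pr$py, vwg)
    }
    expected <- if (min(dists) > 4) "Other" else labels[which.min(dists)]
    expect_equal(as.character(row$label), expected)
  }
})

test_that("an agent staring at WP-1 yields a WP-1 catch of one and no crossover", {
  # synthetic assignments: every sample labelled WP-1
  a <- tidyr::expand_grid(event_id = 1:10, rel_t = seq(0.01, 1.49, by = 1 / 30))
  a$status <- "missing"; a$label <- factor("WP-1",
                                           levels = c("WP-2", "WP-1", "WP",
                                                      "WP+1", "Other"))
  cc <- catch_curves(a)
  wp1 <- cc[cc$label == "WP-1" & cc$n_bin > 0, ]
  expect_true(all(wp1$freq == 1))
  expect_true(is.na(crossover_point(cc, "missing")))
})

test_that("crossover finds the first sustained dominance bin on constructed curves", {
  mk <- function(freq_wp, freq_prev) {
    nb <- length(freq_wp)
    out <- tibble::tibble(
      condition = "missing", bin = rep(0:(nb - 1), 2),
      t_mid = (rep(0:(nb - 1), 2) + 0.5) / 60,
      label = factor(rep(c("WP", "WP-1"), each = nb),
                     levels = c("WP-2", "WP-1", "WP", "WP+1", "Other")),
      freq = c(freq_wp, freq_prev), n_bin = 50)
    class(out) <- c("gw_catch_curves", class(out))
    out
  }
  step <- mk(c(rep(0.1, 30), rep(0.8, 60)), c(rep(0.8, 30), rep(0.1, 60)))
  expect_equal(crossover_point(step, "missing"), (30 + 0.5) / 60)
  none <- mk(rep(0, 90), rep(0.5, 90))
  expect_true(is.na(crossover_point(none, "missing")))
  # a single-bin flicker of dominance does not count
  flick <- mk(c(rep(0.1, 88), 0.9, 0.1), c(rep(0.8, 88), 0.1, 0.8))
  expect_true(is.na(crossover_point(flick, "missing")))
})

test_that("late-window comparison counts participants and applies the exact binomial test", {
  mk_assign <- function(p, wp_frac) {
    n <- 200
    tibble::tibble(participant = p, status = "missing",
                   rel_t = runif(n, 0.5, 0.75),
                   label = factor(ifelse(runif(n) < wp_frac, "WP", "WP-1"),
                                  levels = c("WP-2", "WP-1", "WP", "WP+1",
                                             "Other")))
  }
  set.seed(5)
  a <- dplyr::bind_rows(
    purrr::map(1:11, ~mk_assign(paste0("p", .x), 0.8)),
    mk_assign("p12", 0.2))
  res <- late_window_comparison(a)
  expect_equal(res$n_higher, 11)
  expect_equal(res$n, 12)
  expect_equal(res$test$p_value, 26 / 4096, tolerance = 1e-9)
})

test_that("late saccade selection keeps the TH 1.25-1.5 s window and flags empty events", {
  tr <- build_track(track_spec(n_turns = 3))
  v <- kmh_to_ms(47)
  sched <- schedule_waypoints(tr, v, seed = 2)
  ev <- sched[sched$slot %in% 3:14, ]
  ev <- dplyr::arrange(ev, appear_t)
  mk_sac <- function(tt) tibble::tibble(launch_t = tt, launch_px = 900,
                                        launch_py = 600, landing_t = tt + 0.05,
                                        landing_px = 950, landing_py = 580)
  # one saccade at waypoint TH 1.3 (0.7 s after appearance): included;
  # one at TH 1.6 (0.4 s after): excluded as a potential corrective saccade
  sac <- dplyr::bind_rows(mk_sac(ev$appear_t[4] + 0.7),
                          mk_sac(ev$appear_t[5] + 0.4))
  late <- select_late_saccades(sac, sched)
  expect_equal(nrow(late$saccades), 1)
  expect_equal(late$saccades$slot, ev$slot[4])
  expect_equal(sum(late$events$any_saccade), 1)
  expect_equal(nrow(late$events), nrow(ev))
})

test_that("saccade normalization maps the waypoint pair to (0,0)-(0,1) and round-trips", {
  wp_prev <- c(900, 700); wp <- c(1000, 620)
  n1 <- normalize_saccade(wp_prev, wp, wp_prev, wp, "right")
  expect_equal(c(n1$launch_x, n1$launch_y), c(0, 0), tolerance = 1e-12)
  expect_equal(c(n1$landing_x, n1$landing_y), c(0, 1), tolerance = 1e-12)
  mid <- (wp_prev + wp) / 2
  n2 <- normalize_saccade(mid, mid, wp_prev, wp, "right")
  expect_equal(c(n2$launch_x, n2$launch_y), c(0, 0.5), tolerance = 1e-12)

  # round trip through the inverse similarity transform
  tr <- gazeway:::similarity_to_unit(wp_prev, wp)
  p <- c(812, 655)
  expect_equal(tr$inv(tr$fwd(p)), c(x = p[1], y = p[2]), tolerance = 1e-9)

  # mirroring twice is the identity
  m1 <- normalize_saccade(p, p, wp_prev, wp, "left", screen_cx = 960)
  p_m <- c(2 * 960 - p[1], p[2])
  wp_prev_m <- c(2 * 960 - wp_prev[1], wp_prev[2])
  wp_m <- c(2 * 960 - wp[1], wp[2])
  m2 <- normalize_saccade(p_m, p_m, wp_prev_m, wp_m, "left", screen_cx = 960)
  n0 <- normalize_saccade(p, p, wp_prev, wp, "right")
  expect_equal(c(m2$launch_x, m2$launch_y), c(n0$launch_x, n0$launch_y),
               tolerance = 1e-12)
  expect_error(normalize_saccade(p, p, wp, wp, "right"), "coincident")
})

test_that("amplitude correlations pool with Fisher's z and flag degenerate input", {
  mk <- function(p, rho_target, n = 40) {
    set.seed(match(p, paste0("p", 1:9)))
    x <- rnorm(n)
    y <- rho_target * x + sqrt(1 - rho_target^2) * rnorm(n)
    tibble::tibble(participant = p, required_amp_x = x, actual_amp_x = y,
                   wp_x_deg = x, landing_x_deg = y)
  }
  rec <- dplyr::bind_rows(mk("p1", 0.9), mk("p2", 0.9), mk("p3", 0.9))
  pool <- amplitude_correlations(rec)
  g <- glance(pool)
  expect_equal(g$n_participants, 3)
  expect_gt(g$pooled_rho_amplitude, 0.7)
  # pooled value equals tanh(mean(atanh(rho_i)))
  expect_equal(pool$pooled_rho_amplitude,
               tanh(mean(atanh(pool$per_participant$rho_amplitude))))
  # constant input excluded with report
  degen <- tibble::tibble(participant = "pz", required_amp_x = 1,
                          actual_amp_x = rnorm(10), wp_x_deg = 1,
                          landing_x_deg = rnorm(10))
  pool2 <- amplitude_correlations(dplyr::bind_rows(rec, degen))
  expect_equal(pool2$n_excluded, 1)
  expect_equal(pool2$pooled_rho_amplitude, pool$pooled_rho_amplitude,
               tolerance = 1e-12)
})

test_that("saccade shift tests recover planted shifts and degenerate zeros", {
  mk <- function(p, shift, n = 30) {
    set.seed(match(p, paste0("p", 1:12)) + 50)
    launch_d <- runif(n, 3, 7)
    tibble::tibble(participant = p,
                   launch_dist_wp = launch_d,
                   landing_dist_wp = launch_d - shift + rnorm(n, 0, 0.4),
                   landing_dist_prev = launch_d - shift + 1 + rnorm(n, 0, 0.4))
  }
  rec <- dplyr::bind_rows(purrr::map(paste0("p", 1:8), mk, shift = 1.8))
  res <- saccade_shift_tests(rec)
  expect_equal(res$mean_shift_deg, 1.8, tolerance = 0.2)
  expect_lt(res$toward_wp$p_value, 0.001)
  expect_gt(res$toward_wp$effect_size, 1)

  zero <- tibble::tibble(participant = rep(c("a", "b", "c"), each = 5),
                         launch_dist_wp = 4, landing_dist_wp = 4,
                         landing_dist_prev = 4)
  rz <- saccade_shift_tests(zero)
  expect_equal(rz$toward_wp$statistic, 0)
  expect_equal(rz$toward_wp$effect_size, 0)

  # three-participant hand check of t and d
  hand <- tibble::tibble(participant = c("a", "b", "c"),
                         launch_dist_wp = c(5, 6, 7),
                         landing_dist_wp = c(3, 4.5, 5),
                         landing_dist_prev = c(4, 5, 6))
  rh <- saccade_shift_tests(hand)
  diffs <- c(5 - 3, 6 - 4.5, 7 - 5)
  expect_equal(rh$toward_wp$statistic,
               mean(diffs) / (sd(diffs) / sqrt(3)), tolerance = 1e-9)
  expect_equal(rh$toward_wp$effect_size, mean(diffs) / sd(diffs))
})

test_that("saccade frequency comparison pairs missing and visible rates per participant", {
  ev <- tidyr::expand_grid(participant = paste0("p", 1:6), i = 1:40)
  set.seed(77)
  ev_m <- dplyr::mutate(ev, status = "missing",
                        any_saccade = runif(dplyr::n()) < 0.3)
  ev_v <- dplyr::mutate(ev, status = "visible",
                        any_saccade = runif(dplyr::n()) < 0.45)
  res <- saccade_frequency_test(dplyr::bind_rows(ev_m, ev_v))
  expect_equal(nrow(res$per_participant), 6)
  expect_lt(res$test$estimate, 0)
})
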