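vw <- viewing_geometry()

deg_to_px_x <- function(deg) vw$cx + tan(deg * pi / 180) * vw$distance / vw$m_per_px
deg_to_px_y <- function(deg) vw$cy + tan(deg * pi / 180) * vw$distance / vw$m_per_px

test_that("confidence filtering drops exactly the sub-threshold samples", {
  gz <- tibble::tibble(t = (0:9) / 30, px = 960, py = 540,
                       confidence = c(rep(1, 5), 0.5, rep(0.95, 4)))
  out <- filter_confidence(gz)
  expect_equal(nrow(out), 9)
  expect_false(any(out$confidence < 0.6))
  expect_equal(attr(out, "n_filtered"), 1L)
  all_ones <- tibble::tibble(t = (0:9) / 30, px = 1, py = 1, confidence = 1)
  expect_equal(nrow(filter_confidence(all_ones)), 10)
  low <- dplyr::mutate(all_ones, confidence = 0.2)
  expect_warning(res <- filter_confidence(low), "below")
  expect_equal(nrow(res), 0)
})

test_that("a noiseless line is one segment; an elbow splits at the true breakpoint", {
  t <- (0:59) / 30
  line <- tibble::tibble(t = t, px = deg_to_px_x(-5 + 3 * t),
                         py = deg_to_px_y(1 + 0.5 * t), confidence = 1)
  seg <- segment_gaze(line, vw)
  expect_equal(nrow(seg), 1)

  elbow_x <- ifelse(t < 1, -6 + 4 * t, -2 - 5 * (t - 1))
  elbow <- tibble::tibble(t = t, px = deg_to_px_x(elbow_x),
                          py = deg_to_px_y(0), confidence = 1)
  seg2 <- segment_gaze(elbow, vw)
  # the kink sits exactly on a sample while knots live at inter-sample
  # midpoints, so the fit may spend one short bridging segment on it
  expect_lte(nrow(seg2), 3)
  expect_gte(nrow(seg2), 2)
  expect_lt(min(abs(seg2$t_end - 1)), 1.5 / 30)

  # an enormous penalty always yields a single segment
  noisy <- dplyr::mutate(elbow, px = px + rnorm(60, 0, 3))
  seg3 <- segment_gaze(noisy, vw, penalty = 1e9)
  expect_equal(nrow(seg3), 1)

  expect_error(segment_gaze(line[1:3, ], vw), "at least 4")
  expect_error(segment_gaze(dplyr::arrange(line, dplyr::desc(t)), vw),
               "sorted")
})

test_that("segment count on a saccade staircase tracks the true event count", {
  st <- make_staircase(5, n_sac = 40, noise = 0.3)
  seg <- segment_gaze(st$gaze, vw)
  # roughly two segments per saccade cycle (fixation + transit)
  expect_gt(nrow(seg), 2 * 40 * 0.8)
  expect_lt(nrow(seg), 2 * 40 * 1.6)
})

test_that("segments form a continuous piecewise-linear path within chunks", {
  st <- make_staircase(6, n_sac = 20, noise = 0.3)
  seg <- segment_gaze(st$gaze, vw)
  same_chunk <- diff(seg$chunk) == 0
  expect_true(all(abs(seg$x_start[-1] - seg$x_end[-nrow(seg)])[same_chunk] < 1e-9))
  expect_true(all(abs(seg$t_start[-1] - seg$t_end[-nrow(seg)])[same_chunk] < 1e-9))
})

test_that("classification applies the speed/duration rule with small-saccade rescue", {
  seg <- tibble::tibble(duration = c(0.04, 0.25, 0.10, 0.067, 0.04),
                        amplitude = c(8, 2, 0.0, 2.0, 1.0),
                        mean_speed = c(200, 8, 0, 30, 25))
  out <- classify_segments(seg)
  expect_equal(out$klass, c("saccade",      # 200 deg/s, 40 ms
                            "non_saccade",  # pursuit at 8 deg/s
                            "non_saccade",  # zero-velocity fixation
                            "saccade",      # 2 deg over two 30 Hz intervals
                            "non_saccade")) # small and slow
})

test_that("adjacent saccade segments merge into one event", {
  seg <- tibble::tibble(
    segment = 1:5, chunk = 1,
    t_start = c(0, 0.3, 0.335, 0.38, 0.41),
    t_end = c(0.3, 0.335, 0.38, 0.41, 0.8),
    px_start = c(800, 800, 840, 900, 910),
    py_start = 540, px_end = c(800, 840, 900, 910, 910), py_end = 540,
    x_start = 0, y_start = 0, x_end = 0, y_end = 0, n = c(9, 1, 1, 1, 12),
    duration = c(0.3, 0.035, 0.045, 0.03, 0.39),
    amplitude = c(0.2, 2, 3, 0.5, 0.3),
    mean_speed = c(0.6, 60, 66, 17, 0.7))
  out <- extract_saccades(classify_segments(seg), vw)
  expect_equal(nrow(out), 1)  # main saccade + correction, no gap between
  expect_equal(out$launch_t, 0.3)
  expect_equal(out$landing_t, 0.38)
  none <- extract_saccades(classify_segments(seg[c(1, 5), ]), vw)
  expect_equal(nrow(none), 0)
})

test_that("detection of >= 2 degree saccades at 30 Hz exceeds 95% with few false alarms", {
  n_true <- 0; n_hit <- 0; n_fa <- 0
  for (seed in 1:3) {
    st <- make_staircase(seed, n_sac = 60, noise = 0.5)
    sac <- detect_saccades(st$gaze, vw)
    hit <- vapply(st$launch_t, function(tt) {
      any(sac$launch_t > tt - 1.55 / 30 & sac$launch_t < tt + 1.55 / 30)
    }, logical(1))
    fa <- sum(vapply(sac$launch_t, function(tt) {
      !any(abs(st$launch_t - tt) < 2 / 30)
    }, logical(1)))
    n_true <- n_true + length(hit); n_hit <- n_hit + sum(hit); n_fa <- n_fa + fa
  }
  expect_gte(n_hit / n_true, 0.95)
  expect_lte(n_fa / n_true, 0.05)
})

test_that("classification is invariant to a uniform screen translation", {
  st <- make_staircase(8, n_sac = 30, noise = 0.3)
  base <- extract_saccades(classify_segments(segment_gaze(st$gaze, vw)), vw)
  shifted <- dplyr::mutate(st$gaze, px = px + 40, py = py + 25)
  moved <- extract_saccades(classify_segments(segment_gaze(shifted, vw)), vw)
  expect_equal(nrow(moved), nrow(base))
  matched <- vapply(base$launch_t, function(tt) {
    min(abs(moved$launch_t - tt))
  }, numeric(1))
  expect_lt(max(matched), 1 / 30)
})

test_that("confidence gaps longer than 0.2 s break segments", {
  t <- c((0:29) / 30, (0:29) / 30 + 1.5)
  gz <- tibble::tibble(t = t, px = deg_to_px_x(c(rep(0, 30), rep(5, 30))),
                       py = deg_to_px_y(0), confidence = 1)
  seg <- segment_gaze(gz, vw)
  expect_equal(length(unique(seg$chunk)), 2)
  # the 5-degree jump across the gap is not a segment boundary inside a fit
  expect_true(all(seg$mean_speed < 25))
})
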