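v47 <- design_speed()  # ~13.09 m/s, i.e. "approximately 47 km/h"

test_that("a half-circle holds 16 slots spaced ~9.8 m, halving with doubled interval", {
  tr <- build_track(track_spec(n_turns = 3))
  slots <- generate_slots(tr, v47)
  per_turn <- table(slots$turn)
  expect_equal(unname(per_turn[["1"]]), 16)
  spacing <- diff(slots$arclength[slots$turn == 1])
  expect_equal(spacing, rep(v47 * 0.75, 15), tolerance = 1e-9)
  expect_equal(mean(spacing), 9.8, tolerance = 0.01)
  half <- generate_slots(tr, v47, interval = 1.5)
  expect_equal(sum(half$turn == 1), 8)
  expect_error(generate_slots(tr, v47, interval = 0), "interval")
})

test_that("slot 1 appears exactly when the driver crosses the curvature change", {
  tr <- build_track(track_spec(n_turns = 4))
  slots <- generate_slots(tr, v47)
  s1 <- slots[slots$slot == 1, ]
  expect_equal(s1$appear_arc, (s1$turn - 1) * tr$turn_length, tolerance = 1e-9)
  # appearance events are 0.75 s of travel apart, everywhere
  sched <- schedule_waypoints(tr, v47, seed = 1)
  ts <- sort(sched$appear_t)
  expect_equal(diff(ts), rep(0.75, length(ts) - 1), tolerance = 1e-9)
})

test_that("gap sampling enforces the adjacency rules and is uniform over the feasible set", {
  # feasible configurations: 4 gaps among 16 slots, >= 2 visible between
  sets <- gazeway:::feasible_gap_sets(16, 4, 3)
  expect_equal(ncol(sets), choose(10, 4))  # stars-and-bars count
  draws <- sample_gaps(2000, seed = 7)
  per_turn <- split(draws$slot, draws$turn)
  expect_true(all(lengths(per_turn) == 4))
  expect_true(all(vapply(per_turn, function(s) all(diff(sort(s)) >= 3),
                         logical(1))))
  # drawn configurations are consistent with uniform over the feasible set
  keys <- vapply(per_turn, function(s) paste(sort(s), collapse = "-"),
                 character(1))
  counts <- rep(0, ncol(sets))
  tab <- table(keys)
  counts[seq_along(tab)] <- as.vector(tab)  # zero cells kept
  expect_equal(sum(counts), length(per_turn))
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 1e-3)
  # infeasible demands fail loudly
  expect_error(sample_gaps(1, n_slots = 8, n_gaps = 4, min_sep = 3),
               "unsatisfiable")
})

test_that("rejected gap patterns violate the stated rules", {
  sets <- gazeway:::feasible_gap_sets(16, 4, 3)
  as_key <- apply(sets, 2, paste, collapse = "-")
  expect_false(paste(c(5, 6, 9, 12), collapse = "-") %in% as_key)  # successive
  expect_false(paste(c(5, 7, 10, 13), collapse = "-") %in% as_key) # 1 visible
  expect_true(paste(c(5, 8, 11, 14), collapse = "-") %in% as_key)
})

test_that("each turn has 12 visible and 4 missing waypoints", {
  tr <- build_track(track_spec(n_turns = 6))
  sched <- schedule_waypoints(tr, v47, seed = 3)
  tab <- table(sched$turn[sched$slot <= 16], sched$status[sched$slot <= 16])
  full_turns <- rowSums(tab) == 16
  expect_true(all(tab[full_turns, "missing"] == 4))
  expect_true(all(tab[full_turns, "visible"] == 12))
})

test_that("visibility follows the 2 s appearance, 0.25 s fade-in and removal rules", {
  tr <- build_track(track_spec(n_turns = 3))
  sched <- schedule_waypoints(tr, v47, seed = 5)
  wp <- sched[sched$turn == 2 & sched$slot == 5 & sched$status == "visible", ]
  if (nrow(wp) == 0) wp <- sched[sched$turn == 2 & sched$status == "visible", ][3, ]
  # just at appearance: visible with opacity 0; th = 2 s of nominal travel
  st <- visibility_at(sched, wp$appear_arc, wp$appear_t)
  row <- st[st$turn == wp$turn & st$slot == wp$slot, ]
  expect_true(row$visible)
  expect_equal(row$opacity, 0)
  expect_equal(row$th_now, 2, tolerance = 1e-9)
  # 0.25 s later: full opacity
  st2 <- visibility_at(sched, wp$appear_arc + 0.25 * v47)
  expect_equal(st2$opacity[st2$turn == wp$turn & st2$slot == wp$slot], 1)
  # missing slots are never visible
  miss <- sched[sched$status == "missing", ][1, ]
  for (arc in c(miss$appear_arc, miss$appear_arc + 5, miss$arclength - 5)) {
    stm <- visibility_at(sched, arc)
    expect_false(stm$visible[stm$turn == miss$turn & stm$slot == miss$slot])
  }
})

test_that("at most three waypoints are visible simultaneously without gaps", {
  tr <- build_track(track_spec(n_turns = 4))
  sched <- schedule_waypoints(tr, v47, n_gaps = 0, seed = 1)
  sched$status <- "visible"
  arcs <- seq(tr$turn_length, 3 * tr$turn_length, by = v47 / 60)
  n_vis <- vapply(arcs, function(a) sum(visibility_at(sched, a)$visible),
                  integer(1))
  expect_lte(max(n_vis), 3)
  expect_equal(max(n_vis), 3)  # reached just after each appearance
})

test_that("range labels follow the FAR/MID/NEAR bands with ties to the nearer band", {
  expect_equal(as.character(range_label(c(1.5, 1.0, 0.3, 2.5))),
               c("FAR", "MID", "NEAR", "UPCOMING"))
  expect_equal(as.character(range_label(c(0.5, 1.25, 2.0))),
               c("NEAR", "MID", "FAR"))
  expect_error(range_label(-0.1), "th")
})
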