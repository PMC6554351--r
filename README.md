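# gazeway

Simulation and analysis of gaze strategies for waypoint steering.

When humans steer a winding path, gaze does not rest on a point that moves
with the vehicle: it locks onto **waypoints** — world-fixed locations on
the future path 1–3 s of travel ahead — pursues each one as it approaches
(slow phases of ~0.4 s), and saccades ahead to the next. The critical test
of *predictive* gaze control is to present a path marked only by
periodically appearing waypoints and occasionally withhold one: an agent
with an internal model of the path saccades to the empty, but predictable,
location; a purely stimulus-driven agent stays on what is visible.

`gazeway` is a headless, fully tested implementation of that paradigm for
researchers in eye movements and visuomotor control. It provides:

* **Track and schedule geometry** — alternating 50 m half-circles
  (`build_track()`), yaw rates (`yaw_rate()`: 40 km/h ≈ 13 °/s; the
  nominal "47 km/h" is the speed giving exactly 15 °/s, `design_speed()`),
  and the 16-slots-per-turn waypoint schedule with constrained gap
  sampling — 4 missing of 16, never adjacent, ≥ 2 visible between gaps
  (`schedule_waypoints()`, `sample_gaps()`).
* **Scene projection** — a pinhole camera 1.5 m above the ground with a
  70° horizontal field of view (`project_ground_to_screen()`),
  pixel ↔ visual-angle conversion for a screen viewed at 0.85 m
  (`pixels_to_degrees()`), and optical-marker homography estimation by
  normalized DLT (`estimate_homography()`).
* **Synthetic data** — constant-speed telemetry with smooth
  Ornstein–Uhlenbeck lateral wander (`simulate_driver()`) and gaze
  generators for the open-loop pursue-and-saccade cycle
  (`simulate_gaze_exp1()`) and for four waypoint strategies — predictive,
  reactive, fixed-screen-point, constant-motor-program
  (`simulate_gaze_exp2()`, `gaze_strategy()`), plus tracker degradation
  (`degrade()`).
* **Saccade segmentation** — penalized continuous piecewise-linear
  segmentation by dynamic programming (`segment_gaze()`), the
  speed/duration saccade rule (`classify_segments()`), event extraction
  (`extract_saccades()`) and a matched-filter recovery tier
  (`detect_saccades()`) that reaches ≥ 95% detection of ≥ 2° saccades at
  30 Hz and 0.5° noise.
* **Analyses** — gaze time headway with the 3° trajectory exclusion
  (`time_headway()`, `compute_th_records()`, `summarize_exp1()`),
  waypoint AOI catch curves with the 4° rule and crossover points
  (`exp2_aoi_assignments()`, `catch_curves()`, `crossover_point()`), and
  the missing-waypoint saccade-vector analysis — normalization along the
  WP−1→WP axis with left-turn mirroring, per-participant Spearman
  correlations pooled by Fisher's z, Huber-loss line fits, paired t-tests
  with Cohen's d, exact binomial tests (`exp2_saccade_vectors()`,
  `amplitude_correlations()`, `saccade_shift_tests()`,
  `binomial_test()`).

Results are tibbles throughout; fitted objects have `tidy()`/`glance()`
methods and result types have `autoplot()`/`plot_*()` companions.

## The core quantities

For a fixated point $g$ and driver trajectory $x(t)$, the **gaze time
headway** is $\mathrm{TH} = t^\* - t$ where $t^\*$ minimizes the visual
angle, at the eye, between $g$ and $x(t^\*)$ over the future trajectory;
if that minimum exceeds 3°, no TH is assigned. **AOI catch** is the
fraction of gaze samples within 4° of a (possibly invisible) waypoint
location; the **crossover point** is the time from which the catch at the
newest (or missing) waypoint durably exceeds the preceding waypoint's.
Per-participant Spearman correlations $\rho_i$ pool as
$\bar\rho = \tanh\!\big(\tfrac1n\sum_i \mathrm{atanh}\,\rho_i\big)$.

## Worked example

One predictive agent driving ten turns of the waypoint track:

```r
library(gazeway)

track     <- build_track(track_spec(n_turns = 11))
v         <- design_speed()                       # 13.09 m/s = 15 deg/s
schedule  <- schedule_waypoints(track, v, seed = 1)
telemetry <- simulate_driver(track, v, 10 * track$turn_length / v, seed = 2)
gaze      <- simulate_gaze_exp2(telemetry, schedule, camera_spec(),
                                gaze_strategy("predictive"), seed = 3)

vw       <- viewing_geometry()
saccades <- detect_saccades(filter_confidence(gaze), vw)
aoi      <- exp2_aoi_assignments(gaze, telemetry, schedule, camera_spec(), vw)
curves   <- catch_curves(aoi)
crossover_point(curves, "visible")
#> [1] 0.4083333
crossover_point(curves, "missing")
#> [1] 0.5916667

late <- select_late_saccades(saccades, schedule)
vecs <- exp2_saccade_vectors(late, telemetry, schedule, camera_spec(), vw)
miss <- vecs[vecs$status == "missing", ]
nrow(miss)
#> [1] 19
spearman_rho(miss$wp_x_deg, miss$landing_x_deg)
#> [1] 0.84
mean(miss$launch_dist_wp - miss$landing_dist_wp)
#> [1] 4.27
```

Read: gaze catch crosses over to a newly *visible* waypoint about 0.41 s
after it appears, and to a *missing* waypoint's empty location about
0.18 s later — before the next waypoint appears at 0.75 s. In the last
0.25 s before that, 19 saccades were launched during missing-waypoint
events; their landing positions track where the invisible waypoint would
have been (Spearman ρ = 0.84), and each saccade moved gaze about 4.3°
closer to it — the signature of predictive waypoint targeting. A reactive
agent produces no missing-waypoint crossover at all
(`crossover_point(..., "missing")` is `NA`).

`autoplot(curves)` draws the catch curves, `autoplot(vecs)` the
normalized saccade vectors, and `plot_gaze_segments()` a gaze trace with
its segmentation.

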