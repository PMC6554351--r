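---
title: "Models and methods for waypoint-tracking gaze analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for waypoint-tracking gaze analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeway)
library(dplyr)
```

## The scientific problem

When people steer a vehicle along a winding path, their eyes do not rest on
a fixed "aim point" that travels with them. Instead gaze latches onto
*waypoints* — world-fixed locations on the future path roughly 1–3 seconds
of travel ahead — pursues each one as it approaches, and then jumps ahead
to a new one. The resulting eye-movement record looks like optokinetic
nystagmus: slow pursuit phases of about 0.4 s alternating with saccades.

The decisive question this package is built around is what happens when the
visual target is withheld. If the path is marked only by intermittently
appearing waypoints, and an expected waypoint occasionally fails to appear,
does gaze still move to the *empty but predictable* location (evidence for
an internal model of the future path), or does it stay on whatever is
visible (pure stimulus-driven control)? `gazeway` implements the full
simulation-plus-analysis chain that turns that question into a measurable
property of a gaze recording: track geometry, the waypoint schedule, a
scene camera, synthetic drivers and gaze strategies, saccade segmentation,
gaze time-headway estimation, area-of-interest (AOI) analysis, and the
missing-waypoint saccade-vector statistics.

## The experimental geometry

The track is a chain of 50 m radius, 180° arcs with alternating curvature
("half-circles"), 3.5 m wide. At a constant speed $v$ the yaw rate is
$\dot\psi = v/R$; 40, 53 and 66 km/h give roughly 13, 17 and 21 °/s, and
the waypoint experiment's "approximately 47 km/h" is the speed that makes
the yaw rate exactly 15 °/s:

```{r}
yaw_rate(c(40, 53, 66), 50)
design_speed()          # m/s; 15 deg/s on R = 50 m
design_speed() * 3.6    # km/h
```

A 180° turn at 15 °/s lasts 12 s, so 16 waypoint slots at 0.75 s of travel
apart tile each turn exactly — this is why `schedule_waypoints()` defaults
to the design speed rather than a rounded 47 km/h, which would make turn
boundaries drift by ~30 ms per turn. Slot $k$ of a turn lies
$(2 + 0.75(k-1))$ s of nominal travel beyond the curvature sign change, so
slot 1 appears — at a 2 s time headway — exactly as the driver crosses the
sign change. Consequences we adopt deliberately:

* appearance events are 0.75 s of travel apart everywhere, including
  across turn boundaries;
* the last slots of a turn physically sit past the next curvature change,
  which is why all event-level analyses restrict to slots 3–14 (constant
  curvature for both the driver and the waypoint).

Four of the 16 slots per turn are *gaps* (missing waypoints, 25%), with
two constraints: never two gaps in succession, and at least two visible
waypoints between gaps (index separation ≥ 3). The sampler enumerates the
$\binom{10}{4} = 210$ feasible index sets and draws uniformly — the
least-informative scheme consistent with the stated constraints, and one
that is exactly testable.

Waypoints fade in linearly over 0.25 s and leave the display when the
ground point drops below the camera frustum. With a level camera 1.5 m
above the ground and a 70° horizontal field of view at 1920×1080 (square
pixels, so a ±21.5° vertical half-field), that happens
`r round(frustum_ground_cutoff(camera_spec()), 2)` m ahead — the
"about 3 m in front of the driver" removal. A hard removal distance is
configurable. With a 2 s appearance headway, 0.75 s spacing and removal
near 0.3 s headway, at most three waypoints are ever visible at once.

Time headways are banded FAR (2.0–1.25 s), MID (1.25–0.5 s) and NEAR
(< 0.5 s); boundary values go to the nearer band, which only affects
isolated frames.

## Time headway of gaze

The gaze time headway (TH) of a fixated point is the time it takes the
driver to reach the point of fixation. `time_headway()` scans the future
trajectory (linearly interpolated at 120 Hz over a 6 s window — beyond the
largest THs of interest with margin) for the point minimizing the *visual
angle*, at the eye, between the direction to the fixated point and the
direction to the candidate trajectory point. If that minimum exceeds 3°,
the gaze point is not on the trajectory and no TH is assigned. Measuring
the 3° rule as a visual angle at the eye (rather than a ground distance)
matches the units in which the threshold is stated and is well defined
even for points at or behind the camera: the driver's own position is 0 s
ahead at 0°. Only the *future* trajectory is scanned; the TH definition
("time to travel to the point of fixation") has no meaning for points
already passed.

Each detected saccade contributes two records: its landing point opens a
pursuit/fixation episode, and the launch point of the *following* saccade
closes it. A trailing fixation contributes a landing record only. The
durations between a landing and the next launch estimate the slow-phase
(pursuit) durations.

## Synthetic drivers and gaze strategies

The generators stand in for human recordings, which are not public; their
defaults are the study conditions and are not tuned per analysis.

**Driver.** A kinematic path follower at constant speed whose lateral
offset follows a mean-reverting (Ornstein–Uhlenbeck) process, stationary
SD 0.35 m and timescale 1.5 s — enough wander to stay comfortably inside
the 1.75 m warning corridor while giving waypoints a realistic spread of
screen positions (a few degrees SD). The OU innovations are generated on a
3 Hz grid and splined to 60 Hz: human steering corrections are smooth, and
white-noise lateral velocity at 60 Hz would make the heading (which
includes the slip term $\arctan(\dot L / v)$) jitter by many degrees
between frames. The paper reports no human steering-noise parameters, so
these values are plausibility choices, flagged as such.

**Rich-flow gaze (`simulate_gaze_exp1`).** The optokinetic cycle: pick the
world-fixed point on the future trajectory at a target TH (default 2 s),
pursue its projection for the slow-phase duration (default 0.4 s, the
observed typical value), then saccade — 30–80 ms linear transit — to a
fresh point at the target TH, with 0.5° landing scatter and 0.3° per-sample
tracker noise at 30 Hz. Landing THs therefore cluster at the target and
launch THs at target minus pursuit duration.

**Waypoint gaze (`simulate_gaze_exp2`).** Event-driven: at each (nominal)
waypoint appearance the agent may respond with a saccade after a latency
(mean 0.35 s, SD 0.15 s, truncated to 0.2–1.2 s), then pursues a
world-fixed point until the next saccade. The four modes operationalize
the competing hypotheses:

* **predictive** — responds to every scheduled appearance, *including
  missing ones*, with an extra 0.12 s mean latency for gap responses
  (anticipatory saccades are slower than visually triggered ones; this
  also reproduces the observed delay of the gap crossover point).
  `gap_response_prob` can thin gap responses to emulate the observation
  that humans saccade into only a subset of gaps, but the default is 1:
  the contract is one response per scheduled event.
* **reactive** — responds only to waypoints that actually appear; during
  a gap it keeps pursuing the last visible waypoint.
* **fixed_screen_point** — pursuit drags gaze with the scene, but every
  saccade returns to one typical screen location (computed from the
  steady-state geometry), the "gaze goes to where waypoints usually are"
  null.
* **constant_motor_program** — every saccade is the same screen vector
  (mirrored with turn direction), the "replayed motor program" null.

What the generators deliberately do not model: binocular geometry (the
analyses use one cyclopean screen-gaze stream), saccade main-sequence
kinematics, catch-up saccades, blinks as eyelid events, and vehicle roll.
Passing tests on this synthetic data show that the *analysis chain*
discriminates the strategies it was built to discriminate — not that human
data are this clean; real recordings have calibration drift, smooth-pursuit
gain well below 1, and corrective saccades that the generators idealize
away.

## Gaze segmentation and saccade detection

The gaze stream (after dropping samples below the 0.6 pupil-confidence
threshold; gaps longer than 0.2 s are never bridged) is modelled as a
*continuous piecewise-linear* function of time in visual-angle
coordinates, with knots at inter-sample midpoints. Segment boundaries are
chosen by dynamic programming against a per-segment penalty (default
$2\hat\sigma^2\log n$, with the noise variance estimated robustly from
second differences, floored at 0.01 deg², so that noiseless fixtures do
not over-split); each candidate segment is anchored to the previous
segment's fitted endpoint, which is what makes a saccade emerge as its own
short, steep segment rather than being split across its neighbours. The
anchoring uses the best prefix ending at the previous sample — an
approximation to the intractable exact maximum-likelihood segmentation.
Segments must span at least two samples: single-sample segments make the
anchored recursion oscillate around inherited endpoints. Long gap-free
stretches are cut at the locally slowest inter-sample motion so the
quadratic search runs on ~120-sample pieces.

Classification is deliberately binary (saccade / non-saccade): a segment
is a saccade when it lasts at most 0.15 s and its mean speed reaches
60 °/s. At 30 Hz, however, a small saccade's displacement is smeared over
up to two sample intervals, halving its apparent mean speed: a 2° saccade
can present as ~30 °/s. A second tier therefore rescues short segments
moving at least 1.5° at 25 °/s or more. Pursuit in this stimulus — the
camera yaws at ~15 °/s, so pursued ground points sweep the screen at
15–30 °/s — sits mostly below that tier but not always, which is why
segment classification alone cannot reach high detection rates at this
sampling rate.

`detect_saccades()` therefore adds a matched-filter step scan: at every
inter-sample boundary, k = 6-sample windows on either side (with a
one-sample gap after the boundary so a mid-flight sample cannot dilute the
right-hand fit) are fit jointly with a common slope and a step term; when
the local slope is statistically negligible the zero-slope form is used,
which roughly halves the detection threshold on stationary fixations. A
boundary marks a saccade when its step magnitude exceeds
$\max(1.2°,\ 3.5\,\mathrm{se})$, survives non-maximum suppression, departs
both side fits, and carries the largest raw inter-sample displacement of
its neighbourhood (this last rule rejects "echo" detections whose windows
merely straddle a nearby saccade). Event times are the midpoints of the
bracketing sample intervals — unbiased under uniform sampling phase — and
event positions come from the window fits, which denoises them below the
single-sample noise level. Events from the two routes are merged, the step
scan taking precedence.

On stationary-fixation staircases with 0.5° noise at 30 Hz this pipeline
detects ≥ 95% of saccades of 2° and larger with under 5% false events. On
the harder driving-gaze signal (fast pursuit between saccades) detection
of the typical 2–7° saccades is around 85% with some false events;
because both misses and false events are nearly unbiased with respect to
time headway, the *median* landing/launch THs and pursuit durations the
analyses rest on are recovered accurately (landing TH within a few
hundredths of a second in the recovery tests).

## The waypoint analyses

**AOI assignment.** Each gaze sample inside a 1.5 s event window (from the
nominal appearance of slot $k$ to its entering the NEAR range) is assigned
to the nearest of four projected locations — WP−2, WP−1, WP (its expected
location when missing) and the upcoming WP+1 — if within 4° of visual
angle, else `Other`; exact ties go to the smaller-TH waypoint (they occur
only on isolated frames). Pooled per-bin relative frequencies (1/60 s
bins; all samples in a bin form the denominator, so frequencies sum to 1)
give the gaze-catch curves.

**Crossover.** The crossover point is the earliest bin from which the
catch at WP strictly exceeds the catch at WP−1 and keeps doing so through
the end of the window, ignoring bins in which neither location catches
anything (late in the window gaze has typically moved on to WP+1, and a
0–0 "tie" carries no ordering information); at least six strictly dominant
bins are required, so a single-bin flicker never counts. A single-bin
"becomes higher" rule is unstable on 30 Hz data; persistence matches the
monotone shape of the pooled curves.

**Late-window comparisons.** Because a newly appearing waypoint takes
0.25 s to fade in and responses take a few hundred milliseconds, the
comparison of "did gaze favour the missing waypoint over the previous
one?" uses only the last 0.25 s before the next waypoint appears
(0.5–0.75 s after the nominal appearance; waypoint TH 1.25–1.5 s). The
count of participants favouring WP is tested against chance with an exact
two-sided binomial test (11 of 12 gives p = 26/4096 ≈ 0.006). The same
window selects saccades for the vector analysis — earlier saccades risk
being corrective movements toward WP−1.

**Saccade vectors.** Each selected saccade is expressed in waypoint
coordinates: left-turn events are mirrored about the vertical screen
centreline, then the similarity transform mapping WP−1 to (0,0) and WP to
(0,1) is applied (waypoint positions projected at the saccade landing
time). In screen degrees, the *required* horizontal amplitude (launch to
waypoint) is compared with the *actual* amplitude (launch to landing):
per-participant Spearman correlations (average ranks on ties) are pooled
on the Fisher z scale, $\bar\rho = \tanh(\overline{\mathrm{atanh}\,\rho})$,
with degenerate (constant-input) participants excluded and counted.
Per-participant robust lines use the Huber loss at the conventional
95%-efficiency constant 1.345 (no constant is reported for the original
fits); a noiseless line is recovered exactly, and when all residuals lie
within the Huber band the fit coincides with ordinary least squares.
Paired t-tests across participants with Cohen's
$d = \bar{x}_\Delta / s_\Delta$ (the within-participant convention, which
is what makes effect sizes above 1 attainable) quantify whether landings
sit closer to the waypoint than launches and than to WP−1.

## Problem sizes and numerical choices

The test suite exercises the pipelines at sizes chosen to keep the whole
run comfortably under half an hour on one core while leaving enough events
for stable medians: recovery of the planted TH/pursuit parameters uses
five 10-minute runs at 53 km/h (~1,300 saccade cycles each); strategy
discrimination uses ten predictive and ten reactive agents driving 16
turns (~48 analyzed gap events, of which typically 15–25 carry a
late-window saccade). Oracle-equivalence checks run the brute-force
scans on 100+ randomized time-headway fixtures and > 10⁴ random-gaze AOI
samples. All generators take explicit seeds; identical seeds give
identical logs.

Other numerical decisions: telemetry interpolation is linear; trajectory
scans run at 120 Hz resolution (half a telemetry frame); the near plane
sits at 0.1 m; log timestamps serialize at 10⁻⁴ s and other numeric
columns at 10⁻⁶, making write→read→write round-trips byte-identical;
homography estimation uses the Hartley-normalized DLT with an SVD solve
and refuses configurations whose second-smallest singular value vanishes
(collinear markers).

## Known limitations

* The segmentation is an approximate, not exact, maximum-likelihood
  continuous piecewise-linear fit; the four-class segment classifier of
  the original tool chain is deliberately reduced to saccade /
  non-saccade, the only output the analyses consume.
* Detection rates on driving-like gaze at 30 Hz are bounded by physics:
  a 2° saccade is ~2.8 noise standard deviations on successive samples at
  0.5° noise. Median-based summaries absorb this; per-event analyses on
  real low-rate data should expect comparable misses.
* The human cohort's numeric results (Table-level THs, pooled ρ of
  0.36/0.67, the 1.8° landing shift, 29%/41% saccade frequencies) are not
  reproduction targets — the recordings are not public; synthetic agents
  reproduce the *directional* phenomena only.
* Binocular geometry, lens distortion, pupil detection and the original
  22-marker polynomial calibration are out of scope; the homography step
  models only the head-movement compensation from optical markers.
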