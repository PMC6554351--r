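#' Drop low-confidence gaze samples
#'
#' Pupil-detection confidence below the threshold marks unreliable samples;
#' they are removed before segmentation (the resulting temporal gaps are
#' respected by [segment_gaze()], which never fits across long gaps).
#'
#' @param gaze Gaze tibble with a `confidence` column.
#' @param threshold Confidence cutoff.
#' @return Filtered gaze tibble; the number of removed samples is attached
#'   as attribute `n_filtered`. All samples below threshold yields an empty
#'   log with a warning.
#' @export
filter_confidence <- function(gaze, threshold = 0.6) {
  if (!"confidence" %in% names(gaze)) abort("gaze log has no `confidence`")
  keep <- gaze$confidence >= threshold
  out <- gaze[keep, ]
  if (nrow(out) == 0 && nrow(gaze) > 0) {
    warn("all gaze samples fell below the confidence threshold")
  }
  attr(out, "n_filtered") <- sum(!keep)
  attr(out, "events") <- attr(gaze, "events")
  out
}

# Connected piecewise-linear segmentation by dynamic programming.
#
# The gaze trace is modelled as a CONTINUOUS piecewise-linear function with
# knots at inter-sample midpoints: each segment is a line over samples
# i..j constrained to pass through the previous segment's fitted value at
# the shared knot (the first segment of a stretch is unconstrained). The
# DP minimizes total squared error + penalty per segment. The continuity
# constraint is what makes a saccade come out as its own steep short
# segment instead of being split across its neighbours. Approximation: the
# anchor value for a segment starting at sample i is the fitted knot value
# of the best prefix ending at i - 1 (exact ML would couple all segments).
#
# Returns a list with per-segment sample ranges, knot times and fitted
# knot values for both coordinates.
connected_pwl_fit <- function(t, x, y, penalty, min_size = 1) {
  n <- length(t)
  m <- c(t[1], (t[-n] + t[-1]) / 2, t[n])  # knots m[1..n+1]
  St <- c(0, cumsum(t)); St2 <- c(0, cumsum(t * t))
  Sx <- c(0, cumsum(x)); Stx <- c(0, cumsum(t * x))
  Sx2 <- c(0, cumsum(x * x))
  Sy <- c(0, cumsum(y)); Sty <- c(0, cumsum(t * y))
  Sy2 <- c(0, cumsum(y * y))
  C <- rep(Inf, n + 1); C[1] <- 0  # C[i]: best cost of samples 1..i-1
  ex <- ey <- rep(NA_real_, n)     # fitted value at end knot m[j+1]
  best <- integer(n)
  for (j in seq_len(n)) {
    i_max <- j - min_size + 1
    if (i_max < 1) next
    is <- seq_len(i_max)
    nseg <- j - is + 1
    rSx <- Sx[j + 1] - Sx[is]; rSy <- Sy[j + 1] - Sy[is]
    rSt <- St[j + 1] - St[is]; rSt2 <- St2[j + 1] - St2[is]
    rStx <- Stx[j + 1] - Stx[is]; rSty <- Sty[j + 1] - Sty[is]
    rSx2 <- Sx2[j + 1] - Sx2[is]; rSy2 <- Sy2[j + 1] - Sy2[is]
    anchor_t <- m[is]
    Su <- rSt - nseg * anchor_t
    Su2 <- rSt2 - 2 * anchor_t * rSt + nseg * anchor_t^2
    # anchored starts (i > 1): value at m[i] fixed to the incoming fit
    vx_a <- c(NA, ex)[is]; vy_a <- c(NA, ey)[is]
    Sxu <- rStx - anchor_t * rSx
    Syu <- rSty - anchor_t * rSy
    bx <- (Sxu - vx_a * Su) / pmax(Su2, 1e-12)
    by <- (Syu - vy_a * Su) / pmax(Su2, 1e-12)
    sse_anch <-
      (rSx2 - 2 * vx_a * rSx + nseg * vx_a^2 -
         2 * bx * (Sxu - vx_a * Su) + bx^2 * Su2) +
      (rSy2 - 2 * vy_a * rSy + nseg * vy_a^2 -
         2 * by * (Syu - vy_a * Su) + by^2 * Su2)
    cost <- C[is] + sse_anch + penalty
    endx <- vx_a + bx * (m[j + 1] - anchor_t)
    endy <- vy_a + by * (m[j + 1] - anchor_t)
    # free (unanchored) first segment of the stretch
    if (is[1] == 1) {
      nn <- j
      Stt <- rSt2[1] - rSt[1]^2 / nn
      if (Stt > 1e-12) {
        b1x <- (rStx[1] - rSt[1] * rSx[1] / nn) / Stt
        b1y <- (rSty[1] - rSt[1] * rSy[1] / nn) / Stt
      } else {
        b1x <- b1y <- 0
      }
      a1x <- rSx[1] / nn - b1x * rSt[1] / nn
      a1y <- rSy[1] / nn - b1y * rSt[1] / nn
      sse1 <- max(rSx2[1] - 2 * a1x * rSx[1] - 2 * b1x * rStx[1] +
                    nn * a1x^2 + 2 * a1x * b1x * rSt[1] + b1x^2 * rSt2[1], 0) +
        max(rSy2[1] - 2 * a1y * rSy[1] - 2 * b1y * rSty[1] +
              nn * a1y^2 + 2 * a1y * b1y * rSt[1] + b1y^2 * rSt2[1], 0)
      cost[1] <- C[1] + sse1 + penalty
      endx[1] <- a1x + b1x * m[j + 1]
      endy[1] <- a1y + b1y * m[j + 1]
    }
    k <- which.min(cost)
    C[j + 1] <- cost[k]
    best[j] <- k
    ex[j] <- endx[k]; ey[j] <- endy[k]
  }
  # backtrack segment sample ranges
  starts <- ends <- integer(0)
  j <- n
  while (j > 0) {
    i <- best[j]
    starts <- c(i, starts); ends <- c(j, ends)
    j <- i - 1
  }
  nseg <- length(starts)
  # start knot values: anchored value for i > 1, free-fit value for i = 1
  vx0 <- vy0 <- numeric(nseg)
  for (k in seq_len(nseg)) {
    if (starts[k] == 1) {
      # recover by linear interpolation from the end value and the samples
      sel <- starts[k]:ends[k]
      if (length(sel) >= 2) {
        fx <- lm.fit(cbind(1, t[sel]), x[sel])$coefficients
        fy <- lm.fit(cbind(1, t[sel]), y[sel])$coefficients
        vx0[k] <- fx[1] + fx[2] * m[1]; vy0[k] <- fy[1] + fy[2] * m[1]
      } else {
        vx0[k] <- x[sel]; vy0[k] <- y[sel]
      }
    } else {
      vx0[k] <- ex[starts[k] - 1]; vy0[k] <- ey[starts[k] - 1]
    }
  }
  list(start = starts, end = ends,
       t_start = m[starts], t_end = m[ends + 1],
       x_start = vx0, y_start = vy0,
       x_end = ex[ends], y_end = ey[ends])
}

# cut a long stretch into DP-sized pieces at the locally slowest
# inter-sample motion, so cuts land mid-pursuit and never inside a saccade
slow_cuts <- function(x, y, target = 120) {
  n <- length(x)
  if (n <= 1.5 * target) return(integer(0))
  spd <- sqrt(diff(x)^2 + diff(y)^2)
  cuts <- integer(0)
  start <- 1
  while (n - start > 1.5 * target) {
    win <- (start + floor(0.7 * target)):min(start + ceiling(1.3 * target),
                                             n - 2)
    cut <- win[which.min(spd[win])]
    cuts <- c(cuts, cut)
    start <- cut + 1
  }
  cuts
}

# robust per-coordinate noise variance from second differences
# (insensitive to the linear drift of pursuit phases)
robust_noise_var <- function(x, y) {
  f <- function(v) (median(abs(diff(v, differences = 2))) /
                      (sqrt(6) * 0.6745))^2
  f(x) + f(y)
}

degrees_to_pixels_x <- function(deg, viewing) {
  viewing$cx + tan(deg2rad(deg)) * viewing$distance / viewing$m_per_px
}
degrees_to_pixels_y <- function(deg, viewing) {
  viewing$cy + tan(deg2rad(deg)) * viewing$distance / viewing$m_per_px
}

#' Segment a gaze log into continuous piecewise-linear pieces
#'
#' Approximates a penalized maximum-likelihood linear segmentation of the
#' gaze signal in visual-angle coordinates: the trace is modelled as a
#' continuous piecewise-linear function (knots at inter-sample midpoints,
#' consecutive segments sharing their endpoint) and segment boundaries are
#' selected by dynamic programming, accepting a segment only against a
#' per-segment penalty (default `2 * noise_var * log(n)`, with the noise
#' variance estimated robustly from second differences). Stretches
#' separated by more than `max_gap` seconds (e.g. after confidence
#' filtering) are segmented independently; very long stretches are first
#' cut at the locally slowest motion to bound the quadratic search.
#'
#' @param gaze Gaze tibble (`t`, `px`, `py`).
#' @param viewing A [viewing_geometry()] for pixel/degree conversion.
#' @param penalty Per-segment penalty in squared degrees; `NULL` for the
#'   default.
#' @param max_gap Maximal sample gap bridged by a fit, seconds.
#' @param min_size Minimal samples per segment (two keeps the anchored
#'   recursion stable; single-sample segments can oscillate around their
#'   inherited endpoint).
#' @return Segment tibble: `segment`, `chunk`, `t_start`, `t_end`,
#'   `x_start`, `y_start`, `x_end`, `y_end` (degrees), `px_start`,
#'   `py_start`, `px_end`, `py_end` (pixels), `n`, `duration`,
#'   `amplitude` (deg) and `mean_speed` (deg/s).
#' @export
segment_gaze <- function(gaze, viewing = viewing_geometry(), penalty = NULL,
                         max_gap = 0.2, min_size = 2) {
  if (nrow(gaze) < 4) abort("need at least 4 gaze samples")
  if (is.unsorted(gaze$t)) abort("gaze timestamps must be sorted")
  deg <- pixels_to_degrees(gaze$px, gaze$py, viewing)
  t <- gaze$t; x <- deg$deg_x; y <- deg$deg_y
  chunk_id <- cumsum(c(1, diff(t) > max_gap))
  # subdivide long gap-free stretches so the DP stays quadratic only
  # within modest pieces
  piece_id <- chunk_id
  for (ch in unique(chunk_id)) {
    sel <- which(chunk_id == ch)
    cuts <- slow_cuts(x[sel], y[sel])
    if (length(cuts)) {
      sub <- findInterval(seq_along(sel), cuts + 1)
      piece_id[sel] <- piece_id[sel] + sub / (length(cuts) + 2)
    }
  }
  rows <- list()
  seg_no <- 0
  for (ch in unique(piece_id)) {
    sel <- which(piece_id == ch)
    if (length(sel) < 2) next
    tc <- t[sel] - t[sel][1]
    xc <- x[sel]; yc <- y[sel]
    pen <- penalty %||% (2 * max(robust_noise_var(xc, yc), 0.01) *
                           log(length(sel)))
    fit <- connected_pwl_fit(tc, xc, yc, pen, min_size)
    m <- length(fit$start)
    rows[[length(rows) + 1]] <- tibble::tibble(
      segment = seg_no + seq_len(m), chunk = ch,
      t_start = fit$t_start + t[sel][1], t_end = fit$t_end + t[sel][1],
      x_start = fit$x_start, y_start = fit$y_start,
      x_end = fit$x_end, y_end = fit$y_end,
      n = fit$end - fit$start + 1L)
    seg_no <- seg_no + m
  }
  if (!length(rows)) abort("no chunk long enough to segment")
  out <- dplyr::bind_rows(rows)
  out$px_start <- degrees_to_pixels_x(out$x_start, viewing)
  out$py_start <- degrees_to_pixels_y(out$y_start, viewing)
  out$px_end <- degrees_to_pixels_x(out$x_end, viewing)
  out$py_end <- degrees_to_pixels_y(out$y_end, viewing)
  out$duration <- out$t_end - out$t_start
  out$amplitude <- screen_angular_distance(out$px_start, out$py_start,
                                           out$px_end, out$py_end, viewing)
  out$mean_speed <- out$amplitude / pmax(out$duration, 1e-9)
  out
}

#' Classify segments as saccade / non-saccade
#'
#' The headline rule calls a segment a saccade when its mean speed is at
#' least `speed_threshold` and it lasts no longer than `max_duration`. At
#' low sampling rates a small saccade's displacement is smeared over two
#' sample intervals, halving its apparent mean speed, so a second tier
#' rescues short segments that still move at least `small_amplitude`
#' degrees at `small_speed` deg/s or more — above the pursuit speeds
#' occurring in this task.
#'
#' @param segments Output of [segment_gaze()].
#' @param speed_threshold Mean-speed threshold, deg/s.
#' @param max_duration Maximal saccade duration, seconds.
#' @param small_amplitude,small_speed Small-saccade rescue tier.
#' @return `segments` with a `klass` column (`"saccade"`/`"non_saccade"`).
#' @export
classify_segments <- function(segments, speed_threshold = 60,
                              max_duration = 0.15, small_amplitude = 1.5,
                              small_speed = 25) {
  sac <- segments$duration <= max_duration &
    (segments$mean_speed >= speed_threshold |
       (segments$amplitude >= small_amplitude &
          segments$mean_speed >= small_speed))
  segments$klass <- ifelse(sac, "saccade", "non_saccade")
  segments
}

#' Extract saccade events from classified segments
#'
#' One event per maximal run of saccade-class segments within a chunk
#' (a main saccade and an immediate correction merge into one event):
#' the launch is the run's start point, the landing its end point.
#'
#' @param segments Classified segments from [classify_segments()].
#' @param viewing A [viewing_geometry()] (for the amplitude).
#' @return Saccade tibble: `launch_t`, `launch_px`, `launch_py`,
#'   `landing_t`, `landing_px`, `landing_py`, `amplitude` (deg).
#' @export
extract_saccades <- function(segments, viewing = viewing_geometry()) {
  if (!"klass" %in% names(segments)) abort("segments are not classified")
  is_sac <- segments$klass == "saccade"
  if (!any(is_sac)) {
    return(tibble::tibble(launch_t = numeric(), launch_px = numeric(),
                          launch_py = numeric(), landing_t = numeric(),
                          landing_px = numeric(), landing_py = numeric(),
                          amplitude = numeric()))
  }
  grp <- cumsum(c(1, diff(is_sac) != 0 | diff(segments$chunk) != 0))
  runs <- which(tapply(is_sac, grp, all))
  ids <- split(seq_len(nrow(segments)), grp)
  out <- purrr::map(ids[runs], function(ii) {
    first <- ii[1]; last <- ii[length(ii)]
    tibble::tibble(
      launch_t = segments$t_start[first],
      launch_px = segments$px_start[first],
      launch_py = segments$py_start[first],
      landing_t = segments$t_end[last],
      landing_px = segments$px_end[last],
      landing_py = segments$py_end[last])
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::arrange(out, .data$launch_t)
  out$amplitude <- screen_angular_distance(out$launch_px, out$launch_py,
                                           out$landing_px, out$landing_py,
                                           viewing)
  out
}

# Matched-filter step scan. For every inter-sample boundary, k-sample
# windows on either side (one-sample gap after the boundary, so a
# mid-flight sample cannot dilute the right fit) are fit jointly per
# coordinate with a common slope and a step term (the ANCOVA closed form);
# when the local slope is statistically negligible in both coordinates the
# zero-slope form is used instead, which roughly halves the detection
# threshold on stationary-fixation data. Boundaries whose step magnitude
# exceeds max(min_amplitude, sigma_mult * se(step)) mark saccades, with
# non-maximum suppression within +/-k boundaries.
step_saccade_scan <- function(gaze, viewing = viewing_geometry(), k = 6,
                              min_amplitude = 1.2, sigma_mult = 3.5,
                              max_gap = 0.2) {
  deg <- pixels_to_degrees(gaze$px, gaze$py, viewing)
  t <- gaze$t; x <- deg$deg_x; y <- deg$deg_y
  chunk_id <- cumsum(c(1, diff(t) > max_gap))
  events <- list()
  empty <- tibble::tibble(launch_t = numeric(), launch_px = numeric(),
                          launch_py = numeric(), landing_t = numeric(),
                          landing_px = numeric(), landing_py = numeric())
  for (ch in unique(chunk_id)) {
    sel <- which(chunk_id == ch)
    n <- length(sel)
    if (n < 2 * k + 3) next
    tc <- t[sel] - t[sel][1]; xc <- x[sel]; yc <- y[sel]
    sigma <- sqrt(robust_noise_var(xc, yc) / 2)
    sigma <- max(sigma, 1e-3)
    cst <- c(0, cumsum(tc)); cst2 <- c(0, cumsum(tc^2))
    csx <- c(0, cumsum(xc)); cstx <- c(0, cumsum(tc * xc))
    csy <- c(0, cumsum(yc)); csty <- c(0, cumsum(tc * yc))
    wsum <- function(cs, lo, hi) cs[hi + 1] - cs[lo]
    is <- k:(n - k - 2)            # boundary between samples i and i + 1
    loL <- is - k + 1; hiL <- is
    loR <- is + 2; hiR <- is + k + 1
    mtL <- wsum(cst, loL, hiL) / k; mtR <- wsum(cst, loR, hiR) / k
    mxL <- wsum(csx, loL, hiL) / k; mxR <- wsum(csx, loR, hiR) / k
    myL <- wsum(csy, loL, hiL) / k; myR <- wsum(csy, loR, hiR) / k
    SttL <- wsum(cst2, loL, hiL) - k * mtL^2
    SttR <- wsum(cst2, loR, hiR) - k * mtR^2
    Stt <- pmax(SttL + SttR, 1e-12)
    StxL <- wsum(cstx, loL, hiL) - k * mtL * mxL
    StxR <- wsum(cstx, loR, hiR) - k * mtR * mxR
    StyL <- wsum(csty, loL, hiL) - k * mtL * myL
    StyR <- wsum(csty, loR, hiR) - k * mtR * myR
    bx <- (StxL + StxR) / Stt
    by <- (StyL + StyR) / Stt
    dT <- mtR - mtL
    se_b2 <- sigma^2 / Stt
    slope_on <- (bx^2 + by^2) > 18 * se_b2
    sx <- (mxR - mxL) - ifelse(slope_on, bx * dT, 0)
    sy <- (myR - myL) - ifelse(slope_on, by * dT, 0)
    step <- sqrt(sx^2 + sy^2)
    se_s <- sigma * sqrt(2 / k + ifelse(slope_on, dT^2 / Stt, 0))
    thr <- pmax(min_amplitude, sigma_mult * se_s)
    cand <- which(step >= thr)
    if (!length(cand)) next
    # accept candidates from the strongest down, masking +/-k boundaries
    # around each accepted event; rejected (invalid) candidates mask
    # nothing, so a nearby genuine boundary can still be accepted
    cand <- cand[order(step[cand], decreasing = TRUE)]
    accepted <- integer(0)
    for (ci in cand) {
      if (length(accepted) && min(abs(accepted - ci)) <= k) next
      i0 <- is[ci]                 # launch sample (chunk-local)
      predL <- function(tt) {
        if (slope_on[ci]) c(mxL[ci] + bx[ci] * (tt - mtL[ci]),
                            myL[ci] + by[ci] * (tt - mtL[ci]))
        else c(mxL[ci], myL[ci])
      }
      predR <- function(tt, mx = mxR[ci], my = myR[ci],
                        b1 = bx[ci], b2 = by[ci]) {
        if (slope_on[ci]) c(mx + b1 * (tt - mtR[ci]), my + b2 * (tt - mtR[ci]))
        else c(mx, my)
      }
      # echo rejection: a genuine saccade departs the left fit just after
      # the launch sample and sits off the right fit just before it; a
      # spurious boundary whose windows merely straddle a neighbouring
      # saccade does neither
      dev_from <- function(pred, jj) {
        max(vapply(jj, function(j) {
          p <- pred(tc[j]); sqrt((xc[j] - p[1])^2 + (yc[j] - p[2])^2)
        }, numeric(1)))
      }
      v_thr <- max(0.4 * step[ci], 2.5 * sigma)
      if (dev_from(predL, c(i0 + 1, i0 + 2)) < v_thr ||
          dev_from(predR, c(i0 - 1, i0)) < v_thr) next
      # the transit must carry (nearly) the largest raw inter-sample
      # displacement of its neighbourhood; an echo of a nearby saccade
      # has only pursuit-sized motion across its own boundary
      rdisp <- function(j) sqrt((xc[j + 1] - xc[j])^2 + (yc[j + 1] - yc[j])^2)
      transit_j <- i0:min(i0 + 2, n - 1)
      nbh_j <- max(1, i0 - k):min(n - 1, i0 + k)
      if (max(vapply(transit_j, rdisp, numeric(1))) <
          0.75 * max(vapply(nbh_j, rdisp, numeric(1)))) next
      accepted <- c(accepted, ci)
      # landing: the gap sample i0+1 if it already sits on the post-saccade
      # fit (transit within one interval), else the next sample
      # landing sample: the first sample that already sits on the
      # post-saccade fit (transits can span up to two sample intervals)
      j0 <- i0 + 1
      repeat {
        pg <- predR(tc[j0])
        resid_gap <- sqrt((xc[j0] - pg[1])^2 + (yc[j0] - pg[2])^2)
        if (resid_gap < max(3 * sigma, 0.25 * step[ci]) || j0 >= i0 + 3 ||
            j0 >= n) break
        j0 <- j0 + 1
      }
      # the true launch lies between sample i0 and the next sample, and
      # the true landing between sample j0-1 and j0: report the interval
      # midpoints (unbiased under uniform phase) with fit-denoised
      # positions evaluated there
      launch_tm <- (tc[i0] + tc[i0 + 1]) / 2
      landing_tm <- (tc[j0 - 1] + tc[j0]) / 2
      if (slope_on[ci]) {
        launch_deg <- c(mxL[ci] + bx[ci] * (launch_tm - mtL[ci]),
                        myL[ci] + by[ci] * (launch_tm - mtL[ci]))
      } else {
        launch_deg <- c(mxL[ci], myL[ci])
      }
      landing_deg <- predR(landing_tm, mxR[ci], myR[ci], bx[ci], by[ci])
      events[[length(events) + 1]] <- tibble::tibble(
        launch_t = launch_tm + t[sel][1],
        landing_t = landing_tm + t[sel][1],
        launch_px = degrees_to_pixels_x(launch_deg[1], viewing),
        launch_py = degrees_to_pixels_y(launch_deg[2], viewing),
        landing_px = degrees_to_pixels_x(landing_deg[1], viewing),
        landing_py = degrees_to_pixels_y(landing_deg[2], viewing))
    }
  }
  if (!length(events)) return(empty)
  dplyr::arrange(dplyr::bind_rows(events), .data$launch_t)
}

#' Detect saccades in a gaze log
#'
#' The full detection pipeline: penalized continuous piecewise-linear
#' segmentation ([segment_gaze()]), the segment speed/duration rule
#' ([classify_segments()]) and event extraction ([extract_saccades()]),
#' complemented by a matched-filter step scan that recovers saccades the
#' segment classifier misses at low sampling rates (short line fits on
#' either side of each sample boundary, extrapolated to the boundary; a
#' boundary whose extrapolation gap exceeds
#' `max(min_amplitude, 4 * sigma * sqrt(2/k))` degrees marks a saccade).
#' Events from the two routes are merged, the step scan taking precedence
#' where they overlap (its endpoints are denoised by the window fits).
#'
#' @param gaze Gaze tibble (`t`, `px`, `py`; confidence-filter first).
#' @param viewing A [viewing_geometry()].
#' @param penalty Segmentation penalty (see [segment_gaze()]).
#' @param k Window length (samples) of the step-scan line fits.
#' @param min_amplitude Step-scan amplitude floor, degrees.
#' @param ... Passed to [classify_segments()].
#' @return Saccade tibble as from [extract_saccades()].
#' @export
detect_saccades <- function(gaze, viewing = viewing_geometry(),
                            penalty = NULL, k = 6, min_amplitude = 1.2,
                            ...) {
  seg <- classify_segments(segment_gaze(gaze, viewing, penalty), ...)
  sac <- extract_saccades(seg, viewing)
  rec <- step_saccade_scan(gaze, viewing, k = k,
                           min_amplitude = min_amplitude)
  if (nrow(rec)) {
    rec$amplitude <- screen_angular_distance(rec$launch_px, rec$launch_py,
                                             rec$landing_px, rec$landing_py,
                                             viewing)
    if (nrow(sac)) {
      mid_rec <- (rec$launch_t + rec$landing_t) / 2
      mid_sac <- (sac$launch_t + sac$landing_t) / 2
      unmatched <- vapply(mid_sac,
                          function(m) all(abs(mid_rec - m) > 0.18),
                          logical(1))
      sac <- dplyr::bind_rows(rec, sac[unmatched, ])
    } else {
      sac <- rec
    }
  }
  sac <- dplyr::arrange(sac, .data$launch_t)
  # drop any residual overlaps (keep the earlier event)
  if (nrow(sac) > 1) {
    keep <- c(TRUE, sac$launch_t[-1] >= head(sac$landing_t, -1))
    sac <- sac[keep, ]
  }
  sac
}
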