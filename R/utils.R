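#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median sd cor approx approxfun rnorm runif rbinom t.test
#'   binom.test lm lm.fit coef setNames
#' @importFrom utils head tail combn
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Convert speed from km/h to m/s
#'
#' @param kmh Speed in kilometres per hour.
#' @return Speed in metres per second.
#' @export
kmh_to_ms <- function(kmh) kmh / 3.6

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

# linear interpolators for a telemetry log; headings are continuous
# (unwrapped) by construction of the track model, so plain approxfun works
telemetry_interpolator <- function(telemetry) {
  if (is.unsorted(telemetry$t, strictly = TRUE)) {
    abort("telemetry timestamps must be strictly increasing")
  }
  list(
    x = approxfun(telemetry$t, telemetry$x, rule = 2),
    y = approxfun(telemetry$t, telemetry$y, rule = 2),
    heading = approxfun(telemetry$t, telemetry$heading, rule = 2),
    speed = approxfun(telemetry$t, telemetry$speed, rule = 2),
    t_min = min(telemetry$t),
    t_max = max(telemetry$t)
  )
}

new_seeded_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
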