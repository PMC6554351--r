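#' Plot gaze-catch time courses
#'
#' One panel per condition, relative gaze-catch frequency per AOI over
#' time since the (nominal) waypoint appearance.
#'
#' @param object A [catch_curves()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gw_catch_curves
#' @export
autoplot.gw_catch_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t_mid, y = .data$freq,
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "time since (nominal) waypoint appearance (s)",
                  y = "relative gaze-catch frequency", colour = "AOI") +
    ggplot2::theme_minimal()
}

#' Plot normalized saccade vectors
#'
#' Launch-to-landing segments in the waypoint-aligned frame (WP-1 at
#' (0, 0), WP at (0, 1); left turns mirrored).
#'
#' @param object A `gw_saccade_vectors` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gw_saccade_vectors
#' @export
autoplot.gw_saccade_vectors <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$launch_x, y = .data$launch_y,
                   xend = .data$landing_x, yend = .data$landing_y),
      alpha = 0.4,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::annotate("point", x = c(0, 0), y = c(0, 1), size = 3,
                      shape = c(19, 4)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "normalized x (WP-1 at origin)",
                  y = "normalized y (WP at (0,1))") +
    ggplot2::theme_minimal()
}

#' Plot time-headway distributions of saccade launch and landing points
#'
#' @param th_records Records with `kind` and `th` (e.g. from
#'   [compute_th_records()], optionally with a `speed` column for
#'   faceting).
#' @return A ggplot object.
#' @export
plot_th_distribution <- function(th_records) {
  d <- th_records[is.finite(th_records$th), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$th, fill = .data$kind)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "time headway (s)", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
  if ("speed" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$speed))
  }
  p
}

#' Plot a gaze trace with its piecewise-linear segmentation
#'
#' Horizontal gaze position over time with the fitted segments overlaid;
#' saccade-class segments are highlighted when the segments are
#' classified.
#'
#' @param gaze Gaze tibble.
#' @param segments Output of [segment_gaze()] (classified or not).
#' @return A ggplot object.
#' @export
plot_gaze_segments <- function(gaze, segments) {
  p <- ggplot2::ggplot(gaze, ggplot2::aes(x = .data$t, y = .data$px)) +
    ggplot2::geom_point(size = 0.3, colour = "grey40")
  if ("klass" %in% names(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$t_start, y = .data$px_start,
                   xend = .data$t_end, yend = .data$px_end,
                   colour = .data$klass))
  } else {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$t_start, y = .data$px_start,
                   xend = .data$t_end, yend = .data$px_end),
      colour = "firebrick")
  }
  p + ggplot2::labs(x = "time (s)", y = "horizontal gaze (px)") +
    ggplot2::theme_minimal()
}
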