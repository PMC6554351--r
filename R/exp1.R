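#' Summarize time-headway records across participants and speeds
#'
#' Reproduces the rich-flow steering summary: per participant and speed
#' condition, the median saccade landing and launch time headways and the
#' median pursuit/fixation duration; per condition, the mean and SD of the
#' participant medians, the median within-participant SD (and its
#' between-participant SD); and the Pearson correlations of the
#' participant medians (and within-participant SDs) with speed, computed
#' on the pooled (participant, speed) pairs.
#'
#' @param th_records Tibble with columns `participant`, `speed`, `kind`
#'   (`"saccade_landing"`/`"saccade_launch"`) and `th` (NA rows — excluded
#'   events — are dropped).
#' @param durations Optional tibble with `participant`, `speed`,
#'   `duration` (pursuit intervals).
#' @return A `gw_exp1_summary` object; see [tidy()]/[glance()] methods.
#' @export
summarize_exp1 <- function(th_records, durations = NULL) {
  need <- c("participant", "speed", "kind", "th")
  if (!all(need %in% names(th_records))) {
    abort("`th_records` needs participant, speed, kind, th columns")
  }
  recs <- dplyr::filter(th_records, is.finite(.data$th))
  cells <- recs |>
    dplyr::group_by(.data$participant, .data$speed, .data$kind) |>
    dplyr::summarise(median_th = median(.data$th),
                     within_sd = sd(.data$th), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "kind",
                       values_from = c("median_th", "within_sd", "n"))
  if (!is.null(durations)) {
    dmed <- durations |>
      dplyr::group_by(.data$participant, .data$speed) |>
      dplyr::summarise(median_duration = median(.data$duration),
                       .groups = "drop")
    cells <- dplyr::left_join(cells, dmed, by = c("participant", "speed"))
  }
  summ <- cells |>
    dplyr::group_by(.data$speed) |>
    dplyr::summarise(
      mean_landing_th = mean(.data$median_th_saccade_landing, na.rm = TRUE),
      sd_landing_th = sd(.data$median_th_saccade_landing, na.rm = TRUE),
      mean_launch_th = mean(.data$median_th_saccade_launch, na.rm = TRUE),
      sd_launch_th = sd(.data$median_th_saccade_launch, na.rm = TRUE),
      mean_duration = if ("median_duration" %in% names(cells))
        mean(.data$median_duration, na.rm = TRUE) else NA_real_,
      sd_duration = if ("median_duration" %in% names(cells))
        sd(.data$median_duration, na.rm = TRUE) else NA_real_,
      median_within_sd_landing = median(.data$within_sd_saccade_landing,
                                        na.rm = TRUE),
      median_within_sd_launch = median(.data$within_sd_saccade_launch,
                                       na.rm = TRUE),
      n_participants = dplyr::n(), .groups = "drop")
  n_speeds <- dplyr::n_distinct(cells$speed)
  correl <- list(
    r_landing_speed = if (n_speeds >= 2)
      pearson_r(cells$median_th_saccade_landing, cells$speed) else NA_real_,
    r_launch_speed = if (n_speeds >= 2)
      pearson_r(cells$median_th_saccade_launch, cells$speed) else NA_real_,
    r_within_sd_landing_speed = if (n_speeds >= 2)
      pearson_r(cells$within_sd_saccade_landing, cells$speed) else NA_real_,
    r_within_sd_launch_speed = if (n_speeds >= 2)
      pearson_r(cells$within_sd_saccade_launch, cells$speed) else NA_real_)
  structure(list(cells = cells, by_speed = summ, correlations = correl),
            class = "gw_exp1_summary")
}

#' @export
print.gw_exp1_summary <- function(x, ...) {
  cat("<gw_exp1_summary>\n")
  print(x$by_speed)
  cat(sprintf("Pearson r (median landing TH vs speed): %.3f\n",
              x$correlations$r_landing_speed))
  cat(sprintf("Pearson r (median launch TH vs speed):  %.3f\n",
              x$correlations$r_launch_speed))
  invisible(x)
}
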