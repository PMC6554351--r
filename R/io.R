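# canonical precision: timestamps at 1e-4 s, all other numeric columns at
# 1e-6, so that write -> read -> write reproduces files byte for byte
round_times <- function(df) {
  time_cols <- intersect(c("t", "launch_t", "landing_t", "t_start", "t_end",
                           "appear_t", "remove_t", "event_t"), names(df))
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) next
    df[[col]] <- round(df[[col]], if (col %in% time_cols) 4 else 6)
  }
  df
}

write_table <- function(df, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  df <- round_times(as.data.frame(df))
  if (format == "csv") {
    readr::write_csv(df, path)
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(df, con, verbose = FALSE, digits = NA)
  }
  invisible(path)
}

read_table <- function(path, required, what,
                       format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  df <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("%s file %s lacks column(s): %s", what, path,
                  paste(missing_cols, collapse = ", ")))
  }
  if ("t" %in% names(df) && is.unsorted(df$t)) {
    abort(sprintf("%s file %s: timestamps not sorted", what, path))
  }
  df
}

#' Read and write the pipeline's tabular logs
#'
#' Canonical interchange is CSV with a header; JSON-lines (`.jsonl`) is
#' accepted as an alternate dialect. Times are seconds from trial start
#' (serialized at 1e-4 s precision, making round-trips exact), screen
#' coordinates pixels, ground coordinates metres.
#'
#' @param x Tibble to write.
#' @param path File path (`.csv` or `.jsonl`).
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return Readers return validated tibbles; writers return `path`
#'   invisibly.
#' @name gaze_io
NULL

#' @rdname gaze_io
#' @export
write_telemetry <- function(x, path, format = "auto")
  write_table(x, path, format)

#' @rdname gaze_io
#' @export
read_telemetry <- function(path, format = "auto")
  read_table(path, c("t", "x", "y", "heading", "speed"), "telemetry", format)

#' @rdname gaze_io
#' @export
write_gaze <- function(x, path, format = "auto") write_table(x, path, format)

#' @rdname gaze_io
#' @export
read_gaze <- function(path, format = "auto")
  read_table(path, c("t", "px", "py", "confidence"), "gaze", format)

#' @rdname gaze_io
#' @export
write_waypoints <- function(x, path, format = "auto") {
  out <- write_table(x, path, format)
  invisible(out)
}

#' @rdname gaze_io
#' @export
read_waypoints <- function(path, format = "auto") {
  df <- read_table(path, c("turn", "slot", "status", "x", "y", "arclength",
                           "appear_t"), "waypoint", format)
  df
}

#' @rdname gaze_io
#' @export
write_saccades <- function(x, path, format = "auto")
  write_table(x, path, format)

#' @rdname gaze_io
#' @export
read_saccades <- function(path, format = "auto")
  read_table(path, c("launch_t", "launch_px", "launch_py", "landing_t",
                     "landing_px", "landing_py"), "saccade", format)

#' @rdname gaze_io
#' @export
write_segments <- function(x, path, format = "auto")
  write_table(x, path, format)

#' Read a run manifest
#'
#' A manifest maps trials to participants and conditions and points at the
#' per-trial log files. Columns: `participant`, `trial`, `condition`,
#' `telemetry`, `gaze` and optionally `waypoints`, `seed`. Referenced
#' files must exist (paths resolved relative to the manifest).
#'
#' @param path Manifest CSV path.
#' @return Validated manifest tibble with absolute paths.
#' @export
read_manifest <- function(path) {
  m <- read_table(path, c("participant", "trial", "condition",
                          "telemetry", "gaze"), "manifest")
  if (anyDuplicated(paste(m$participant, m$trial))) {
    abort("manifest has duplicated participant/trial ids")
  }
  base <- dirname(normalizePath(path))
  for (col in intersect(c("telemetry", "gaze", "waypoints"), names(m))) {
    p <- m[[col]]
    abs <- ifelse(grepl("^/", p), p, file.path(base, p))
    bad <- !file.exists(abs)
    if (any(bad)) {
      abort(sprintf("manifest references missing file(s): %s",
                    paste(abs[bad], collapse = ", ")))
    }
    m[[col]] <- abs
  }
  m
}

#' Read a YAML run configuration
#'
#' Recognized keys (all optional, with the experiment's defaults):
#' `nominal_speed_kmh`, `interval_s`, `gap_fraction`, `fade_in_s`,
#' `radius_m`, `n_turns`, `seed`.
#'
#' @param path YAML file path.
#' @return Named list of configuration values merged over defaults.
#' @export
read_run_config <- function(path) {
  defaults <- list(nominal_speed_kmh = 47, interval_s = 0.75,
                   gap_fraction = 0.25, fade_in_s = 0.25, radius_m = 50,
                   n_turns = 10, seed = 1L)
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  utils::modifyList(defaults, cfg[intersect(names(cfg), names(defaults))])
}

#' Write a statistical test report as JSON
#'
#' @param tests Named list of `gw_htest` objects.
#' @param path Output JSON path.
#' @param inputs_digest Optional provenance string.
#' @return `path`, invisibly.
#' @export
write_test_report <- function(tests, path, inputs_digest = NA_character_) {
  rows <- purrr::imap(tests, function(tst, nm) {
    list(test_name = nm, inputs_digest = inputs_digest,
         statistic = tst$statistic, p = tst$p_value, d = tst$effect_size,
         n = tst$n, sidedness = tst$sidedness)
  })
  jsonlite::write_json(unname(rows), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
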