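#' Index breath-level asynchrony records into a windowed count series
#'
#' Groups respiratory cycles into consecutive half-open windows
#' `[origin + k*T, origin + (k+1)*T)` of length `T = window_minutes` and
#' counts asynchrony events in each. In mode `"events"` every set flag
#' counts (a breath with two asynchrony types contributes 2); in mode
#' `"breaths"` each breath with at least one flag contributes 1. A
#' trailing window not fully covered by the record is dropped so the
#' Poisson exposure per window stays homogeneous.
#'
#' @param breaths Data frame with a `timestamp` column (POSIXct, or
#'   numeric minutes) and 0/1 flag columns; extra columns are ignored.
#' @param window_minutes Window length T in minutes (> 0).
#' @param counting_mode `"events"` (default) or `"breaths"`.
#' @param origin Series origin. Default: the first breath's timestamp
#'   truncated to the whole minute.
#' @param end End of the covered span. Default: the last breath's
#'   timestamp, so the window containing it is treated as partial and
#'   dropped. Pass the true end of recording to keep it.
#' @param flag_cols Names of the asynchrony flag columns.
#' @return Tibble with `window` (1-based), `window_start`, `count` and
#'   `n_breaths`; empty input gives a zero-row tibble.
#' @examples
#' b <- tibble::tibble(timestamp = c(1, 6, 7), iee = 1, double_cycling = 0,
#'                     short_cycling = 0, prolonged_cycling = 0)
#' index_events(b, window_minutes = 5, end = 11)
#' @export
index_events <- function(breaths, window_minutes = 15,
                         counting_mode = c("events", "breaths"),
                         origin = NULL, end = NULL,
                         flag_cols = c("iee", "double_cycling",
                                       "short_cycling", "prolonged_cycling")) {
  counting_mode <- match.arg(counting_mode)
  if (!is.numeric(window_minutes) || length(window_minutes) != 1 || window_minutes <= 0) {
    stop("`window_minutes` must be a single positive number", call. = FALSE)
  }
  empty <- tibble::tibble(
    window = integer(), window_start = numeric(),
    count = integer(), n_breaths = integer()
  )
  if (is.null(breaths) || nrow(breaths) == 0) return(empty)
  if (!"timestamp" %in% names(breaths)) stop("`breaths` needs a `timestamp` column", call. = FALSE)

  tmin <- to_minutes(breaths$timestamp)
  if (is.unsorted(tmin)) {
    warning("breath timestamps are not sorted; sorting internally", call. = FALSE)
    o <- order(tmin)
    breaths <- breaths[o, ]
    tmin <- tmin[o]
  }
  flag_cols <- intersect(flag_cols, names(breaths))
  flags <- as.matrix(breaths[flag_cols])
  if (length(flag_cols) == 0) flags <- matrix(0, nrow(breaths), 0)

  origin_min <- if (is.null(origin)) floor(tmin[1]) else to_minutes(origin)
  end_min <- if (is.null(end)) tmin[length(tmin)] else to_minutes(end)
  n_win <- floor((end_min - origin_min) / window_minutes)
  if (n_win < 1) return(empty)

  w <- floor((tmin - origin_min) / window_minutes) + 1
  keep <- w >= 1 & w <= n_win
  w <- factor(w[keep], levels = seq_len(n_win))
  per_breath <- if (ncol(flags) == 0) {
    rep(0L, sum(keep))
  } else if (counting_mode == "events") {
    as.integer(rowSums(flags[keep, , drop = FALSE]))
  } else {
    as.integer(rowSums(flags[keep, , drop = FALSE]) > 0)
  }
  tibble::tibble(
    window = seq_len(n_win),
    window_start = origin_min + (seq_len(n_win) - 1) * window_minutes,
    count = as.integer(tapply(per_breath, w, sum, default = 0L)),
    n_breaths = as.integer(table(w))
  )
}

# timestamps as minutes on a common numeric axis
to_minutes <- function(ts) {
  if (inherits(ts, "POSIXt")) as.numeric(ts) / 60 else as.numeric(ts)
}

#' Align raw cardiovascular samples to count windows
#'
#' Averages heart-rate and SpO2 samples within each half-open window.
#' Windows without any sample are returned with `NA` (missing, never 0).
#'
#' @param raw Data frame with columns `time` (POSIXct or numeric
#'   minutes), `hr`, `spo2`.
#' @param window_minutes Window length T in minutes.
#' @param origin Window origin; default the first sample's time
#'   truncated to the minute.
#' @param n_windows Number of windows to produce; default covers all
#'   samples.
#' @return Tibble with `window`, `hr`, `spo2`, `n_samples`.
#' @export
resample_cardio <- function(raw, window_minutes = 15, origin = NULL,
                            n_windows = NULL) {
  stopifnot(all(c("time", "hr", "spo2") %in% names(raw)))
  if (window_minutes <= 0) stop("`window_minutes` must be positive", call. = FALSE)
  tmin <- to_minutes(raw$time)
  origin_min <- if (is.null(origin)) floor(min(tmin)) else to_minutes(origin)
  w <- floor((tmin - origin_min) / window_minutes) + 1
  if (is.null(n_windows)) n_windows <- max(w)
  keep <- w >= 1 & w <= n_windows
  wf <- factor(w[keep], levels = seq_len(n_windows))
  tibble::tibble(
    window = seq_len(n_windows),
    hr = as.numeric(tapply(raw$hr[keep], wf, mean)),
    spo2 = as.numeric(tapply(raw$spo2[keep], wf, mean)),
    n_samples = as.integer(table(wf))
  )
}

#' Read / write breath records and count series CSV files
#'
#' Plain CSV dialects: breath records carry `timestamp` (ISO-8601) plus
#' the four 0/1 flag columns; count series carry `window_start`,
#' `count`, `n_breaths` and optionally `true_state` / `patient_id`.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return The read functions return tibbles; writers return `path`
#'   invisibly.
#' @export
write_breaths_csv <- function(x, path) {
  cols <- intersect(
    c("timestamp", "iee", "double_cycling", "short_cycling", "prolonged_cycling"),
    names(x)
  )
  readr::write_csv(x[cols], path)
  invisible(path)
}

#' @rdname write_breaths_csv
#' @export
read_breaths_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(timestamp = readr::col_datetime()))
}

#' @rdname write_breaths_csv
#' @export
write_count_series_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_breaths_csv
#' @export
read_count_series_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
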