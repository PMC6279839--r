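#' Cardiovascular episode thresholds
#'
#' Clinical cut-offs defining episodes: bradycardia HR < 60 bpm,
#' tachycardia HR > 100 bpm, hypoxemia SpO2 < 90%.
#'
#' @param bradycardia,tachycardia Heart-rate bounds in bpm.
#' @param hypoxemia SpO2 bound in %.
#' @return Named list of thresholds.
#' @export
episode_thresholds <- function(bradycardia = 60, tachycardia = 100,
                               hypoxemia = 90) {
  if (bradycardia >= tachycardia) {
    stop("the bradycardia bound must be below the tachycardia bound", call. = FALSE)
  }
  list(bradycardia = bradycardia, tachycardia = tachycardia, hypoxemia = hypoxemia)
}

#' Detect cardiovascular episodes per window
#'
#' For each window, flags whether any within-window sample crosses each
#' threshold and computes the fraction of window time spent past it,
#' treating samples as equally spaced. Windows whose samples are all
#' missing propagate `NA` rather than 0.
#'
#' @param cardio Data frame with columns `window`, `hr`, `spo2`; one or
#'   more sample rows per window (e.g. from [simulate_cardio()] or one
#'   row per window from [resample_cardio()]).
#' @param thresholds From [episode_thresholds()].
#' @return Long tibble with `window`, `type` (bradycardia /
#'   tachycardia / hypoxemia), `episode` (logical) and `time_pct`
#'   (percent of window time in episode).
#' @export
detect_episodes <- function(cardio, thresholds = episode_thresholds()) {
  stopifnot(all(c("window", "hr", "spo2") %in% names(cardio)))
  any_na <- function(hit) if (all(is.na(hit))) NA else any(hit, na.rm = TRUE)
  pct_na <- function(hit) if (all(is.na(hit))) NA_real_ else 100 * mean(hit, na.rm = TRUE)
  wide <- cardio |>
    dplyr::group_by(window = .data$window) |>
    dplyr::summarise(
      episode_bradycardia = any_na(.data$hr < thresholds$bradycardia),
      time_pct_bradycardia = pct_na(.data$hr < thresholds$bradycardia),
      episode_tachycardia = any_na(.data$hr > thresholds$tachycardia),
      time_pct_tachycardia = pct_na(.data$hr > thresholds$tachycardia),
      episode_hypoxemia = any_na(.data$spo2 < thresholds$hypoxemia),
      time_pct_hypoxemia = pct_na(.data$spo2 < thresholds$hypoxemia),
      .groups = "drop"
    )
  wide |>
    tidyr::pivot_longer(-"window",
      names_to = c(".value", "type"),
      names_pattern = "(episode|time_pct)_(.*)"
    ) |>
    dplyr::arrange(.data$window, .data$type)
}

#' State-matched cardiovascular episode statistics
#'
#' Matches each decoded state's windows with the corresponding
#' cardiovascular windows and summarises, per state and episode type,
#' the percentage of windows with at least one episode and the mean
#' (SD) percent of window time in episode — a Table-2-style
#' descriptive summary (no significance testing).
#'
#' @param states Integer decoded state per window (e.g. a Viterbi
#'   path), aligned with `episodes$window`.
#' @param episodes Output of [detect_episodes()].
#' @param K Number of states; defaults to `max(states)`.
#' @return Tibble with `state`, `type`, `n_windows`, `pct_episode`,
#'   `time_pct_mean`, `time_pct_sd`. States with no (non-missing)
#'   windows yield `NA` statistics, never 0.
#' @export
state_matched_stats <- function(states, episodes, K = max(states)) {
  states <- as.integer(states)
  n_win <- length(states)
  if (!all(episodes$window %in% seq_len(n_win))) {
    stop("`episodes` windows must align with the decoded state sequence", call. = FALSE)
  }
  map <- tibble::tibble(window = seq_len(n_win), state = states)
  episodes |>
    dplyr::inner_join(map, by = "window") |>
    dplyr::filter(!is.na(.data$episode)) |>
    dplyr::group_by(state = .data$state, type = .data$type) |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      pct_episode = 100 * mean(.data$episode),
      time_pct_mean = mean(.data$time_pct),
      time_pct_sd = sd(.data$time_pct),
      .groups = "drop"
    ) |>
    tidyr::complete(
      state = seq_len(K),
      type = c("bradycardia", "tachycardia", "hypoxemia"),
      fill = list(n_windows = 0L)
    ) |>
    dplyr::mutate(n_windows = tidyr::replace_na(.data$n_windows, 0L)) |>
    dplyr::arrange(.data$state, .data$type)
}
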