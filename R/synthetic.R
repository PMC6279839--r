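#' Build a persistent transition matrix with a prescribed stationary law
#'
#' Constructs a tridiagonal (birth-death) row-stochastic matrix whose
#' stationary distribution equals `stationary` and whose diagonal entries
#' are all at least `persistence`. Off-diagonal mass is placed only on
#' neighbouring states, reflecting the empirical behaviour of asynchrony
#' risk states, where most switches are to adjacent risk levels. The
#' up/down rates satisfy detailed balance
#' \eqn{\pi_i A_{i,i+1} = \pi_{i+1} A_{i+1,i}}, which makes `stationary`
#' the exact stationary law by construction; they are then scaled so the
#' least persistent row has diagonal exactly `persistence`.
#'
#' @param stationary Target stationary distribution (entries > 0, sums to 1).
#' @param persistence Lower bound for the diagonal, in (0, 1).
#' @return A K x K transition matrix.
#' @examples
#' make_persistent_matrix(c(0.5, 0.5), 0.9)
#' A <- make_persistent_matrix(c(0.52, 0.28, 0.14, 0.06), 0.85)
#' stationary_distribution(A)
#' @export
make_persistent_matrix <- function(stationary, persistence = 0.85) {
  p <- as.numeric(stationary)
  K <- length(p)
  if (any(!is.finite(p)) || any(p <= 0) || abs(sum(p) - 1) > 1e-8) {
    stop("`stationary` must have strictly positive entries summing to 1", call. = FALSE)
  }
  if (!is.finite(persistence) || persistence <= 0 || persistence >= 1) {
    stop("`persistence` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (K == 1) return(matrix(1, 1, 1))

  # base rates: up_i = pi_{i+1}, down_{i+1} = pi_i satisfy detailed balance
  A <- matrix(0, K, K)
  for (i in seq_len(K - 1)) {
    A[i, i + 1] <- p[i + 1]
    A[i + 1, i] <- p[i]
  }
  off <- rowSums(A)
  scale <- (1 - persistence) / max(off)
  if (!is.finite(scale) || scale <= 0) {
    stop("requested persistence is incompatible with the stationary distribution", call. = FALSE)
  }
  A <- A * scale
  diag(A) <- 1 - rowSums(A)
  A
}

#' Simulate a latent risk-state sequence
#'
#' Draws a Markov chain of length `n_windows` from the initial
#' distribution and transition matrix in `params`.
#'
#' @param params An [hmm_params] object.
#' @param n_windows Number of windows to simulate (>= 1).
#' @param seed Optional integer seed; the global RNG state is untouched.
#' @return Integer vector of states in `1:K`.
#' @export
simulate_states <- function(params, n_windows, seed = NULL) {
  stopifnot(inherits(params, "hmm_params"))
  if (!is.numeric(n_windows) || n_windows < 1) stop("`n_windows` must be >= 1", call. = FALSE)
  local_seed(seed)
  n <- as.integer(n_windows)
  K <- params$K
  s <- integer(n)
  s[1] <- sample.int(K, 1, prob = params$pi)
  for (t in seq_len(n - 1L)) {
    s[t + 1L] <- sample.int(K, 1, prob = params$A[s[t], ])
  }
  s
}

#' Simulate a windowed count series given a state sequence
#'
#' Window counts are independent Poisson draws with mean
#' `lambda[state]`; the exposure column `n_breaths` records the number
#' of respiratory cycles per window (constant by default).
#'
#' @inheritParams simulate_states
#' @param states Integer state sequence in `1:K`.
#' @param exposure_rate Mean breaths per window; the default 330
#'   corresponds to roughly 22 breaths/min over a 15-minute window.
#' @param patient_id Identifier stored in the output.
#' @return A tibble with columns `patient_id`, `window`, `true_state`,
#'   `count`, `n_breaths`.
#' @export
simulate_counts <- function(params, states, exposure_rate = 330, seed = NULL,
                            patient_id = "sim") {
  stopifnot(inherits(params, "hmm_params"))
  states <- as.integer(states)
  if (any(states < 1L | states > params$K)) {
    stop("all states must lie in 1..K", call. = FALSE)
  }
  local_seed(seed)
  x <- rpois(length(states), params$lambda[states])
  tibble::tibble(
    patient_id = patient_id,
    window = seq_along(states),
    true_state = states,
    count = x,
    n_breaths = as.integer(round(exposure_rate))
  )
}

#' Simulate a cohort of count sequences from one ground-truth model
#'
#' Convenience wrapper drawing `n_patients` independent state/count
#' sequences from the same parameters.
#'
#' @inheritParams simulate_counts
#' @param n_patients Number of sequences.
#' @param n_windows Windows per sequence.
#' @return A tibble stacking [simulate_counts()] output, with
#'   `patient_id` `"p01"`, `"p02"`, ...
#' @export
simulate_cohort <- function(params, n_patients, n_windows, exposure_rate = 330,
                            seed = NULL) {
  local_seed(seed)
  purrr::map_dfr(seq_len(n_patients), function(i) {
    s <- simulate_states(params, n_windows)
    simulate_counts(params, s,
      exposure_rate = exposure_rate,
      patient_id = sprintf("p%02d", i)
    )
  })
}

#' Simulate breath-level asynchrony records
#'
#' Generates timestamped respiratory cycles spanning
#' `length(states) * window_minutes` minutes. Breaths arrive as a
#' Poisson number per window, uniformly placed within the window; each
#' breath carries independent per-type asynchrony flags with the
#' probabilities of the state active in its window. The `window` and
#' `state` bookkeeping columns let round-trip tests compare indexed
#' counts against the generator's own tally; they are ignored by
#' [index_events()].
#'
#' @param states Integer state sequence.
#' @param window_minutes Window length T in minutes.
#' @param breath_rate Breaths per minute (default 22).
#' @param event_rates K x 4 matrix of per-breath flag probabilities,
#'   columns `iee`, `double_cycling`, `short_cycling`,
#'   `prolonged_cycling`; row sums must be <= 1.
#' @param origin Start time (POSIXct) of the record.
#' @param seed Optional integer seed.
#' @return Tibble with `timestamp`, the four 0/1 flag columns, `window`
#'   and `state`.
#' @export
simulate_breaths <- function(states, window_minutes = 15, breath_rate = 22,
                             event_rates,
                             origin = as.POSIXct("2000-01-01 00:00:00", tz = "UTC"),
                             seed = NULL) {
  states <- as.integer(states)
  event_rates <- as.matrix(event_rates)
  types <- c("iee", "double_cycling", "short_cycling", "prolonged_cycling")
  if (ncol(event_rates) != length(types)) {
    stop("`event_rates` must have one column per asynchrony type (", length(types), ")", call. = FALSE)
  }
  if (any(event_rates < 0) || any(event_rates > 1) || any(rowSums(event_rates) > 1 + 1e-12)) {
    stop("`event_rates` must be probabilities with row sums <= 1", call. = FALSE)
  }
  if (max(states) > nrow(event_rates)) stop("state index exceeds rows of `event_rates`", call. = FALSE)
  local_seed(seed)
  colnames(event_rates) <- types

  per_window <- purrr::map_dfr(seq_along(states), function(w) {
    nb <- rpois(1, breath_rate * window_minutes)
    if (nb == 0) return(NULL)
    offset_min <- sort(runif(nb, 0, window_minutes))
    flags <- vapply(
      types,
      function(ty) rbinom(nb, 1L, event_rates[states[w], ty]),
      integer(nb)
    )
    # vapply drops to a vector when nb == 1
    flags <- matrix(flags, nrow = nb, dimnames = list(NULL, types))
    dplyr::bind_cols(
      tibble::tibble(
        timestamp = origin + 60 * ((w - 1) * window_minutes + offset_min),
        window = w,
        state = states[w]
      ),
      tibble::as_tibble(flags)
    )
  })
  per_window[, c("timestamp", types, "window", "state")]
}

#' Per-state Gaussian model for cardiovascular series
#'
#' Default heart-rate and oxygen-saturation model used by
#' [simulate_cardio()]: HR is state-independent (mean 85 bpm, SD 12),
#' while the SpO2 mean decreases with risk state so that hypoxemia
#' episodes (SpO2 < 90%) become markedly more frequent in the
#' highest-risk state.
#'
#' @param K Number of states.
#' @return Tibble with columns `state`, `hr_mean`, `hr_sd`, `spo2_mean`,
#'   `spo2_sd`.
#' @export
default_cardio_model <- function(K = 4) {
  spo2 <- c(96.5, 96, 95.5, 93)
  tibble::tibble(
    state = seq_len(K),
    hr_mean = 85,
    hr_sd = 12,
    spo2_mean = if (K == 4) spo2 else seq(96.5, 93, length.out = K),
    spo2_sd = 2.5
  )
}

#' Simulate state-coupled cardiovascular samples
#'
#' Draws `samples_per_window` heart-rate and SpO2 samples per window
#' from state-conditional Gaussians; SpO2 is clamped to (0, 100].
#'
#' @param states Integer state sequence.
#' @param cardio_model Per-state means/SDs as from [default_cardio_model()].
#' @param samples_per_window Samples per window (equally spaced in time).
#' @param seed Optional integer seed.
#' @return Tibble with `window`, `state`, `sample`, `hr`, `spo2`.
#' @export
simulate_cardio <- function(states, cardio_model = default_cardio_model(max(states)),
                            samples_per_window = 15, seed = NULL) {
  states <- as.integer(states)
  stopifnot(all(c("state", "hr_mean", "hr_sd", "spo2_mean", "spo2_sd") %in% names(cardio_model)))
  local_seed(seed)
  m <- cardio_model[match(states, cardio_model$state), ]
  n <- length(states) * samples_per_window
  rep_idx <- rep(seq_along(states), each = samples_per_window)
  tibble::tibble(
    window = rep_idx,
    state = states[rep_idx],
    sample = rep(seq_len(samples_per_window), times = length(states)),
    hr = rnorm(n, m$hr_mean[rep_idx], m$hr_sd[rep_idx]),
    spo2 = pmin(100, pmax(1e-6, rnorm(n, m$spo2_mean[rep_idx], m$spo2_sd[rep_idx])))
  )
}
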