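#' One-step-ahead forecast of the next window's asynchrony count
#'
#' Filters the observed counts up to the last window (forward pass),
#' propagates the filtered state distribution one step through the
#' transition matrix, and summarises the resulting Poisson-mixture
#' predictive distribution: next-state probabilities, the expected
#' count, and an equal-tailed predictive count interval from the exact
#' mixture CDF.
#'
#' @inheritParams forward_backward
#' @param level Coverage of the predictive interval, default 0.95.
#' @return Object of class `hmm_forecast`: list with
#'   `next_state_probs`, `expected_count`, `interval` (`c(lower,
#'   upper)`), `level`.
#' @export
forecast_one_step <- function(params, x, level = 0.95) {
  stopifnot(inherits(params, "hmm_params"))
  x <- as_count_sequences(x)[[1]]
  fb <- forward_backward(params, x)
  p_next <- drop(fb$filtered[length(x), , drop = FALSE] %*% params$A)
  int <- mixture_interval(matrix(p_next, nrow = 1), params$lambda, level)
  structure(
    list(
      next_state_probs = p_next,
      expected_count = sum(p_next * params$lambda),
      interval = c(lower = int$lower, upper = int$upper),
      level = level
    ),
    class = "hmm_forecast"
  )
}

#' @export
print.hmm_forecast <- function(x, ...) {
  cat("One-step-ahead forecast\n")
  cat("next-state probabilities:", format(round(x$next_state_probs, 3)), "\n")
  cat(sprintf("expected count: %.2f; %g%% predictive interval [%d, %d]\n",
              x$expected_count, 100 * x$level, x$interval[1], x$interval[2]))
  invisible(x)
}

#' Rolling one-step-ahead forecasts along a series
#'
#' For every window `t >= 2`, the forecast of window `t` made from
#' windows `1..t-1` via filtering with frozen parameters. This is the
#' prediction stream scored in cross-validation.
#'
#' @inheritParams forecast_one_step
#' @param level Optional; if non-`NULL`, equal-tailed predictive count
#'   intervals are added.
#' @return Tibble with `window` (2..n), `actual`, `expected` and, when
#'   `level` is given, `lower`/`upper`.
#' @export
forecast_series <- function(params, x, level = NULL) {
  stopifnot(inherits(params, "hmm_params"))
  x <- as_count_sequences(x)[[1]]
  n <- length(x)
  if (n < 2) {
    return(tibble::tibble(window = integer(), actual = numeric(), expected = numeric()))
  }
  fb <- forward_backward(params, x)
  P <- fb$filtered[-n, , drop = FALSE] %*% params$A
  out <- tibble::tibble(
    window = 2:n,
    actual = x[-1],
    expected = drop(P %*% params$lambda)
  )
  if (!is.null(level)) {
    int <- mixture_interval(P, params$lambda, level)
    out$lower <- int$lower
    out$upper <- int$upper
  }
  out
}

# equal-tailed count quantiles of Poisson mixtures; W is a (rows x K)
# matrix of mixture weights
mixture_interval <- function(W, lambda, level) {
  a <- (1 - level) / 2
  kmax <- max(qpois(1 - 1e-12, max(lambda)), 10)
  grid <- 0:kmax
  cdf_k <- vapply(lambda, function(l) ppois(grid, l), numeric(length(grid)))
  Fm <- W %*% t(cdf_k) # rows: forecasts, cols: grid
  first_ge <- function(p) {
    idx <- max.col(Fm >= p, ties.method = "first")
    grid[idx]
  }
  list(lower = first_ge(a), upper = first_ge(1 - a))
}

#' Probability of being at or above a risk state next window
#'
#' Sums the forecast next-state probabilities over states
#' `threshold_state..K` — the quantity a smart alarm would monitor for
#' a patient entering a high-asynchrony regime.
#'
#' @param forecast An `hmm_forecast` (or a bare probability vector).
#' @param threshold_state State index in `1..K`.
#' @return Single probability.
#' @export
risk_state_probability <- function(forecast, threshold_state) {
  p <- if (inherits(forecast, "hmm_forecast")) forecast$next_state_probs else as.numeric(forecast)
  K <- length(p)
  if (!is.numeric(threshold_state) || length(threshold_state) != 1 ||
      threshold_state < 1 || threshold_state > K) {
    stop("`threshold_state` must lie in 1..K", call. = FALSE)
  }
  sum(p[seq(from = as.integer(threshold_state), to = K)])
}
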