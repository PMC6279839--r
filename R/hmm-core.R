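#' Poisson log probability mass
#'
#' Log pmf `log(exp(-lambda) lambda^x / x!)`, evaluated through the
#' log-gamma function so it is finite for any valid count and mean.
#'
#' @param x Non-negative integer count(s).
#' @param lambda Poisson mean(s), > 0.
#' @return Numeric vector of log-probabilities.
#' @export
poisson_logpmf <- function(x, lambda) {
  if (any(x < 0) || any(x != floor(x))) stop("`x` must be non-negative integers", call. = FALSE)
  if (any(lambda <= 0)) stop("`lambda` must be > 0", call. = FALSE)
  dpois(x, lambda, log = TRUE)
}

# n x K matrix of log emission probabilities
emission_logprob <- function(x, lambda) {
  vapply(lambda, function(l) dpois(x, l, log = TRUE), numeric(length(x)))
}

#' Forward-backward smoothing for a Poisson HMM
#'
#' Runs the scaled forward-backward recursions, returning the filtered
#' distributions `p(state_t | x_{1:t})`, the smoothed posteriors
#' `gamma = p(state_t | x_{1:n})`, the expected transition counts
#' `xi_sum` and the exact log-likelihood. Numerically stable for long
#' series (1e5+ windows) and large Poisson means.
#'
#' @param params An [hmm_params] object.
#' @param x Non-negative integer counts (vector, or data frame with a
#'   `count` column).
#' @return List with elements `filtered` (n x K), `gamma` (n x K, rows
#'   sum to 1), `xi_sum` (K x K) and `loglik`.
#' @export
forward_backward <- function(params, x) {
  stopifnot(inherits(params, "hmm_params"))
  x <- as_count_sequences(x)[[1]]
  logb <- emission_logprob(x, params$lambda)
  logb <- matrix(logb, nrow = length(x))
  hmm_forward_backward_cpp(logb, params$pi, params$A)
}

#' Most likely latent state path (Viterbi)
#'
#' Computes in log space the state sequence maximising the joint
#' probability of states and observed counts. Ties are broken towards
#' the lower state index.
#'
#' @inheritParams forward_backward
#' @return Integer vector of states in `1:K`.
#' @export
viterbi_path <- function(params, x) {
  stopifnot(inherits(params, "hmm_params"))
  x <- as_count_sequences(x)[[1]]
  logb <- matrix(emission_logprob(x, params$lambda), nrow = length(x))
  hmm_viterbi_cpp(logb, log(params$pi), log(params$A))
}

#' Decode a count series: posteriors, Viterbi path and time spent
#'
#' Bundles [forward_backward()] and [viterbi_path()] and adds `tspent`,
#' the per-state fraction of windows, both as Viterbi occupancy (the
#' headline convention) and as the mean smoothed posterior.
#'
#' @inheritParams forward_backward
#' @return List of class `hmm_decode` with `gamma`, `xi_sum`,
#'   `viterbi_path`, `loglik`, `tspent` (Viterbi occupancy) and
#'   `tspent_gamma`.
#' @export
decode_states <- function(params, x) {
  fb <- forward_backward(params, x)
  vp <- viterbi_path(params, x)
  structure(
    list(
      gamma = fb$gamma,
      xi_sum = fb$xi_sum,
      filtered = fb$filtered,
      viterbi_path = vp,
      loglik = fb$loglik,
      tspent = as.numeric(tabulate(vp, params$K)) / length(vp),
      tspent_gamma = colMeans(fb$gamma)
    ),
    class = "hmm_decode"
  )
}

#' @export
print.hmm_decode <- function(x, ...) {
  cat("HMM decoding of", length(x$viterbi_path), "windows\n")
  cat("log-likelihood:", format(x$loglik), "\n")
  cat("tspent (Viterbi):", format(round(x$tspent, 3)), "\n")
  invisible(x)
}

#' Equal-tailed Poisson count interval
#'
#' For each state mean, the equal-tailed interval on the count scale
#' from the exact Poisson quantile function: `lower` is the smallest
#' integer k with CDF(k) >= (1-level)/2 and `upper` the smallest k with
#' CDF(k) >= 1-(1-level)/2. No normal approximation is used. At the
#' default 95% level this is the convention under which a state with
#' mean 1 event/window has interval (0, 3).
#'
#' @param lambda Poisson mean(s), > 0.
#' @param level Coverage level in (0, 1), default 0.95.
#' @return Tibble with columns `lambda`, `lower`, `upper`.
#' @examples
#' credible_interval(c(1, 11, 38, 119))
#' @export
credible_interval <- function(lambda, level = 0.95) {
  if (any(lambda <= 0)) stop("`lambda` must be > 0", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must lie strictly inside (0, 1)", call. = FALSE)
  }
  a <- (1 - level) / 2
  tibble::tibble(
    lambda = as.numeric(lambda),
    lower = qpois(a, lambda),
    upper = qpois(1 - a, lambda)
  )
}
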