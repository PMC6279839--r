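#' Tidy a fitted Poisson HMM
#'
#' One row per state: the fitted Poisson mean, its equal-tailed count
#' interval, the initial probability and the time-spent fractions
#' (Viterbi occupancy and mean smoothed posterior) on the training
#' data — the layout of the per-state summary table clinicians read.
#'
#' @param x A `poisson_hmm` fit.
#' @param level Level for the count intervals.
#' @param ... Unused.
#' @return A tibble with columns `state`, `lambda`, `lower`, `upper`,
#'   `pi`, `tspent`, `tspent_gamma`.
#' @export
tidy.poisson_hmm <- function(x, level = 0.95, ...) {
  ci <- credible_interval(x$params$lambda, level)
  tibble::tibble(
    state = seq_len(x$K),
    lambda = x$params$lambda,
    lower = ci$lower,
    upper = ci$upper,
    pi = x$params$pi,
    tspent = x$tspent,
    tspent_gamma = x$tspent_gamma
  )
}

#' Glance at a fitted Poisson HMM
#'
#' @param x A `poisson_hmm` fit.
#' @param ... Unused.
#' @return One-row tibble with `K`, `n_seq`, `n_obs`, `loglik`, `df`,
#'   `AIC`, `BIC`, `n_iter` (iterations of the winning restart),
#'   `converged`.
#' @export
glance.poisson_hmm <- function(x, ...) {
  df <- (x$K - 1) + x$K * (x$K - 1) + x$K
  n_iter <- if (is.na(x$best_restart)) {
    NA_integer_
  } else {
    sum(x$trace$restart == x$best_restart)
  }
  tibble::tibble(
    K = x$K, n_seq = x$n_seq, n_obs = x$n_obs,
    loglik = x$loglik, df = df,
    AIC = -2 * x$loglik + 2 * df,
    BIC = -2 * x$loglik + log(x$n_obs) * df,
    n_iter = n_iter,
    converged = x$converged
  )
}

#' Augment training data with decoded states
#'
#' @param x A `poisson_hmm` fit.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `window`, `count`, the Viterbi
#'   state `.state` and its smoothed posterior probability
#'   `.state_prob`.
#' @export
augment.poisson_hmm <- function(x, ...) {
  purrr::imap_dfr(x$data, function(counts, id) {
    d <- x$decode[[id]]
    tibble::tibble(
      patient_id = id,
      window = seq_along(counts),
      count = counts,
      .state = d$viterbi_path,
      .state_prob = d$gamma[cbind(seq_along(counts), d$viterbi_path)]
    )
  })
}

#' @export
tidy.hmm_cv <- function(x, ...) x$per_fold

#' @export
glance.hmm_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k, K = x$K,
    mean_rmse_hmm = x$summary$mean_rmse[x$summary$model == "hmm"],
    se_rmse_hmm = x$summary$se_rmse[x$summary$model == "hmm"],
    mean_rmse_base = x$summary$mean_rmse[x$summary$model == "base"],
    se_rmse_base = x$summary$se_rmse[x$summary$model == "base"]
  )
}
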