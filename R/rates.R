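#' Per-state asynchrony rates from counts and exposure
#'
#' Converts per-state expected counts into approximate asynchrony rates
#' (% of respiratory cycles). The per-state exposure (breaths per
#' window) is estimated with a log-link Poisson regression of
#' `n_breaths` on the decoded state, whose fitted values are the
#' per-state mean breath counts; the rate is then
#' `100 * lambda_j / exposure_j`. Equal-tailed 95% count intervals and
#' the Viterbi time-spent fractions complete a Table-1-style summary.
#'
#' @param series Data frame with `count` and `n_breaths` columns (one
#'   sequence).
#' @param params An [hmm_params] object (e.g. `fit$params`).
#' @param decode Optional [decode_states()] result; computed from
#'   `series` if missing.
#' @param level Level for the count intervals.
#' @return Tibble with one row per state: `state`, `lambda`, `lower`,
#'   `upper`, `exposure`, `rate_pct`, `tspent`. States never visited by
#'   the Viterbi path get `NA` exposure and rate.
#' @export
state_rates <- function(series, params, decode = NULL, level = 0.95) {
  stopifnot(inherits(params, "hmm_params"))
  if (!is.data.frame(series) || !"count" %in% names(series)) {
    stop("`series` must be a data frame with a `count` column", call. = FALSE)
  }
  if (!"n_breaths" %in% names(series) || any(is.na(series$n_breaths))) {
    stop("`series` must carry the exposure column `n_breaths` (breaths per window); ",
         "supply it to convert counts to rates", call. = FALSE)
  }
  if (any(series$n_breaths <= 0)) stop("all `n_breaths` must be > 0", call. = FALSE)
  if (is.null(decode)) decode <- decode_states(params, series$count)
  K <- params$K
  st <- factor(decode$viterbi_path, levels = seq_len(K))

  # log-link intercept model of breaths per window, evaluated per state
  exposure <- vapply(seq_len(K), function(j) {
    n_j <- series$n_breaths[st == j]
    if (length(n_j) == 0) return(NA_real_)
    exp(coef(glm(n_j ~ 1, family = poisson()))[[1]])
  }, numeric(1))

  ci <- credible_interval(params$lambda, level)
  tibble::tibble(
    state = seq_len(K),
    lambda = params$lambda,
    lower = ci$lower,
    upper = ci$upper,
    exposure = as.numeric(exposure),
    rate_pct = 100 * params$lambda / as.numeric(exposure),
    tspent = decode$tspent
  )
}
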