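#' Root mean square forecast error
#'
#' @param predictions,actual Equal-length numeric vectors.
#' @return `sqrt(mean((predictions - actual)^2))`.
#' @export
rmse <- function(predictions, actual) {
  if (length(predictions) != length(actual)) {
    stop("`predictions` and `actual` must have equal length", call. = FALSE)
  }
  if (length(actual) == 0) stop("need at least one prediction", call. = FALSE)
  sqrt(mean((predictions - actual)^2))
}

#' Zero-count base model forecasts
#'
#' The benchmark forecaster predicts zero events for every window after
#' the first — zero being the single most likely outcome in these
#' heavily zero-inflated series.
#'
#' @param x Count sequence (vector or data frame with `count`).
#' @return Numeric vector of zeros, one per window `t >= 2`.
#' @export
base_model_forecast <- function(x) {
  if (is.data.frame(x)) x <- x$count
  rep(0, max(0L, length(x) - 1L))
}

#' k-fold cross-validated one-step-ahead forecast error
#'
#' Splits sequences (patients) into k folds with a seeded shuffle —
#' always by whole sequence, never within one, so no patient's windows
#' leak across folds. For each fold, a Poisson HMM is fitted on the
#' remaining folds and one-step-ahead forecasts are produced for every
#' window `t >= 2` of the held-out sequences by filtering with the
#' frozen parameters. The per-fold RMSE pools all held-out windows, and
#' the zero-count base model is scored on the identical index set.
#'
#' @param data Data frame with `patient_id` and `count` columns, or a
#'   list of count vectors.
#' @param k Number of folds (default 5).
#' @param K Number of HMM states (default 4).
#' @param n_restarts EM restarts per training fit.
#' @param seed Optional integer seed (fold shuffle + EM restarts).
#' @param tol,max_iter Passed to [fit_poisson_hmm()].
#' @return Object of class `hmm_cv`: list with `per_fold` (tibble:
#'   `fold`, `n_windows`, `rmse_hmm`, `rmse_base`), `summary` (means
#'   and standard errors `sd/sqrt(k)`), `fold_assignment` (tibble
#'   mapping sequence id to fold), `k`, `K`.
#' @export
kfold_cv <- function(data, k = 5, K = 4, n_restarts = 3, seed = NULL,
                     tol = 1e-6, max_iter = 500) {
  seqs <- as_count_sequences(data)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (length(seqs) < k) {
    stop("need at least as many sequences (patients) as folds", call. = FALSE)
  }
  local_seed(seed)
  ids <- names(seqs)
  shuffled <- sample(ids)
  fold_of <- setNames(rep(seq_len(k), length.out = length(ids)), shuffled)
  assignment <- tibble::tibble(patient_id = shuffled, fold = as.integer(fold_of))

  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    test_ids <- shuffled[fold_of == f]
    train <- seqs[setdiff(ids, test_ids)]
    fit <- fit_poisson_hmm(train, K = K, n_restarts = n_restarts,
                           tol = tol, max_iter = max_iter)
    fc <- purrr::map_dfr(seqs[test_ids], function(x) {
      forecast_series(fit$params, x)
    })
    tibble::tibble(
      fold = f,
      n_windows = nrow(fc),
      rmse_hmm = rmse(fc$expected, fc$actual),
      rmse_base = rmse(rep(0, nrow(fc)), fc$actual)
    )
  })

  structure(
    list(
      per_fold = per_fold,
      summary = tibble::tibble(
        model = c("hmm", "base"),
        mean_rmse = c(mean(per_fold$rmse_hmm), mean(per_fold$rmse_base)),
        se_rmse = c(sd(per_fold$rmse_hmm), sd(per_fold$rmse_base)) / sqrt(k)
      ),
      fold_assignment = assignment,
      k = k, K = K
    ),
    class = "hmm_cv"
  )
}

#' @export
print.hmm_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated one-step-ahead forecast error\n", x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s RMSE %.3f (SE %.3f)\n", s$model[i], s$mean_rmse[i], s$se_rmse[i]))
  }
  invisible(x)
}
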