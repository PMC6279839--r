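#' Fit a Poisson hidden Markov model by EM (Baum-Welch)
#'
#' Maximum-likelihood estimation of a K-state Poisson HMM from one or
#' several windowed count sequences. Each EM iteration runs the scaled
#' forward-backward recursions per sequence and pools the sufficient
#' statistics, so a cohort of patients contributes to a single shared
#' parameter set: the M-step sets
#' `lambda_j = sum_t gamma_t(j) x_t / sum_t gamma_t(j)`, transition rows
#' from normalised expected transition counts, and `pi` from the
#' first-window posteriors averaged over sequences. The fit is restarted
#' from several random initialisations and the restart with the highest
#' final log-likelihood is kept; states are relabelled so the fitted
#' means are increasing before return.
#'
#' Initialisation draws `lambda` from jittered quantiles of the observed
#' non-zero counts, uses a uniform `pi`, and a diagonal-heavy transition
#' matrix (0.8 on the diagonal). Numerical floors (`lambda >= 1e-6`,
#' transition entries `>= 1e-12` before row normalisation) guard
#' degenerate data such as all-zero series.
#'
#' @param data Numeric count vector, data frame with a `count` column
#'   (and optional `patient_id` grouping multiple sequences), or a list
#'   of count vectors.
#' @param K Number of latent states (default 4).
#' @param n_restarts Random restarts (default 10).
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Optional integer seed for the restarts.
#' @param method `"pooled"` (default) fits one model on all sequences
#'   jointly; `"average"` fits each sequence separately and averages the
#'   canonically ordered parameters, mirroring a per-patient-average
#'   summary of the transition structure.
#' @return Object of class `poisson_hmm`: a list with `params`
#'   ([hmm_params]), `loglik`, `trace` (tibble of per-restart,
#'   per-iteration log-likelihoods), `converged`, `best_restart`,
#'   `decode` (list of [decode_states()] results per sequence),
#'   `tspent`, `data`, `n_obs`, `n_seq`, `K`, `method`.
#' @examples
#' truth <- hmm_params(c(.5, .5), make_persistent_matrix(c(.5, .5), .9), c(2, 30))
#' y <- simulate_counts(truth, simulate_states(truth, 500, seed = 1), seed = 2)
#' fit <- fit_poisson_hmm(y, K = 2, n_restarts = 3, seed = 3)
#' tidy(fit)
#' @export
fit_poisson_hmm <- function(data, K = 4, n_restarts = 10, tol = 1e-6,
                            max_iter = 500, seed = NULL,
                            method = c("pooled", "average")) {
  method <- match.arg(method)
  seqs <- as_count_sequences(data)
  if (K < 1) stop("`K` must be >= 1", call. = FALSE)
  all_x <- unlist(seqs, use.names = FALSE)
  if (length(unique(all_x)) < K) {
    warning("fewer than K distinct count values observed; states may be redundant",
            call. = FALSE)
  }
  if (all(all_x == 0) && K > 1) {
    warning("all counts are zero; fitted means collapse to the numerical floor",
            call. = FALSE)
  }
  local_seed(seed)

  if (method == "average") {
    fits <- lapply(seqs, function(x) {
      em_run_restarts(list(x), K, n_restarts, tol, max_iter)
    })
    pars <- lapply(fits, function(f) canonicalize(f$params))
    params <- hmm_params(
      pi = Reduce(`+`, lapply(pars, `[[`, "pi")) / length(pars),
      A = Reduce(`+`, lapply(pars, `[[`, "A")) / length(pars),
      lambda = Reduce(`+`, lapply(pars, `[[`, "lambda")) / length(pars)
    )
    trace <- purrr::imap_dfr(fits, function(f, id) {
      dplyr::mutate(f$trace, patient_id = id, .before = 1)
    })
    best <- NA_integer_
    converged <- all(vapply(fits, `[[`, logical(1), "converged"))
  } else {
    run <- em_run_restarts(seqs, K, n_restarts, tol, max_iter)
    params <- canonicalize(run$params)
    trace <- run$trace
    best <- run$best_restart
    converged <- run$converged
  }

  decode <- lapply(seqs, function(x) decode_states(params, x))
  vp_all <- unlist(lapply(decode, `[[`, "viterbi_path"))
  loglik <- sum(vapply(decode, `[[`, numeric(1), "loglik"))

  structure(
    list(
      params = params, K = K, loglik = loglik, trace = trace,
      converged = converged, best_restart = best,
      decode = decode,
      tspent = tabulate(vp_all, K) / length(vp_all),
      tspent_gamma = colMeans(do.call(rbind, lapply(decode, `[[`, "gamma"))),
      data = seqs, n_obs = length(all_x), n_seq = length(seqs),
      method = method
    ),
    class = "poisson_hmm"
  )
}

# one full set of EM restarts on a list of sequences; best by final loglik
em_run_restarts <- function(seqs, K, n_restarts, tol, max_iter) {
  best <- NULL
  traces <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- em_init(seqs, K, spread = r > 1)
    run <- em_one(seqs, init, tol, max_iter)
    traces[[r]] <- tibble::tibble(
      restart = r, iteration = seq_along(run$ll_trace), loglik = run$ll_trace
    )
    if (is.null(best) || run$loglik > best$loglik) {
      best <- run
      best$restart <- r
    }
  }
  list(
    params = best$params, loglik = best$loglik,
    trace = dplyr::bind_rows(traces),
    best_restart = best$restart, converged = best$converged
  )
}

em_init <- function(seqs, K, spread = FALSE) {
  x <- unlist(seqs, use.names = FALSE)
  nz <- x[x > 0]
  # lambda from quantiles of the non-zero counts; after the first restart the
  # quantile positions themselves are randomised so the restarts explore
  # genuinely different basins (skewed count data otherwise pulls every
  # jittered init into the same merged-state optimum)
  probs <- if (spread) sort(runif(K, 0.02, 0.995)) else (seq_len(K) - 0.5) / K
  base <- if (length(nz) >= K) {
    quantile(nz, probs = probs, names = FALSE, type = 7)
  } else {
    seq(0.5, max(1, max(x)), length.out = K)
  }
  lambda <- pmax(base * exp(rnorm(K, 0, 0.3)), 1e-3)
  lambda <- sort(lambda + seq_len(K) * 1e-6) # keep distinct
  A <- matrix((1 - 0.8) / max(1, K - 1), K, K)
  diag(A) <- if (K == 1) 1 else 0.8
  list(pi = rep(1 / K, K), A = A, lambda = lambda)
}

em_one <- function(seqs, init, tol, max_iter) {
  K <- length(init$lambda)
  pi <- init$pi; A <- init$A; lambda <- init$lambda
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    num_l <- den_l <- numeric(K)
    Xi <- matrix(0, K, K)
    pi_acc <- numeric(K)
    ll <- 0
    for (x in seqs) {
      logb <- matrix(emission_logprob(x, lambda), nrow = length(x))
      fb <- hmm_forward_backward_cpp(logb, pi, A)
      num_l <- num_l + colSums(fb$gamma * x)
      den_l <- den_l + colSums(fb$gamma)
      Xi <- Xi + fb$xi_sum
      pi_acc <- pi_acc + fb$gamma[1, ]
      ll <- ll + fb$loglik
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    lambda <- pmax(num_l / pmax(den_l, 1e-300), 1e-6)
    if (K > 1) {
      Xi[Xi < 1e-12] <- 1e-12
      A <- Xi / rowSums(Xi)
    }
    pi <- pi_acc / length(seqs)
    pi <- pmax(pi, 1e-12); pi <- pi / sum(pi)
  }
  list(
    params = hmm_params(pi, A, lambda, reorder = FALSE),
    loglik = ll_trace[length(ll_trace)],
    ll_trace = ll_trace, converged = converged
  )
}

canonicalize <- function(params) {
  hmm_params(params$pi, params$A, params$lambda, reorder = TRUE)
}

#' @export
print.poisson_hmm <- function(x, digits = 3, ...) {
  cat("Poisson hidden Markov model fit (EM)\n")
  cat(sprintf("K = %d states, %d sequence(s), %d windows, logLik = %.2f\n",
              x$K, x$n_seq, x$n_obs, x$loglik))
  if (!x$converged) cat("warning: EM did not reach the convergence tolerance\n")
  print(x$params, digits = digits)
  cat("tspent (Viterbi):", format(round(x$tspent, 3)), "\n")
  invisible(x)
}
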