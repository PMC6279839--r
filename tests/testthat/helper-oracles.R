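# Independent oracles used against the package's recursions.

# Exhaustive enumeration over all K^n latent paths: exact log-likelihood by
# log-sum-exp and the exact joint-MAP (Viterbi) path.
enum_loglik_viterbi <- function(params, x) {
  n <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(params$K)), n)))
  lp <- apply(paths, 1, function(s) {
    v <- log(params$pi[s[1]]) + sum(dpois(x, params$lambda[s], log = TRUE))
    if (n > 1) v <- v + sum(log(params$A[cbind(s[-n], s[-1])]))
    v
  })
  m <- max(lp)
  list(
    loglik = m + log(sum(exp(lp - m))),
    viterbi = unname(paths[which.max(lp), ])
  )
}

# random valid parameter set with well-separated means (ties in the MAP path
# would make the enumeration argmax convention-dependent)
random_params <- function(K) {
  A <- matrix(rgamma(K * K, shape = 2), K)
  A <- A / rowSums(A)
  pi <- rgamma(K, shape = 2)
  hmm_params(pi / sum(pi), A, sort(runif(K, 0.5, 40)), reorder = FALSE)
}

# stationary distribution by power iteration (independent of eigen)
power_stationary <- function(A, iters = 10000) {
  v <- rep(1 / nrow(A), nrow(A))
  for (i in seq_len(iters)) v <- drop(v %*% A)
  v / sum(v)
}

table1_lambda <- c(1, 11, 38, 119)
table1_tspent <- c(0.52, 0.28, 0.14, 0.06)
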