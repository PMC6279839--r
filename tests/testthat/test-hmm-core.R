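test_that("Poisson log-pmf is exact and normalised", {
  expect_equal(poisson_logpmf(0, 1), -1)
  expect_equal(poisson_logpmf(2, 2), log(2) - 2)
  expect_equal(sum(exp(poisson_logpmf(0:500, 119))), 1, tolerance = 1e-12)
  expect_error(poisson_logpmf(-1, 1), "non-negative")
  expect_error(poisson_logpmf(2, 0), "lambda")
})

test_that("forward-backward matches exhaustive path enumeration", {
  # degenerate single state
  p1 <- hmm_params(1, matrix(1), 3.5)
  x <- c(0L, 2L, 7L, 1L)
  fb1 <- forward_backward(p1, x)
  expect_equal(fb1$loglik, sum(dpois(x, 3.5, log = TRUE)))
  expect_true(all(fb1$gamma == 1))

  # K = 2, n = 6 against the 2^6-path oracle
  withr::with_seed(101, {
    p2 <- random_params(2)
    x2 <- rpois(6, 8)
  })
  fb2 <- forward_backward(p2, x2)
  oracle <- enum_loglik_viterbi(p2, x2)
  expect_equal(fb2$loglik, oracle$loglik, tolerance = 1e-10)
  expect_equal(rowSums(fb2$gamma), rep(1, 6), tolerance = 1e-10)

  # randomized property: K <= 3, n <= 8
  withr::with_seed(202, {
    for (rep in 1:12) {
      K <- sample(1:3, 1)
      n <- sample(2:8, 1)
      p <- random_params(K)
      x <- rpois(n, sample(c(1, 5, 20), n, replace = TRUE))
      fb <- forward_backward(p, x)
      o <- enum_loglik_viterbi(p, x)
      expect_equal(fb$loglik, o$loglik, tolerance = 1e-10)
      expect_equal(viterbi_path(p, x), o$viterbi)
      expect_equal(rowSums(fb$gamma), rep(1, n), tolerance = 1e-10)
      expect_equal(sum(fb$xi_sum), n - 1, tolerance = 1e-8)
    }
  })
})

test_that("log-likelihood is invariant to state relabelling", {
  withr::with_seed(7, {
    p <- random_params(3)
    x <- rpois(50, 10)
  })
  perm <- c(3, 1, 2)
  pp <- hmm_params(p$pi[perm], p$A[perm, perm], p$lambda[perm], reorder = FALSE)
  expect_equal(forward_backward(p, x)$loglik, forward_backward(pp, x)$loglik,
               tolerance = 1e-12)
})

test_that("Viterbi decodes an obvious regime switch", {
  A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE)
  p <- hmm_params(c(0.5, 0.5), A, c(1, 100), reorder = FALSE)
  x <- c(0L, 1L, 0L, 95L, 110L)
  expect_equal(viterbi_path(p, x), c(1L, 1L, 1L, 2L, 2L))
  expect_equal(viterbi_path(p, x), enum_loglik_viterbi(p, x)$viterbi)
  # single state: constant path
  expect_equal(viterbi_path(hmm_params(1, matrix(1), 2), c(1L, 5L)), c(1L, 1L))
})

test_that("recursions stay finite on long series with large means", {
  p <- hmm_params(c(0.9, 0.1), matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE),
                  c(5, 1000), reorder = FALSE)
  withr::with_seed(3, {
    s <- simulate_states(p, 100000)
    x <- rpois(100000, p$lambda[s])
  })
  fb <- forward_backward(p, x)
  expect_true(is.finite(fb$loglik))
  expect_equal(rowSums(fb$gamma), rep(1, 100000), tolerance = 1e-10)
  expect_false(anyNA(viterbi_path(p, x)))
})

test_that("equal-tailed Poisson count intervals match the exact CDF", {
  ci <- credible_interval(c(1, 11, 38, 119))
  expect_equal(ci$lower, c(0, 5, 26, 98))
  expect_equal(ci$upper, c(3, 18, 51, 141))

  # definition check over a lambda grid by the exact-CDF oracle, and the
  # interval always contains floor(lambda)
  grid <- c(0.1, 0.5, 1, 2.7, 10, 38.4, 119, 250, 500)
  ci_g <- credible_interval(grid, 0.95)
  for (i in seq_along(grid)) {
    lo <- ci_g$lower[i]; hi <- ci_g$upper[i]; l <- grid[i]
    expect_true(ppois(hi, l) >= 0.975 && (hi == 0 || ppois(hi - 1, l) < 0.975))
    expect_true(ppois(lo, l) >= 0.025 && (lo == 0 || ppois(lo - 1, l) < 0.025))
    expect_true(lo <= floor(l) && floor(l) <= hi)
  }
  expect_error(credible_interval(0), "lambda")
  expect_error(credible_interval(1, level = 1), "level")
})
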