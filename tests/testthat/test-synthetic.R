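test_that("persistent matrix construction hits the requested stationary law", {
  expect_equal(make_persistent_matrix(1), matrix(1, 1, 1))
  expect_equal(
    make_persistent_matrix(c(0.5, 0.5), 0.9),
    matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  )

  A <- make_persistent_matrix(table1_tspent, 0.8)
  expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-12)
  expect_true(all(diag(A) >= 0.8 - 1e-12))
  expect_equal(power_stationary(A), table1_tspent, tolerance = 1e-8)
  # tridiagonal: no direct jumps between non-neighbouring states
  expect_equal(A[1, 3], 0)
  expect_equal(A[4, 1], 0)
  # detailed balance
  for (i in 1:3) {
    expect_equal(table1_tspent[i] * A[i, i + 1], table1_tspent[i + 1] * A[i + 1, i])
  }

  expect_error(make_persistent_matrix(c(0.7, 0.7), 0.9), "summing to 1")
  expect_error(make_persistent_matrix(c(0.5, 0.5), 1), "persistence")
  expect_error(make_persistent_matrix(c(0.5, 0.5), 0), "persistence")
})

test_that("random stationary targets are achieved across draws", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      K <- sample(2:6, 1)
      p <- rgamma(K, 1) + 0.05
      p <- p / sum(p)
      A <- make_persistent_matrix(p, runif(1, 0.5, 0.95))
      expect_equal(rowSums(A), rep(1, K), tolerance = 1e-12)
      expect_equal(power_stationary(A), p, tolerance = 1e-8)
    }
  })
})

test_that("state simulation follows the chain and is reproducible", {
  p1 <- hmm_params(1, matrix(1), 5)
  expect_equal(simulate_states(p1, 5, seed = 1), rep(1L, 5))

  # absorbing chain started in state 2 stays there
  pab <- hmm_params(c(0, 1), diag(2), c(1, 10), reorder = FALSE)
  expect_equal(simulate_states(pab, 10, seed = 1), rep(2L, 10))

  A <- make_persistent_matrix(table1_tspent, 0.85)
  params <- hmm_params(table1_tspent, A, table1_lambda)
  s1 <- simulate_states(params, 1000, seed = 7)
  s2 <- simulate_states(params, 1000, seed = 7)
  expect_identical(s1, s2)

  # empirical occupancy matches the stationary law within 3 SE
  s <- simulate_states(params, 100000, seed = 11)
  freq <- tabulate(s, 4) / length(s)
  # SE inflated by chain autocorrelation; persistence 0.85 gives an
  # effective-sample-size factor of roughly (1+d)/(1-d) with d ~ diag
  for (j in 1:4) {
    se <- sqrt(table1_tspent[j] * (1 - table1_tspent[j]) / length(s)) * sqrt(1.85 / 0.15)
    expect_lt(abs(freq[j] - table1_tspent[j]), 3 * se)
  }
})

test_that("count emission matches the Poisson mean-variance identity", {
  params <- hmm_params(c(0.5, 0.5), make_persistent_matrix(c(0.5, 0.5), 0.9), c(1e-9, 5),
                       reorder = FALSE)
  y0 <- simulate_counts(params, rep(1L, 200), seed = 1)
  expect_true(all(y0$count == 0)) # near-zero mean

  truth <- hmm_params(table1_tspent, make_persistent_matrix(table1_tspent, 0.85),
                      table1_lambda)
  s <- simulate_states(truth, 30000, seed = 5)
  y <- simulate_counts(truth, s, seed = 6)
  expect_identical(y$count, simulate_counts(truth, s, seed = 6)$count)
  expect_true(all(y$n_breaths == 330))

  # per-state conditional means recover the generating lambdas
  for (j in 1:4) {
    xs <- y$count[s == j]
    se <- sqrt(table1_lambda[j] / length(xs))
    expect_lt(abs(mean(xs) - table1_lambda[j]), 4 * se)
    expect_lt(abs(var(xs) / table1_lambda[j] - 1), 0.15)
  }

  # marginal long-run mean = sum_j pi_j lambda_j within 3 Monte-Carlo SE
  mu <- sum(table1_tspent * table1_lambda)
  se_mu <- sd(y$count) / sqrt(nrow(y)) * sqrt(1.85 / 0.15)
  expect_lt(abs(mean(y$count) - mu), 3 * se_mu)

  # positively skewed with mode at/near zero
  skew <- mean((y$count - mean(y$count))^3) / sd(y$count)^3
  expect_gt(skew, 0)
  # mode at/near zero: P(0) and P(1) are tied under a unit-mean lowest state
  expect_lte(as.integer(names(which.max(table(y$count)))), 1L)
})

test_that("breath generator produces flags at the configured per-state rates", {
  r0 <- matrix(0, 2, 4)
  b0 <- simulate_breaths(c(1L, 2L), event_rates = r0, seed = 1)
  expect_equal(sum(b0$iee) + sum(b0$double_cycling) +
                 sum(b0$short_cycling) + sum(b0$prolonged_cycling), 0)

  # forced: every breath flagged for one type in a single window
  r1 <- matrix(c(1, 0, 0, 0), 1, 4)
  b1 <- simulate_breaths(1L, window_minutes = 1, breath_rate = 10,
                         event_rates = r1, seed = 2)
  expect_equal(sum(b1$iee), nrow(b1))

  # state-dependent rates: indexed counts per window near breath_rate*T*rate
  rates <- rbind(c(0.002, 0.001, 0, 0), c(0.05, 0.02, 0.01, 0.005))
  states <- rep(c(1L, 2L), each = 150)
  b <- simulate_breaths(states, window_minutes = 15, breath_rate = 22,
                        event_rates = rates, seed = 3)
  per_w <- dplyr::count(dplyr::group_by(b, window, state),
                        wt = iee + double_cycling + short_cycling + prolonged_cycling)
  m <- tapply(per_w$n, per_w$state, mean)
  expected <- 22 * 15 * rowSums(rates)
  for (j in 1:2) expect_lt(abs(m[j] / expected[j] - 1), 0.15)

  expect_error(simulate_breaths(1L, event_rates = matrix(0.5, 1, 4)), "row sums")
})

test_that("cardio generator couples SpO2 depression to the high-risk state", {
  model0 <- tibble::tibble(state = 1:2, hr_mean = c(70, 80), hr_sd = 0,
                           spo2_mean = c(96, 88), spo2_sd = 0)
  cd <- simulate_cardio(c(1L, 2L), model0, samples_per_window = 4, seed = 1)
  expect_equal(unique(cd$hr[cd$state == 1]), 70)
  expect_equal(unique(cd$spo2[cd$state == 2]), 88)

  # HR 70, SD 0: no bradycardia or tachycardia possible
  eps <- detect_episodes(cd[cd$state == 1, ])
  expect_true(all(!eps$episode[eps$type %in% c("bradycardia", "tachycardia")]))

  states <- rep(1:4, each = 500)
  cd4 <- simulate_cardio(states, seed = 9)
  expect_true(all(cd4$spo2 <= 100))
  hyp <- tapply(cd4$spo2 < 90, cd4$state, mean)
  expect_gt(hyp[["4"]], hyp[["1"]])
})
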