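mk_breaths <- function(t_minutes, flags = NULL) {
  n <- length(t_minutes)
  out <- tibble::tibble(
    timestamp = t_minutes,
    iee = 0L, double_cycling = 0L, short_cycling = 0L, prolonged_cycling = 0L
  )
  if (!is.null(flags)) out[names(flags)] <- flags
  out
}

test_that("windows are half-open, counts are conserved, partial tail dropped", {
  # no flags -> zero counts
  b <- mk_breaths(seq(0, 9.5, by = 1))
  z <- index_events(b, window_minutes = 5, end = 10)
  expect_equal(z$count, c(0L, 0L))
  expect_equal(z$n_breaths, c(5L, 5L))

  # hand count: breaths at minutes 1, 6, 7; origin 1; windows [1,6), [6,11)
  b2 <- mk_breaths(c(1, 6, 7), flags = list(iee = 1L))
  z2 <- index_events(b2, window_minutes = 5, end = 11)
  expect_equal(z2$count, c(1L, 2L))
  expect_equal(z2$n_breaths, c(1L, 2L))

  # without a declared end the trailing partial window is dropped
  z2b <- index_events(b2, window_minutes = 5)
  expect_equal(z2b$count, 1L)

  # a breath with two flags: 2 in events mode, 1 in breaths mode
  b3 <- mk_breaths(c(0.5), flags = list(iee = 1L, double_cycling = 1L))
  expect_equal(index_events(b3, 1, "events", end = 1)$count, 2L)
  expect_equal(index_events(b3, 1, "breaths", end = 1)$count, 1L)

  # conservation within covered windows
  withr::with_seed(1, {
    t <- sort(runif(500, 0, 60))
    fl <- list(iee = rbinom(500, 1, 0.1), double_cycling = rbinom(500, 1, 0.05))
    b4 <- mk_breaths(t, fl)
  })
  z4 <- index_events(b4, 15, end = 60)
  expect_equal(sum(z4$count), sum(b4$iee) + sum(b4$double_cycling))
  expect_equal(sum(z4$n_breaths), 500L)

  expect_equal(nrow(index_events(mk_breaths(numeric(0)), 5)), 0L)
  expect_error(index_events(b4, -5), "positive")
  expect_warning(index_events(mk_breaths(c(5, 1)), 5), "not sorted")
})

test_that("indexing at T then aggregating 3 windows equals indexing at 3T", {
  withr::with_seed(2, {
    t <- sort(runif(2000, 0, 90))
    b <- mk_breaths(t, list(iee = rbinom(2000, 1, 0.2),
                            short_cycling = rbinom(2000, 1, 0.1)))
  })
  fine <- index_events(b, 5, origin = 0, end = 90)
  coarse <- index_events(b, 15, origin = 0, end = 90)
  agg <- tapply(fine$count, rep(seq_len(6), each = 3), sum)
  expect_identical(as.integer(agg), coarse$count)
  aggn <- tapply(fine$n_breaths, rep(seq_len(6), each = 3), sum)
  expect_identical(as.integer(aggn), coarse$n_breaths)
})

test_that("round trip with the breath generator recovers counts exactly", {
  states <- rep(c(1L, 2L, 1L, 2L), each = 5)
  rates <- rbind(c(0.01, 0.005, 0, 0), c(0.1, 0.05, 0.02, 0.01))
  b <- simulate_breaths(states, window_minutes = 15, breath_rate = 22,
                        event_rates = rates, seed = 42)
  truth <- b |>
    dplyr::group_by(window) |>
    dplyr::summarise(
      count = sum(iee + double_cycling + short_cycling + prolonged_cycling),
      n = dplyr::n()
    ) |>
    tidyr::complete(window = seq_along(states), fill = list(count = 0L, n = 0L))
  z <- index_events(
    b, 15,
    origin = as.POSIXct("2000-01-01 00:00:00", tz = "UTC"),
    end = as.POSIXct("2000-01-01 00:00:00", tz = "UTC") + 60 * 15 * length(states)
  )
  expect_equal(nrow(z), length(states))
  expect_equal(z$count, as.integer(truth$count))
  expect_equal(z$n_breaths, as.integer(truth$n))
})

test_that("cardio resampling averages per window and marks gaps missing", {
  raw <- tibble::tibble(time = c(1, 2, 16), hr = c(60, 100, 75), spo2 = c(95, 97, 92))
  rs <- resample_cardio(raw, 15, origin = 0, n_windows = 3)
  expect_equal(rs$hr, c(80, 75, NA))
  expect_equal(rs$spo2, c(96, 92, NA))
  expect_true(is.na(rs$hr[3])) # gap is missing, not zero
  expect_equal(rs$n_samples, c(2L, 1L, 0L))

  const <- tibble::tibble(time = seq(0, 59, 1), hr = 80, spo2 = 96)
  rc <- resample_cardio(const, 15)
  expect_true(all(rc$hr == 80))
})
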