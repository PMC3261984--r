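test_that("threshold grids are inclusive regular sequences", {
  expect_length(threshold_grid(-5, 5, 0.1), 101L)
  expect_length(threshold_grid(19, 29, 0.1), 101L)
  expect_equal(threshold_grid(0, 2, 0.5), c(0, 0.5, 1, 1.5, 2))
  expect_error(threshold_grid(0, 2, 0), "positive")
  # coarse-to-fine fit budget for the classic ranges: 11x11 coarse plus at
  # most a 21x21 fine window
  expect_lte(length(threshold_grid(-5, 5, 1))^2, 121L)
  expect_lte(length(threshold_grid(-1, 1, 0.1))^2, 441L)
})

strong_search_series <- function(n = 1000L, seed = 51L) {
  eff <- true_effect_surface(
    0, 25, cold_slope = 0.3, hot_slope = 0.3,
    cold_lag_weights = lag_weights_spline(10L, 3L,
                                          lag_weights_acute(10L, rate = 3)),
    hot_lag_weights = lag_weights_spline(10L, 3L, lag_weights_acute(10L)))
  simulate_series(scenario_config(n_days = n, seed = seed, true_effect = eff))
}

test_that("search minimizes residual deviance and is order-invariant", {
  s <- strong_search_series()
  lag <- lag_spec(10L, 3L)
  cg <- threshold_grid(-2, 2, 1)
  hg <- threshold_grid(23, 27, 1)
  sr <- search_thresholds(s, cold_grid = cg, hot_grid = hg, lag = lag)
  expect_equal(sr$n_fits, length(cg) * length(hg))
  expect_equal(nrow(sr$deviance_grid), sr$n_fits)
  ok <- !sr$deviance_grid$failed
  expect_equal(sr$min_deviance, min(sr$deviance_grid$residual_deviance[ok]))
  best <- sr$best
  # shuffling candidate order changes nothing
  set.seed(1)
  sr2 <- search_thresholds(s, cold_grid = sample(cg), hot_grid = sample(hg),
                           lag = lag)
  expect_equal(sr2$best$cold_threshold, best$cold_threshold)
  expect_equal(sr2$best$hot_threshold, best$hot_threshold)
  # the winning cell reproduces under an independent refit
  refit <- fit_ccdlnm(s, crossbasis_spec(best, lag))
  expect_equal(refit$deviance, sr$min_deviance, tolerance = 1e-6)
})

test_that("coarse-to-fine matches the exhaustive search on a unimodal surface", {
  s <- strong_search_series(seed = 52L)
  lag <- lag_spec(10L, 3L)
  ex <- search_thresholds(s, cold_grid = threshold_grid(-2, 2, 0.5),
                          hot_grid = threshold_grid(23, 27, 0.5), lag = lag)
  cf <- coarse_to_fine(s, cold_range = c(-2, 2), hot_range = c(23, 27),
                       coarse_step = 1, fine_step = 0.5, lag = lag)
  expect_equal(cf$best$cold_threshold, ex$best$cold_threshold)
  expect_equal(cf$best$hot_threshold, ex$best$hot_threshold)
  expect_lte(cf$n_fits, 25L + 25L)
  expect_named(cf$refine, c("cold_window", "hot_window"))
})

test_that("stronger embedded effects concentrate the recovered thresholds", {
  lag <- lag_spec(10L, 3L)
  spread <- sapply(c(weak = 0.05, strong = 0.4), function(slope) {
    ests <- sapply(1:4, function(i) {
      eff <- true_effect_surface(
        0, 25, cold_slope = slope, hot_slope = slope,
        cold_lag_weights = lag_weights_spline(10L, 3L),
        hot_lag_weights = lag_weights_spline(10L, 3L))
      s <- simulate_series(scenario_config(n_days = 800L, seed = 700 + i,
                                           true_effect = eff))
      sr <- coarse_to_fine(s, cold_range = c(-4, 4), hot_range = c(21, 29),
                           coarse_step = 2, fine_step = 1, lag = lag)
      c(sr$best$cold_threshold, sr$best$hot_threshold)
    })
    mean(abs(ests[1, ] - 0)) + mean(abs(ests[2, ] - 25))
  })
  expect_lt(spread["strong"], spread["weak"] + 1e-9)
})
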