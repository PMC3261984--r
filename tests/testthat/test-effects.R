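fit_small <- function(n = 500L, seed = 41L, spec = truth_cb_spec(10L)) {
  s <- small_series(n = n, seed = seed)
  fit_ccdlnm(s, spec)
}

test_that("relative risk is exactly 1 at the centering temperature", {
  fit <- fit_small()
  surf <- predict_surface(fit, temp_grid = c(fit$spec$center - 3,
                                             fit$spec$center,
                                             fit$spec$center + 3))
  expect_equal(unname(surf$log_rr[2, ]), rep(0, 11))
  expect_equal(unname(surf$se[2, ]), rep(0, 11))
  ce <- cumulative_effect(fit, list(at_temperature = fit$spec$center),
                          c(0L, 10L))
  expect_equal(ce$percent_increase, 0)
  expect_equal(ce$se, 0)
})

test_that("threshold-model surface is flat inside the comfort band", {
  fit <- fit_small(spec = truth_cb_spec(8L))
  surf <- predict_surface(fit, temp_grid = seq(1, 24, by = 1))
  expect_true(all(surf$log_rr == 0))
  expect_true(all(surf$se == 0))
})

test_that("cumulative effects add exactly across adjoining lag windows", {
  fit <- fit_small(spec = truth_cb_spec(27L))
  for (est in list("per_degree_below_cold", "per_degree_above_hot",
                   list(at_temperature = -4))) {
    full <- cumulative_effect(fit, est, c(0L, 27L))
    a <- cumulative_effect(fit, est, c(0L, 2L))
    b <- cumulative_effect(fit, est, c(3L, 27L))
    expect_equal(full$log_rr, a$log_rr + b$log_rr, tolerance = 1e-12)
  }
  # a single-lag window equals the lag slice at that lag
  surf <- predict_surface(fit, temp_grid = -1)
  sl <- lag_slice(surf, -1)
  ce0 <- cumulative_effect(fit, list(at_temperature = -1), c(0L, 0L))
  expect_equal(ce0$log_rr, sl$log_rr[sl$lag == 0], tolerance = 1e-12)
})

test_that("slices refuse off-grid values instead of interpolating", {
  fit <- fit_small()
  surf <- predict_surface(fit, temp_grid = seq(-10, 30, by = 0.5))
  expect_error(lag_slice(surf, -9.87), "not on the grid")
  expect_error(temp_slice(surf, 99), "not on the grid")
  flat <- lag_slice(surf, surf$temperatures[
    which.min(abs(surf$temperatures - fit$spec$center))])
  expect_true(all(is.finite(flat$rr)))
})

test_that("indicator-lag slices match the explicit lagged-GLM oracle", {
  s <- small_series(n = 450L, seed = 42L)
  od <- oracle_design(s, max_lag = 3L)
  fit <- fit_ccdlnm(s, crossbasis_spec(spline_spec(1L),
                                       lag_spec(3L, kind = "indicator")))
  orc <- fit_quasipoisson(od$design$y,
                          cbind(od$design$X[, -od$design$cb_index,
                                            drop = FALSE], od$XL))
  surf <- predict_surface(fit, temp_grid = fit$spec$center + 1)
  sl <- lag_slice(surf, fit$spec$center + 1)
  expect_equal(sl$rr, unname(exp(orc$coefficients[paste0("xl", 0:3)])),
               tolerance = 1e-8)
})

test_that("temp slice of a threshold model is piecewise linear in log-RR", {
  fit <- fit_small(spec = truth_cb_spec(8L))
  surf <- predict_surface(fit, temp_grid = seq(-10, 35, by = 0.5))
  ts0 <- temp_slice(surf, 0)
  cold <- ts0$temperature < 0
  slopes <- diff(ts0$log_rr[cold]) / diff(ts0$temperature[cold])
  expect_lt(max(abs(slopes - slopes[1])), 1e-10)
  hot <- ts0$temperature > 25
  slopes <- diff(ts0$log_rr[hot]) / diff(ts0$temperature[hot])
  expect_lt(max(abs(slopes - slopes[1])), 1e-10)
})

test_that("delta-method cumulative variance matches a parametric bootstrap", {
  fit <- fit_small(n = 800L, seed = 43L, spec = truth_cb_spec(27L))
  ce <- cumulative_effect(fit, "per_degree_below_cold", c(0L, 18L))
  w <- cumulative_weights(fit$spec, fit$spec$exposure$cold_threshold - 1,
                          c(0L, 18L))
  blk_idx <- fit$cb_index
  V <- fit$covariance[blk_idx, blk_idx]
  set.seed(99)
  R <- chol(V)
  draws <- matrix(rnorm(1000 * nrow(V)), 1000) %*% R
  boot <- draws %*% w  # deviations around the point estimate
  expect_equal(sd(boot), ce$se, tolerance = 0.05)
})

test_that("the fitted surface recovers a known embedded effect surface", {
  # pointwise 95% bands should cover the true log-RR at nearly all cells
  reps <- 6
  cover <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- scenario("both_effects", n_days = 1500L, seed = 600 + i)
    s <- simulate_series(cfg)
    fit <- fit_ccdlnm(s, truth_cb_spec(27L))
    surf <- predict_surface(fit, temp_grid = seq(-8, 30, by = 1))
    eff <- cfg$true_effect
    truth <- outer(seq(-8, 30, by = 1), 0:27, function(x, l)
      eff$cold_slope * eff$cold_lag_weights[l + 1] * pmax(eff$cold_threshold - x, 0) +
        eff$hot_slope * eff$hot_lag_weights[l + 1] * pmax(x - eff$hot_threshold, 0))
    inside <- abs(surf$log_rr - truth) <= qnorm(0.975) * surf$se + 1e-12
    cover[i] <- mean(inside)
  }
  expect_gt(mean(cover), 0.9)
})
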