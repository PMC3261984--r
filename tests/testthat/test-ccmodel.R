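test_that("strata partition the series under both schemes", {
  d1 <- seq(as.Date("2005-01-01"), as.Date("2005-12-31"), by = "day")
  expect_equal(nlevels(make_strata(d1, strata_spec("calendar_month"))), 12L)
  d3 <- seq(as.Date("2005-01-01"), as.Date("2007-12-31"), by = "day")
  expect_equal(nlevels(make_strata(d3, strata_spec("calendar_month"))), 36L)
  st21 <- make_strata(d3[1:1095], strata_spec("fixed_window", 21))
  expect_equal(nlevels(st21), 53L)
  expect_equal(as.vector(table(st21)), c(rep(21L, 52), 3L))
  # exhaustive partition: every day labelled, windows contiguous and disjoint
  for (spec in list(strata_spec("calendar_month"),
                    strata_spec("fixed_window", 28))) {
    st <- make_strata(d3, spec)
    expect_false(anyNA(st))
    expect_equal(sum(table(st)), length(d3))
    expect_true(all(diff(as.integer(st)) %in% c(0L, 1L)))  # contiguous blocks
  }
  expect_error(make_strata(as.Date(character(0)),
                           strata_spec("calendar_month")), "empty")
})

test_that("the design matrix has the documented blocks", {
  s <- small_series(n = 500L, seed = 21L)
  cb <- build_crossbasis(s$tmean, truth_cb_spec(max_lag = 27L))
  st <- make_strata(s$date, strata_spec("fixed_window", 21))
  d <- build_design(s, cb, st)
  cn <- colnames(d$X)
  expect_equal(length(d$cb_index), 8L)            # 2 exposure cols x 4 lag df
  expect_equal(sum(grepl("\\.s[0-9]$", cn)), 12L) # 4 smooths x 3 df
  expect_equal(sum(grepl("^dow", cn)), 6L)        # 7 weekday levels, ref-coded
  # first window (days 1..21) is wiped by the 27-day burn-in: no indicator
  expect_equal(nlevels(d$strata), nlevels(droplevels(st[-(1:27)])))
  expect_false("strata.w001" %in% cn)
  expect_equal(d$rows[1], 28L)
})

test_that("quasi-Poisson fit matches closed forms and scales correctly", {
  set.seed(31)
  y <- rpois(500, 20)
  X <- matrix(1, 500, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_quasipoisson(y, X)
  expect_equal(unname(f$coefficients), log(mean(y)), tolerance = 1e-10)
  f2 <- fit_quasipoisson(2L * y, X)
  expect_equal(unname(f2$coefficients - f$coefficients), log(2),
               tolerance = 1e-10)
  expect_error(fit_quasipoisson(c(-1, y), rbind(1, X)), "negative")
})

test_that("Pearson dispersion is calibrated for equidispersed counts", {
  set.seed(32)
  phis <- replicate(200, {
    y <- rpois(1000, 15)
    fit_quasipoisson(y, matrix(1, 1000, 1))$dispersion
  })
  expect_lt(mean(abs(phis - 1)), 0.1)
})

test_that("dispersion and fit are invariant to basis reparameterization", {
  s <- small_series(n = 300L, seed = 22L)
  cb <- build_crossbasis(s$tmean, truth_cb_spec(max_lag = 10L))
  st <- make_strata(s$date, strata_spec("calendar_month"))
  d <- build_design(s, cb, st)
  f1 <- fit_quasipoisson(d$y, d$X)
  A <- diag(ncol(d$X))
  set.seed(5)
  # invertible recombination of the cross-basis block spans the same space
  A[d$cb_index, d$cb_index] <- matrix(rnorm(64), 8, 8) + 2 * diag(8)
  f2 <- fit_quasipoisson(d$y, d$X %*% A)
  expect_equal(f1$dispersion, f2$dispersion, tolerance = 1e-8)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-8)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
})

test_that("residual deviance never increases when a nested model gains columns", {
  s <- small_series(n = 300L, seed = 23L)
  cb <- build_crossbasis(s$tmean, truth_cb_spec(max_lag = 5L))
  st <- make_strata(s$date, strata_spec("calendar_month"))
  d <- build_design(s, cb, st)
  devs <- sapply(seq(2, ncol(d$X), by = 7), function(k)
    fit_quasipoisson(d$y, d$X[, unique(c(1, d$cb_index[1], 2:k)),
                              drop = FALSE])$deviance)
  expect_true(all(diff(devs) <= 1e-8))
})

test_that("QAIC follows the quasi-likelihood formula", {
  f <- structure(list(loglik = -100, dispersion = 1, rank = 5L),
                 class = "cc_fit")
  expect_equal(qaic(f), 210)
  f$dispersion <- 2.5
  expect_equal(qaic(f), 225)  # penalty inflated by the dispersion
  # a pure-noise column cannot improve expected QAIC by more than ~2*phi
  set.seed(33)
  diffs <- replicate(200, {
    y <- rpois(150, 10)
    X0 <- matrix(1, 150, 1)
    X1 <- cbind(X0, rnorm(150))
    fit_quasipoisson(y, X1)$qaic - fit_quasipoisson(y, X0)$qaic
  })
  expect_gt(mean(diffs), -0.5)  # E[change] is about +1 for a useless column
})

test_that("conditional fit equals the stratified-indicator fit", {
  s <- small_series(n = 350L, seed = 24L)
  cb <- build_crossbasis(s$tmean, truth_cb_spec(max_lag = 8L))
  st <- make_strata(s$date, strata_spec("calendar_month"))
  d <- build_design(s, cb, st)
  full <- fit_quasipoisson(d$y, d$X)
  Xns <- d$X[, -c(1L, grep("^strata", colnames(d$X))), drop = FALSE]
  cond <- fit_conditional(d$y, Xns, d$strata)
  common <- colnames(Xns)
  expect_equal(cond$coefficients[common], full$coefficients[common],
               tolerance = 1e-6)
  expect_equal(cond$covariance[common, common],
               full$covariance[common, common], tolerance = 1e-6)
  expect_equal(cond$dispersion, full$dispersion, tolerance = 1e-6)
})

test_that("single-stratum conditional fit equals the ordinary fit", {
  set.seed(34)
  y <- rpois(120, exp(2 + 0.3 * scale(1:120)))
  X <- cbind(x = as.vector(scale(1:120)))
  one <- factor(rep("a", 120))
  cond <- fit_conditional(y, X, one)
  full <- fit_quasipoisson(y, cbind(1, X))
  expect_equal(unname(cond$coefficients["x"]),
               unname(full$coefficients[2]), tolerance = 1e-8)
})

test_that("all-zero strata are dropped and carry no information", {
  set.seed(35)
  y <- c(rpois(50, 8), rep(0L, 25), rpois(50, 8))
  x <- rnorm(125)
  st <- factor(rep(c("a", "zero", "b"), c(50, 25, 50)))
  with_zero <- fit_conditional(y, cbind(x = x), st)
  without <- fit_conditional(y[-(51:75)], cbind(x = x[-(51:75)]),
                             droplevels(st[-(51:75)]))
  expect_equal(with_zero$coefficients, without$coefficients, tolerance = 1e-10)
})

test_that("time spline gives df-per-year columns continuous in day index", {
  d3 <- seq(as.Date("2005-01-01"), as.Date("2007-12-31"), by = "day")
  tm <- time_spline_design(d3, 7)
  expect_equal(ncol(tm), 21L)
  expect_equal(ncol(time_spline_design(d3[1:365], 1)), 1L)
  expect_lt(max(abs(diff(tm))), 0.2)  # no jumps between consecutive days
})
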