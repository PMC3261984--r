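test_that("equally spaced knots split the range into equal sub-intervals", {
  expect_equal(equally_spaced_knots(0, 10, 2), 5)
  expect_equal(equally_spaced_knots(-11, 31, 5), c(-2.6, 5.8, 14.2, 22.6))
  expect_identical(equally_spaced_knots(0, 10, 1), numeric(0))
  expect_error(equally_spaced_knots(10, 0, 3), "invalid range")
  # affine invariance: knots map under the same affine transform as the range
  for (i in 1:20) {
    set.seed(i)
    lo <- runif(1, -50, 0); hi <- lo + runif(1, 1, 60)
    a <- runif(1, 0.1, 5); b <- runif(1, -10, 10)
    df <- sample(2:8, 1)
    k1 <- equally_spaced_knots(lo, hi, df)
    k2 <- equally_spaced_knots(a * lo + b, a * hi + b, df)
    expect_equal(k2, a * k1 + b, tolerance = 1e-12)
  }
})

test_that("lag knots sit at equal intervals on the log-lag scale", {
  k <- log_spaced_lag_knots(27, 4)
  expect_equal(k, c(3, 9), tolerance = 1e-12)
  expect_identical(log_spaced_lag_knots(27, 2), numeric(0))
  expect_error(log_spaced_lag_knots(0, 4), "invalid range")
  for (L in c(10, 20, 27, 30)) for (df in 3:6) {
    k <- log_spaced_lag_knots(L, df)
    expect_length(k, df - 2L)
    expect_true(all(k > 0 & k < L))
    gaps <- diff(c(0, log(k), log(L)))  # log(1) = 0 anchor
    expect_equal(max(gaps) - min(gaps), 0, tolerance = 1e-10)
  }
})

test_that("natural cubic spline basis has df columns and extrapolates linearly", {
  for (i in 1:15) {
    set.seed(100 + i)
    df <- sample(1:7, 1)
    bk <- sort(runif(2, -20, 40))
    while (diff(bk) < 5) bk <- sort(runif(2, -20, 40))
    sp <- spline_spec(df, boundary_knots = bk)
    x <- runif(50, bk[1] - 10, bk[2] + 10)
    m <- ns_basis(x, sp)
    expect_equal(ncol(m), df)
    expect_equal(nrow(m), 50L)
    # linearity beyond the boundary knots: constant slope on each side
    for (side in list(seq(bk[1] - 8, bk[1] - 1, length.out = 5),
                      seq(bk[2] + 1, bk[2] + 8, length.out = 5))) {
      mb <- ns_basis(side, sp)
      slopes <- diff(mb) / diff(side)
      expect_lt(max(abs(sweep(slopes, 2, slopes[1, ]))), 1e-8)
    }
  }
})

test_that("spline basis is continuous and affine when there are no knots", {
  sp <- spline_spec(1L, boundary_knots = c(0, 10))
  x <- seq(-5, 15, by = 0.5)
  m <- ns_basis(x, sp)
  expect_equal(ncol(m), 1L)
  slopes <- diff(m[, 1]) / diff(x)
  expect_lt(max(abs(slopes - slopes[1])), 1e-10)  # affine in x everywhere

  sp2 <- spline_spec(4L, boundary_knots = c(-10, 30))
  x <- runif(100, -15, 35)
  eps <- 1e-9 * pmax(abs(x), 1)
  expect_lt(max(abs(ns_basis(x + eps, sp2) - ns_basis(x, sp2))), 1e-6)
})

test_that("spline basis rejects non-finite input naming the index", {
  sp <- spline_spec(3L, boundary_knots = c(0, 10))
  expect_error(ns_basis(c(1, NA, 3), sp), "index 2")
  expect_equal(nrow(ns_basis(numeric(0), sp)), 0L)
})

test_that("threshold basis is the pair of hinge exceedances", {
  sp <- threshold_spec(0.8, 24.9)
  expect_equal(unname(threshold_basis(-1, sp)[1, ]), c(1.8, 0))
  expect_equal(unname(threshold_basis(30, sp)[1, ]), c(0, 5.1))
  expect_equal(unname(threshold_basis(14, sp)[1, ]), c(0, 0))
  x <- seq(-15, 40, by = 0.1)
  m <- threshold_basis(x, sp)
  expect_true(all(m >= 0))
  comfort <- x >= 0.8 & x <= 24.9
  expect_true(all(m[comfort, ] == 0))
  # piecewise linear: slope -1 below cold, +1 above hot
  expect_equal(unique(round(diff(m[x < 0.8, "cold"]) / 0.1, 6)), -1)
  expect_error(threshold_spec(25, 10))
})

test_that("lag basis kinds have the documented shapes", {
  ind <- lag_spec(5L, kind = "indicator")
  expect_equal(lag_basis(ind), diag(6), ignore_attr = TRUE)
  ns4 <- lag_spec(27L, 4L)
  B <- lag_basis(ns4)
  expect_equal(dim(B), c(28L, 4L))
  expect_true(all(B[, 1] == 1))  # intercept column
  expect_equal(ncol(lag_basis(lag_spec(20L, 2L))), 2L)
  expect_error(lag_basis(ns4, lags = 28), "out of range")
})
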