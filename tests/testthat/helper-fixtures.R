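# Shared fixtures: small simulated series and fit shortcuts used across the
# unit tests. Everything is generated in code at test time.

small_series <- function(n = 400L, seed = 11L, name = "both_effects", ...) {
  simulate_series(scenario(name, n_days = n, seed = seed, ...))
}

# Double-threshold cross-basis at the generator's true thresholds.
truth_cb_spec <- function(max_lag = 27L, df = 4L)
  crossbasis_spec(threshold_spec(0, 25), lag_spec(max_lag, df))

# Design pieces for a linear-exposure, indicator-lag model (the explicit
# lagged-GLM oracle setting).
oracle_design <- function(series, max_lag = 3L) {
  x <- series$tmean
  cb <- build_crossbasis(
    x, crossbasis_spec(spline_spec(1L), lag_spec(max_lag, kind = "indicator")))
  st <- make_strata(series$date, strata_spec("calendar_month"))
  d <- build_design(series, cb, st)
  rows <- attr(cb, "valid_from"):length(x)
  XL <- sapply(0:max_lag, function(l) x[rows - l])
  colnames(XL) <- paste0("xl", 0:max_lag)
  list(design = d, cb = cb, XL = XL, x = x)
}
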