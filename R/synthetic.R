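# Synthetic daily series with known embedded temperature-lag effects: the
# test bed for every stage of the analysis. Weather follows a sinusoidal
# annual cycle with AR(1) noise; mortality is generated from the same
# log-linear structure the models assume, with a configurable true
# double-threshold exposure effect distributed over lags.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Define the true exposure-lag effect surface of a simulation
#'
#' The embedded effect is double-threshold in temperature: log relative risk
#' \code{cold_slope} per degree below \code{cold_threshold} and
#' \code{hot_slope} per degree above \code{hot_threshold}, distributed over
#' lags by \code{lag_weights}. Weights may be negative at mid lags to encode
#' mortality displacement (harvesting): acute excess deaths followed by
#' compensating deficits.
#'
#' @param cold_threshold,hot_threshold degrees Celsius.
#' @param cold_slope,hot_slope log relative risk per degree of exceedance,
#'   for a total (all-lag) exposure effect when the weights sum to 1.
#' @param lag_weights numeric vector over lags \code{0..max_lag}, shared by
#'   both sides unless a side-specific profile is given.
#' @param cold_lag_weights,hot_lag_weights optional side-specific lag
#'   profiles (cold effects are typically delayed, hot effects acute).
#' @return an object of class \code{"true_effect"}.
#' @export
true_effect_surface <- function(cold_threshold = 0, hot_threshold = 25,
                                cold_slope = 0, hot_slope = 0,
                                lag_weights = lag_weights_null(27L),
                                cold_lag_weights = NULL,
                                hot_lag_weights = NULL) {
  if (cold_threshold >= hot_threshold)
    stop("'cold_threshold' must be below 'hot_threshold'")
  if (is.null(cold_lag_weights)) cold_lag_weights <- lag_weights
  if (is.null(hot_lag_weights)) hot_lag_weights <- lag_weights
  if (length(cold_lag_weights) != length(hot_lag_weights))
    stop("cold and hot lag-weight vectors must have equal length")
  structure(list(cold_threshold = cold_threshold,
                 hot_threshold = hot_threshold,
                 cold_slope = cold_slope, hot_slope = hot_slope,
                 lag_weights = lag_weights,
                 cold_lag_weights = cold_lag_weights,
                 hot_lag_weights = hot_lag_weights,
                 max_lag = length(cold_lag_weights) - 1L),
            class = "true_effect")
}

#' Lag-weight shapes for simulation scenarios
#'
#' Builders for the lag profiles used by the named scenarios:
#' \code{lag_weights_null} (all zero), \code{lag_weights_acute} (smooth
#' exponential decay from lag 0, normalised to sum 1),
#' \code{lag_weights_delayed} (zero at lags 0..\code{onset - 1}, then a
#' smooth bump, sum 1), and \code{lag_weights_harvesting} (acute positive
#' phase summing to 1 followed by a negative displacement phase summing to
#' \code{-deficit}).
#'
#' @param max_lag maximum lag.
#' @param rate decay constant (days) of the acute profile.
#' @param onset first non-zero lag of the delayed profile.
#' @param peak_after days after onset at which the delayed bump peaks.
#' @param deficit total weight of the negative (displacement) phase.
#' @return numeric vector of length \code{max_lag + 1}.
#' @name lag_weights
NULL

#' @rdname lag_weights
#' @export
lag_weights_null <- function(max_lag = 27L) rep(0, max_lag + 1L)

#' @rdname lag_weights
#' @export
lag_weights_acute <- function(max_lag = 27L, rate = 1.2) {
  w <- exp(-(0:max_lag) / rate)
  w / sum(w)
}

#' @rdname lag_weights
#' @export
lag_weights_delayed <- function(max_lag = 27L, onset = 3L, peak_after = 3) {
  l <- 0:max_lag
  w <- ifelse(l < onset, 0,
              ((l - onset + 1) / peak_after)^2 * exp(-(l - onset + 1) / peak_after))
  w / sum(w)
}

#' @rdname lag_weights
#' @param df,target for \code{lag_weights_spline}: the shape \code{target}
#'   (a vector over lags \code{0..max_lag}) is projected onto the span of
#'   the \code{df}-column log-knot lag spline basis and renormalised to sum
#'   1, giving a smooth profile the distributed-lag model can represent
#'   exactly. Used by recovery scenarios so that coverage measures
#'   estimation error, not basis-approximation error.
#' @export
lag_weights_spline <- function(max_lag = 27L, df = 4L,
                               target = lag_weights_acute(max_lag),
                               normalize = TRUE) {
  B <- lag_basis(lag_spec(max_lag, df), 0:max_lag)
  w <- drop(B %*% qr.solve(B, target))
  # the intercept column is in the span, so projection preserves sum(target);
  # renormalising is only meaningful for profiles summing to 1
  if (normalize) w / sum(w) else w
}

#' @rdname lag_weights
#' @export
lag_weights_harvesting <- function(max_lag = 27L, rate = 1.2, deficit = 1,
                                   onset = 3L, peak_after = 3) {
  up <- lag_weights_acute(max_lag, rate)
  up[(onset + 1L):(max_lag + 1L)] <- 0
  up <- up / sum(up)
  down <- lag_weights_delayed(max_lag, onset = onset + 1L,
                              peak_after = peak_after)
  up - deficit * down
}

#' Configure a simulation scenario
#'
#' Collects every knob of the generator: series length, the temperature
#' process (annual level, seasonal amplitude, AR(1) coefficient and
#' innovation standard deviation, all in degrees Celsius), the baseline
#' daily death counts per cause, day-of-week log-scale offsets, the
#' winter-peaking seasonal mortality amplitude (log scale), the
#' overdispersion of the counts (variance/mean ratio; 1 = Poisson), and the
#' embedded [true_effect_surface()].
#'
#' @param n_days series length in days.
#' @param seed integer seed; the series is a pure function of (config, seed).
#' @param temperature list(level, amplitude, ar, sd).
#' @param baseline named daily means for nonaccidental, cardiopulmonary,
#'   cardiovascular and respiratory deaths.
#' @param dow_effects 7 log-scale offsets (Mon..Sun).
#' @param season_amplitude log-scale amplitude of the smooth (non-influenza)
#'   winter mortality peak not attributable to temperature.
#' @param influenza_effect log-scale mortality increase on days with any
#'   influenza deaths (absorbed by the model's influenza indicator).
#' @param overdispersion variance/mean ratio of the counts, >= 1.
#' @param true_effect a [true_effect_surface()].
#' @param start_date first calendar day.
#' @return an object of class \code{"scenario_config"}.
#' @export
scenario_config <- function(n_days = 1095L, seed = 1L,
                            temperature = list(level = 13, amplitude = 14.6,
                                               ar = 0.8, sd = 2.2),
                            baseline = c(nonaccidental = 56,
                                         cardiopulmonary = 34,
                                         cardiovascular = 30,
                                         respiratory = 4),
                            dow_effects = c(0.02, 0, -0.01, 0, 0, 0.01, -0.02),
                            season_amplitude = 0.08,
                            influenza_effect = 0.08,
                            overdispersion = 2.5,
                            true_effect = true_effect_surface(),
                            start_date = as.Date("2005-01-01")) {
  stopifnot(n_days > 0, overdispersion >= 1, all(baseline > 0),
            temperature$sd > 0, length(dow_effects) == 7L,
            inherits(true_effect, "true_effect"))
  structure(list(n_days = as.integer(n_days), seed = as.integer(seed),
                 temperature = temperature, baseline = baseline,
                 dow_effects = dow_effects,
                 season_amplitude = season_amplitude,
                 influenza_effect = influenza_effect,
                 overdispersion = overdispersion, true_effect = true_effect,
                 start_date = as.Date(start_date)),
            class = "scenario_config")
}

#' Named simulation scenarios
#'
#' Presets covering the qualitative patterns the analysis must detect:
#' \describe{
#'   \item{null}{no temperature effect; calibration of confidence intervals.}
#'   \item{hot_acute_harvesting}{acute hot effect over lags 0-3 followed by a
#'     fully compensating mortality deficit (net all-lag effect zero).}
#'   \item{cold_delayed}{cold effect absent at lags 0-2, then a smooth bump
#'     persisting about 10 days.}
#'   \item{both_effects}{strong cold (smooth bump from lag 1) and hot (smooth
#'     acute decay) effects with thresholds 0 and 25 degrees Celsius; the
#'     parameter-recovery workhorse.}
#'   \item{tianjin_like}{a 3-year series whose marginal moments match a
#'     northern-Chinese city (mean temperature about 13 +/- 11 degrees
#'     Celsius, 56 +/- 14 nonaccidental deaths/day, temperature measures
#'     rank-correlated above 0.94), with moderate delayed-cold and
#'     acute-hot-with-harvesting effects at thresholds 0.8 and 24.9.}
#' }
#'
#' @param name scenario name.
#' @param n_days,seed overrides of the preset length and seed.
#' @param ... further overrides passed to [scenario_config()].
#' @return a [scenario_config()].
#' @export
scenario <- function(name = c("null", "hot_acute_harvesting", "cold_delayed",
                              "both_effects", "tianjin_like"),
                     n_days = NULL, seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    null = list(n_days = 3000L,
                true_effect = true_effect_surface(0, 25, 0, 0)),
    hot_acute_harvesting = list(
      n_days = 3000L,
      true_effect = true_effect_surface(
        0, 25, cold_slope = 0, hot_slope = 0.08,
        lag_weights = lag_weights_spline(
          27L, 4L, target = lag_weights_harvesting(27L),
          normalize = FALSE))),
    cold_delayed = list(
      n_days = 3000L,
      true_effect = true_effect_surface(
        0, 25, cold_slope = 0.06, hot_slope = 0,
        lag_weights = lag_weights_delayed(27L))),
    both_effects = list(
      n_days = 3000L,
      true_effect = true_effect_surface(
        0, 25, cold_slope = 0.08, hot_slope = 0.08,
        cold_lag_weights = lag_weights_spline(
          27L, 4L, target = lag_weights_delayed(27L)),
        hot_lag_weights = lag_weights_spline(
          27L, 4L, target = lag_weights_acute(27L)))),
    tianjin_like = list(
      n_days = 1095L,
      true_effect = true_effect_surface(
        0.8, 24.9, cold_slope = 0.03, hot_slope = 0.02,
        cold_lag_weights = lag_weights_delayed(27L),
        hot_lag_weights = lag_weights_harvesting(27L, deficit = 0.6))))
  over <- list(...)
  args[names(over)] <- over
  if (!is.null(n_days)) args$n_days <- n_days
  args$seed <- seed
  do.call(scenario_config, args)
}

#' Generate daily weather and covariates
#'
#' Mean temperature is a sinusoidal annual cycle (summer peak) plus AR(1)
#' noise; maximum and minimum temperatures are offsets of the mean with
#' independent day-to-day noise small enough to keep the three measures
#' rank-correlated above 0.94. Humidity and pollutant concentrations carry
#' their own seasonal cycles (pollutants peak in winter); holiday flags are
#' Bernoulli and the influenza-death indicator is winter-weighted.
#'
#' @param config a [scenario_config()].
#' @return data.frame of dates, temperatures, humidity, pollutants and flags.
#' @export
gen_weather <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  restore <- local_seed(config$seed)
  on.exit(restore())
  n <- config$n_days
  dates <- config$start_date + 0:(n - 1L)
  doy <- as.integer(format(dates, "%j"))
  tp <- config$temperature
  season <- cos(2 * pi * (doy - 201) / 365.25)       # peak ~20 July
  ar <- as.vector(stats::arima.sim(list(ar = tp$ar), n, sd = tp$sd))
  tmean <- tp$level + tp$amplitude * season + ar
  tmax <- tmean + 6 + stats::rnorm(n, 0, 1.2)
  tmin <- tmean - 5 + stats::rnorm(n, 0, 1.2)
  humidity <- pmin(pmax(60 + 10 * season + stats::rnorm(n, 0, 14), 5), 100)
  wseason <- cos(2 * pi * (doy - 15) / 365.25)       # winter peak
  pm10 <- exp(log(100) + 0.25 * wseason + stats::rnorm(n, 0, 0.35))
  so2 <- exp(log(60) + 0.35 * wseason + stats::rnorm(n, 0, 0.35))
  no2 <- exp(log(50) + 0.20 * wseason + stats::rnorm(n, 0, 0.30))
  holiday <- stats::rbinom(n, 1L, 0.04)
  influenza <- stats::rbinom(n, 1L, stats::plogis(-4 + 2.5 * wseason))
  data.frame(date = dates, tmax = tmax, tmean = tmean, tmin = tmin,
             humidity = humidity, pm10 = pm10, so2 = so2, no2 = no2,
             holiday = holiday, influenza = influenza)
}

# Distributed-lag linear predictor contribution on each day, with separate
# cold and hot lag profiles; the exposure history before day 1 is padded
# with the first observed value.
lagged_effect <- function(x, eff) {
  L <- eff$max_lag
  xp <- c(rep(x[1L], L), x)
  hc <- eff$cold_slope * pmax(eff$cold_threshold - xp, 0)
  hh <- eff$hot_slope * pmax(xp - eff$hot_threshold, 0)
  n <- length(x)
  out <- numeric(n)
  for (l in 0:L) {
    idx <- (L - l + 1L):(L - l + n)
    out <- out + eff$cold_lag_weights[l + 1L] * hc[idx] +
      eff$hot_lag_weights[l + 1L] * hh[idx]
  }
  out
}

#' Generate daily death counts from weather
#'
#' Counts follow \eqn{\log\mu_t = \log(\mathrm{baseline})
#'   + a_s \cos(\cdot) + \mathrm{DOW}_t
#'   + \sum_l w_l h(x_{t-l})} with \eqn{h} the double-threshold exposure
#' transform of the configured [true_effect_surface()] applied to mean
#' temperature, a winter-peaking seasonal term (deliberately confounded with
#' temperature so stratum adjustment is exercised) and day-of-week offsets.
#' Counts are negative binomial with variance equal to
#' \code{overdispersion * mean} (Poisson when overdispersion is 1).
#'
#' @param weather output of [gen_weather()].
#' @param config the same [scenario_config()].
#' @return data.frame of daily counts per cause, plus the true per-day
#'   log-risk contribution of temperature as attribute \code{"true_log_rr"}.
#' @export
gen_mortality <- function(weather, config) {
  stopifnot(inherits(config, "scenario_config"))
  restore <- local_seed(config$seed + 500000L)
  on.exit(restore())
  n <- nrow(weather)
  doy <- as.integer(format(weather$date, "%j"))
  wseason <- cos(2 * pi * (doy - 15) / 365.25)
  dow_i <- (as.integer(format(weather$date, "%u")))  # 1=Mon
  lp_common <- config$season_amplitude * wseason +
    config$influenza_effect * weather$influenza +
    config$dow_effects[dow_i] +
    lagged_effect(weather$tmean, config$true_effect)
  d <- config$overdispersion
  counts <- lapply(config$baseline, function(b) {
    mu <- b * exp(lp_common)
    if (any(!is.finite(mu)) || any(mu > 1e6))
      stop("mean count overflow: mis-specified scenario")
    if (d == 1) stats::rpois(n, mu)
    else stats::rnbinom(n, size = mu / (d - 1), mu = mu)
  })
  out <- as.data.frame(counts)
  out$date <- weather$date
  attr(out, "true_log_rr") <- lagged_effect(weather$tmean, config$true_effect)
  out
}

#' Simulate a complete daily series
#'
#' @param config a [scenario_config()].
#' @return a [as_daily_series()] table with attribute \code{"config"}.
#' @export
simulate_series <- function(config) {
  w <- gen_weather(config)
  m <- gen_mortality(w, config)
  s <- as_daily_series(cbind(w, m[setdiff(names(m), "date")]))
  attr(s, "config") <- config
  s
}

#' Write the named fixture scenarios to disk
#'
#' Writes each scenario's daily series as CSV together with a
#' machine-readable truth file (JSON) recording the embedded effect, for
#' parameter-recovery tests.
#'
#' @param out_dir output directory (created if needed).
#' @param n_days optional common override of scenario length.
#' @param seed integer seed.
#' @return invisibly, the data.frame of files written.
#' @export
gen_fixture_suite <- function(out_dir, n_days = NULL, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  names <- c("null", "hot_acute_harvesting", "cold_delayed",
             "both_effects", "tianjin_like")
  files <- lapply(names, function(nm) {
    cfg <- scenario(nm, n_days = n_days, seed = seed)
    s <- simulate_series(cfg)
    csv <- file.path(out_dir, paste0(nm, ".csv"))
    write_daily_series(s, csv)
    truth <- file.path(out_dir, paste0(nm, "_truth.json"))
    write_truth(cfg, truth)
    data.frame(scenario = nm, series = csv, truth = truth)
  })
  invisible(do.call(rbind, files))
}

#' @rdname gen_fixture_suite
#' @param series a daily series table.
#' @param path file path.
#' @export
write_daily_series <- function(series, path) {
  df <- as.data.frame(series)
  df$dow <- NULL
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname gen_fixture_suite
#' @export
read_daily_series <- function(path) {
  as_daily_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname gen_fixture_suite
#' @param config a [scenario_config()].
#' @export
write_truth <- function(config, path) {
  eff <- config$true_effect
  obj <- list(kind = "double_threshold",
              cold_threshold = eff$cold_threshold,
              hot_threshold = eff$hot_threshold,
              cold_slope = eff$cold_slope, hot_slope = eff$hot_slope,
              lag_weights = eff$lag_weights,
              cold_lag_weights = eff$cold_lag_weights,
              hot_lag_weights = eff$hot_lag_weights,
              max_lag = eff$max_lag,
              n_days = config$n_days, seed = config$seed,
              baseline = as.list(config$baseline),
              overdispersion = config$overdispersion)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gen_fixture_suite
#' @export
read_truth <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(effect = true_effect_surface(o$cold_threshold, o$hot_threshold,
                                    o$cold_slope, o$hot_slope,
                                    o$lag_weights,
                                    cold_lag_weights = o$cold_lag_weights,
                                    hot_lag_weights = o$hot_lag_weights),
       n_days = o$n_days, seed = o$seed,
       baseline = unlist(o$baseline), overdispersion = o$overdispersion)
}

#' True cumulative effect over a lag window
#'
#' The estimand targeted by [cumulative_effect()] on simulated data: the
#' per-degree-exceedance log relative risk summed over the window,
#' \code{slope * sum(lag_weights[window])}, returned on the percent scale.
#'
#' @param effect a [true_effect_surface()].
#' @param side \code{"cold"} or \code{"hot"}.
#' @param lag_range integer pair.
#' @return list(log_rr, percent_increase).
#' @export
true_cumulative <- function(effect, side = c("cold", "hot"), lag_range) {
  side <- match.arg(side)
  w <- if (side == "cold") effect$cold_lag_weights else effect$hot_lag_weights
  w <- w[(lag_range[1L] + 1L):(lag_range[2L] + 1L)]
  slope <- if (side == "cold") effect$cold_slope else effect$hot_slope
  lr <- slope * sum(w)
  list(log_rr = lr, percent_increase = 100 * (exp(lr) - 1))
}
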