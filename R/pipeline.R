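# Orchestration of the full study workflow: descriptive summaries,
# temperature-measure and model-form comparison by QAIC, the main
# spline-DLNM + threshold-search + double-threshold analysis, sensitivity
# analyses, and the case-crossover vs time-series design comparison.

#' Configure an analysis run
#'
#' Defaults follow the study set-up: a 5-df natural cubic spline for
#' temperature crossed with a 4-df log-knot spline over lags 0..27, centered
#' at the observed median temperature; calendar-month case-crossover strata;
#' threshold candidate ranges -5..5 (cold) and 19..29 (hot) degrees Celsius.
#'
#' @param causes death-count columns to analyse.
#' @param measures temperature columns to compare.
#' @param temp_df,lag_df,max_lag cross-basis dimensions.
#' @param strata a [strata_spec()].
#' @param cold_range,hot_range threshold search ranges (degrees Celsius).
#' @param threshold_search \code{"coarse_to_fine"} (default) or
#'   \code{"exhaustive"} at \code{fine_step}.
#' @param coarse_step,fine_step threshold grid steps.
#' @param sensitivity_windows fixed-window lengths (days) for sensitivity.
#' @param sensitivity_max_lags alternative maximum lags for sensitivity.
#' @param lag_windows list of lag windows for the cumulative-effect table.
#' @return an object of class \code{"analysis_config"}.
#' @export
analysis_config <- function(causes = c("nonaccidental", "cardiopulmonary",
                                       "cardiovascular", "respiratory"),
                            measures = c("tmax", "tmean", "tmin"),
                            temp_df = 5L, lag_df = 4L, max_lag = 27L,
                            strata = strata_spec("calendar_month"),
                            cold_range = c(-5, 5), hot_range = c(19, 29),
                            threshold_search = c("coarse_to_fine",
                                                 "exhaustive"),
                            coarse_step = 1, fine_step = 0.1,
                            sensitivity_windows = c(30L, 28L, 21L),
                            sensitivity_max_lags = c(20L, 30L),
                            lag_windows = list(c(0L, 2L), c(0L, 18L),
                                               c(0L, 27L))) {
  structure(list(causes = causes, measures = measures,
                 temp_df = as.integer(temp_df), lag_df = as.integer(lag_df),
                 max_lag = as.integer(max_lag), strata = strata,
                 cold_range = cold_range, hot_range = hot_range,
                 threshold_search = match.arg(threshold_search),
                 coarse_step = coarse_step, fine_step = fine_step,
                 sensitivity_windows = as.integer(sensitivity_windows),
                 sensitivity_max_lags = as.integer(sensitivity_max_lags),
                 lag_windows = lag_windows),
            class = "analysis_config")
}

spline_cb_spec <- function(config, max_lag = config$max_lag) {
  crossbasis_spec(spline_spec(config$temp_df),
                  lag_spec(max_lag, config$lag_df))
}

threshold_cb_spec <- function(config, thresholds,
                              max_lag = config$max_lag) {
  crossbasis_spec(thresholds, lag_spec(max_lag, config$lag_df))
}

#' Descriptive summaries of a daily series
#'
#' Quantiles, mean and standard deviation per variable, and Spearman rank
#' correlations (with two-sided p-values) among the temperature measures and
#' humidity. Constant columns have zero standard deviation and undefined
#' correlations, reported as \code{NA}.
#'
#' @param series a [as_daily_series()] table.
#' @return list with data.frames \code{summary} and \code{correlations}.
#' @export
summarize_series <- function(series) {
  vars <- c("tmax", "tmean", "tmin", "humidity", "pm10", "so2", "no2",
            "nonaccidental", "cardiopulmonary", "cardiovascular",
            "respiratory", "influenza")
  vars <- intersect(vars, names(series))
  smry <- do.call(rbind, lapply(vars, function(v) {
    x <- series[[v]]
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1))
    data.frame(variable = v, min = q[1L], p25 = q[2L], median = q[3L],
               p75 = q[4L], max = q[5L], mean = mean(x),
               sd = stats::sd(x), row.names = NULL)
  }))
  cv <- c("tmax", "tmean", "tmin", "humidity")
  cv <- intersect(cv, names(series))
  pairs <- utils::combn(cv, 2L)
  corr <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- series[[pairs[1L, i]]]; b <- series[[pairs[2L, i]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(data.frame(var1 = pairs[1L, i], var2 = pairs[2L, i],
                        rho = NA_real_, p_value = NA_real_))
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                           exact = FALSE))
    data.frame(var1 = pairs[1L, i], var2 = pairs[2L, i],
               rho = unname(ct$estimate), p_value = ct$p.value)
  }))
  list(summary = smry, correlations = corr)
}

#' Compare temperature measures and model forms by QAIC
#'
#' Fits both model forms (natural cubic spline exposure, and double
#' threshold at per-measure default thresholds set to the 10th and 90th
#' percentiles of the measure) for every temperature measure and cause, and
#' tabulates QAIC; the minimum per cause flags the best-predicting measure.
#'
#' @param series a [as_daily_series()] table.
#' @param config an [analysis_config()].
#' @param thresholds optional named list measure -> [threshold_spec()]
#'   overriding the percentile defaults for the threshold form.
#' @return data.frame: measure, cause, form, qaic, dispersion, best (flag).
#' @export
compare_measures <- function(series, config = analysis_config(),
                             thresholds = NULL) {
  rows <- list()
  for (ms in config$measures) {
    th <- if (!is.null(thresholds[[ms]])) thresholds[[ms]]
    else {
      q <- stats::quantile(series[[ms]], c(0.1, 0.9))
      threshold_spec(q[[1L]], q[[2L]])
    }
    for (cause in config$causes) {
      for (form in c("ns", "double_threshold")) {
        spec <- if (form == "ns") spline_cb_spec(config)
        else threshold_cb_spec(config, th)
        row <- tryCatch({
          fit <- fit_ccdlnm(series, spec, outcome = cause, measure = ms,
                            strata = config$strata)
          data.frame(measure = ms, cause = cause, form = form,
                     qaic = fit$qaic, dispersion = fit$dispersion,
                     failed = FALSE)
        }, error = function(e)
          data.frame(measure = ms, cause = cause, form = form,
                     qaic = NA_real_, dispersion = NA_real_, failed = TRUE))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  for (cause in unique(out$cause)) {
    i <- which(out$cause == cause & !out$failed)
    if (length(i)) out$best[i[which.min(out$qaic[i])]] <- TRUE
  }
  out
}

run_threshold_search <- function(series, cause, measure, config) {
  if (config$threshold_search == "exhaustive") {
    search_thresholds(series, outcome = cause,
                      cold_grid = threshold_grid(config$cold_range[1L],
                                                 config$cold_range[2L],
                                                 config$fine_step),
                      hot_grid = threshold_grid(config$hot_range[1L],
                                                config$hot_range[2L],
                                                config$fine_step),
                      lag = lag_spec(config$max_lag, config$lag_df),
                      strata = config$strata, measure = measure)
  } else {
    coarse_to_fine(series, outcome = cause,
                   cold_range = config$cold_range,
                   hot_range = config$hot_range,
                   coarse_step = config$coarse_step,
                   fine_step = config$fine_step,
                   lag = lag_spec(config$max_lag, config$lag_df),
                   strata = config$strata, measure = measure)
  }
}

cumulative_table_row <- function(fit, side, window, cause) {
  est <- cumulative_effect(fit, paste0("per_degree_",
                                       if (side == "cold") "below_cold"
                                       else "above_hot"), window)
  data.frame(cause = cause, effect = side,
             lag_window = paste(window, collapse = "-"),
             percent_increase = est$percent_increase,
             lo95 = est$ci95[1L], hi95 = est$ci95[2L],
             p_value = est$p_value, significant = est$significant)
}

#' Run the full main analysis for one or more causes
#'
#' For each cause and the chosen temperature measure: fit the spline-DLNM
#' and extract its relative-risk surface and overall (all-lag cumulative)
#' effect curve; search the cold/hot thresholds by residual deviance; refit
#' the double-threshold model at the selected thresholds; extract the
#' per-degree-exceedance lag curves; and tabulate cumulative cold and hot
#' effects over the configured lag windows with two-sided z-tests.
#'
#' @param series a [as_daily_series()] table.
#' @param config an [analysis_config()].
#' @param measure temperature measure used for the main results.
#' @return list per cause: \code{spline_fit}, \code{surface},
#'   \code{overall} (temperature curve of the all-lag cumulative effect),
#'   \code{search}, \code{threshold_fit}, \code{lag_curves},
#'   \code{cumulative} (Table-3-shaped data.frame); plus \code{cumulative}
#'   combined across causes.
#' @export
run_main_analysis <- function(series, config = analysis_config(),
                              measure = "tmean") {
  out <- list()
  cum_all <- list()
  for (cause in config$causes) {
    res <- list()
    res$spline_fit <- fit_ccdlnm(series, spline_cb_spec(config),
                                 outcome = cause, measure = measure,
                                 strata = config$strata)
    res$surface <- predict_surface(res$spline_fit)
    res$overall <- overall_effect_curve(res$spline_fit)
    res$search <- run_threshold_search(series, cause, measure, config)
    res$threshold_fit <- fit_ccdlnm(
      series, threshold_cb_spec(config, res$search$best),
      outcome = cause, measure = measure, strata = config$strata)
    tsurf <- predict_surface(
      res$threshold_fit,
      temp_grid = c(res$search$best$cold_threshold - 1,
                    res$search$best$hot_threshold + 1))
    res$lag_curves <- list(
      cold = lag_slice(tsurf, res$search$best$cold_threshold - 1),
      hot = lag_slice(tsurf, res$search$best$hot_threshold + 1))
    res$cumulative <- do.call(rbind, lapply(config$lag_windows, function(w)
      rbind(cumulative_table_row(res$threshold_fit, "cold", w, cause),
            cumulative_table_row(res$threshold_fit, "hot", w, cause))))
    cum_all[[cause]] <- res$cumulative
    out[[cause]] <- res
  }
  out$cumulative <- do.call(rbind, cum_all)
  rownames(out$cumulative) <- NULL
  out
}

#' Overall (all-lag cumulative) effect across temperature
#'
#' The temperature-response curve of the cumulative effect over all lags,
#' the analogue of an overall-effect plot.
#'
#' @param fit a \code{"cc_fit"} from [fit_ccdlnm()].
#' @param temp_grid temperatures; default 0.1-degree steps over the basis
#'   range.
#' @return data.frame: temperature, rr, lo95, hi95.
#' @export
overall_effect_curve <- function(fit, temp_grid = NULL) {
  spec <- fit$spec
  if (is.null(temp_grid)) {
    rng <- if (inherits(spec$exposure, "spline_spec"))
      spec$exposure$boundary_knots
    else c(spec$exposure$cold_threshold - 5, spec$exposure$hot_threshold + 5)
    temp_grid <- seq(rng[1L], rng[2L], by = 0.1)
  }
  z <- stats::qnorm(0.975)
  blk <- cb_block(fit)
  rows <- lapply(temp_grid, function(x) {
    w <- cumulative_weights(spec, x, c(0L, spec$lag$max_lag))
    est <- drop(w %*% blk$beta)
    se <- sqrt(max(drop(w %*% blk$V %*% w), 0))
    data.frame(temperature = x, rr = exp(est),
               lo95 = exp(est - z * se), hi95 = exp(est + z * se))
  })
  do.call(rbind, rows)
}

#' Sensitivity analysis over strata windows and maximum lags
#'
#' Repeats the cumulative cold/hot estimates of the double-threshold model
#' under each alternative setting (fixed case-crossover windows of 30, 28
#' and 21 days; maximum lags 20 and 30) alongside the baseline, and flags
#' whether each alternative's 95% CI overlaps the baseline's ("similar
#' results" operationalised as CI overlap).
#'
#' @param series a [as_daily_series()] table.
#' @param config an [analysis_config()].
#' @param thresholds a [threshold_spec()] held fixed across settings.
#' @param outcome cause analysed.
#' @param measure temperature measure.
#' @param lag_range lag window of the reported cumulative effects; capped at
#'   each setting's maximum lag.
#' @return data.frame: setting, effect, estimate, lo95, hi95,
#'   overlaps_baseline, plus the per-run configuration fields.
#' @export
sensitivity_analysis <- function(series, config = analysis_config(),
                                 thresholds,
                                 outcome = "nonaccidental",
                                 measure = "tmean",
                                 lag_range = c(0L, 18L)) {
  stopifnot(inherits(thresholds, "threshold_spec"))
  settings <- c(list(list(label = "baseline", strata = config$strata,
                          max_lag = config$max_lag)),
                lapply(config$sensitivity_windows, function(w)
                  list(label = sprintf("window_%dd", w),
                       strata = strata_spec("fixed_window", w),
                       max_lag = config$max_lag)),
                lapply(config$sensitivity_max_lags, function(L)
                  list(label = sprintf("max_lag_%d", L),
                       strata = config$strata, max_lag = L)))
  rows <- lapply(settings, function(s) {
    fit <- fit_ccdlnm(series,
                      threshold_cb_spec(config, thresholds,
                                        max_lag = s$max_lag),
                      outcome = outcome, measure = measure,
                      strata = s$strata)
    lr <- c(lag_range[1L], min(lag_range[2L], s$max_lag))
    do.call(rbind, lapply(c("cold", "hot"), function(side) {
      est <- cumulative_effect(fit, paste0("per_degree_",
                                           if (side == "cold") "below_cold"
                                           else "above_hot"), lr)
      data.frame(setting = s$label, effect = side,
                 estimate = est$percent_increase,
                 lo95 = est$ci95[1L], hi95 = est$ci95[2L],
                 max_lag = s$max_lag,
                 strata_scheme = s$strata$scheme,
                 window_days = if (is.null(s$strata$window_days)) NA_integer_
                 else s$strata$window_days,
                 lag_window = paste(lr, collapse = "-"))
    }))
  })
  out <- do.call(rbind, rows)
  base <- out[out$setting == "baseline", ]
  out$overlaps_baseline <- vapply(seq_len(nrow(out)), function(i) {
    b <- base[base$effect == out$effect[i], ]
    out$lo95[i] <= b$hi95 && out$hi95[i] >= b$lo95
  }, logical(1L))
  rownames(out) <- NULL
  out
}

#' Compare the case-crossover and time-series designs
#'
#' Fits the same cross-basis model with calendar strata (case-crossover) and
#' with a natural cubic spline of time at 7 df/year (time-series) on the
#' same rows, reporting QAIC and the mean absolute deviance residual per
#' design and cause.
#'
#' @param series a [as_daily_series()] table.
#' @param config an [analysis_config()].
#' @param measure temperature measure.
#' @param df_per_year time-spline flexibility of the time-series design.
#' @return data.frame: cause, design, qaic, dispersion,
#'   mean_abs_dev_residual, n_used.
#' @export
compare_designs <- function(series, config = analysis_config(),
                            measure = "tmean", df_per_year = 7) {
  tm <- time_spline_design(series$date, df_per_year)
  rows <- list()
  for (cause in config$causes) {
    for (design in c("case_crossover", "time_series")) {
      strat <- if (design == "case_crossover") config$strata else tm
      fit <- fit_ccdlnm(series, spline_cb_spec(config), outcome = cause,
                        measure = measure, strata = strat)
      y <- series[[cause]][fit$rows]
      mu <- fit$fitted
      dres <- sign(y - mu) * sqrt(pmax(2 * (ifelse(y > 0,
                                                   y * log(y / mu), 0) -
                                              (y - mu)), 0))
      rows[[length(rows) + 1L]] <-
        data.frame(cause = cause, design = design, qaic = fit$qaic,
                   dispersion = fit$dispersion,
                   mean_abs_dev_residual = mean(abs(dres)),
                   n_used = fit$n_used)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
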