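# Time-stratified case-crossover machinery: strata construction, the full
# covariate design around the cross-basis, overdispersed Poisson fitting,
# QAIC, and the equivalent conditional Poisson fit with strata eliminated.

#' Validate and normalise a daily series table
#'
#' Checks the input table for the columns the analysis needs, verifies that
#' dates are consecutive without duplicates and that counts are non-negative
#' integers, and adds a day-of-week factor.
#'
#' @param df a data.frame with columns \code{date} (Date or ISO-8601 string),
#'   death counts (\code{nonaccidental}, \code{cardiopulmonary},
#'   \code{cardiovascular}, \code{respiratory}), temperatures (\code{tmax},
#'   \code{tmean}, \code{tmin}), \code{humidity}, pollutants (\code{pm10},
#'   \code{so2}, \code{no2}), and binary \code{holiday} and \code{influenza}
#'   flags.
#' @return the validated data.frame with a \code{dow} factor column, class
#'   \code{"daily_series"} prepended.
#' @export
as_daily_series <- function(df) {
  needed <- c("date", "nonaccidental", "cardiopulmonary", "cardiovascular",
              "respiratory", "tmax", "tmean", "tmin", "humidity",
              "pm10", "so2", "no2", "holiday", "influenza")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates")
  if (nrow(df) > 1L && !all(diff(as.integer(df$date)) == 1L))
    stop("dates must be consecutive days without duplicates")
  for (v in c("nonaccidental", "cardiopulmonary", "cardiovascular",
              "respiratory")) {
    y <- df[[v]]
    if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
      stop(sprintf("'%s' must be non-negative integer counts", v))
  }
  for (v in c("holiday", "influenza"))
    if (!all(df[[v]] %in% c(0, 1)))
      stop(sprintf("'%s' must be 0/1", v))
  df$dow <- factor(weekdays(df$date, abbreviate = TRUE),
                   levels = weekdays(as.Date("2001-01-01") + 0:6,
                                     abbreviate = TRUE))
  class(df) <- unique(c("daily_series", class(df)))
  df
}

#' Specify the referent-window scheme of the case-crossover
#'
#' Time-stratified case-crossover strata are fixed, disjoint windows that
#' jointly cover the series (avoiding overlap bias): either calendar months
#' within year, or consecutive fixed-length blocks anchored at the first day
#' of the series.
#'
#' @param scheme \code{"calendar_month"} or \code{"fixed_window"}.
#' @param window_days window length in days (e.g. 30, 28 or 21), used only
#'   for \code{scheme = "fixed_window"}.
#' @return an object of class \code{"strata_spec"}.
#' @export
strata_spec <- function(scheme = c("calendar_month", "fixed_window"),
                        window_days = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "fixed_window") {
    if (is.null(window_days) || window_days < 2)
      stop("'window_days' must be given (>= 2) for fixed windows")
    window_days <- as.integer(window_days)
  }
  structure(list(scheme = scheme, window_days = window_days),
            class = "strata_spec")
}

#' Assign each day to its case-crossover stratum
#'
#' @param dates consecutive Date vector.
#' @param spec a [strata_spec()].
#' @return a factor of stratum labels, one per day; labels partition the
#'   series into disjoint windows.
#' @export
make_strata <- function(dates, spec) {
  stopifnot(inherits(spec, "strata_spec"))
  if (length(dates) == 0L) stop("empty date vector")
  dates <- as.Date(dates)
  if (spec$scheme == "calendar_month") {
    lab <- format(dates, "%Y-%m")
  } else {
    lab <- sprintf("w%03d", (seq_along(dates) - 1L) %/% spec$window_days + 1L)
  }
  factor(lab, levels = unique(lab))
}

# Natural cubic spline confounder smooth with interior knots at the 33rd and
# 66th percentiles (quantile placement is the usual choice for confounder
# smooths; equal spacing is reserved for the temperature basis).
confounder_smooth <- function(x, df = 3L, name = "v") {
  kn <- if (df >= 2L)
    unname(stats::quantile(x, probs = seq_len(df - 1L) / df)) else NULL
  m <- splines::ns(x, knots = kn, Boundary.knots = range(x), intercept = FALSE)
  m <- unclass(m)
  attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  colnames(m) <- paste0(name, ".s", seq_len(ncol(m)))
  m
}

#' Assemble the full case-crossover regression design
#'
#' Builds the design matrix: intercept, the cross-basis block, 3-df natural
#' cubic spline smooths of same-day humidity, PM10, SO2 and NO2, day-of-week
#' indicators, the holiday and influenza flags, and reference-coded stratum
#' indicators. Rows with incomplete cross-basis history are excluded; strata
#' emptied by the exclusion contribute no indicator. Covariate columns that
#' are constant on the used rows carry no information and are dropped (they
#' would otherwise alias the intercept); genuine aliasing among the remaining
#' columns is an error.
#'
#' @param series a [as_daily_series()] table.
#' @param crossbasis a built [build_crossbasis()] matrix for the exposure.
#' @param strata stratum factor from [make_strata()].
#' @param outcome which death-count column to model.
#' @return list with elements \code{y} (response), \code{X} (design matrix),
#'   \code{rows} (row indices of \code{series} used), \code{strata} (factor
#'   on used rows), \code{cb_index} (column indices of the cross-basis block
#'   in \code{X}), \code{dropped} (names of constant columns removed).
#' @export
build_design <- function(series, crossbasis, strata,
                         outcome = "nonaccidental") {
  stopifnot(inherits(crossbasis, "crossbasis"))
  if (!outcome %in% names(series)) stop("unknown outcome column: ", outcome)
  n <- nrow(series)
  if (n != nrow(crossbasis) || n != length(strata))
    stop("series, crossbasis and strata must be aligned by day")
  rows <- attr(crossbasis, "valid_from"):n
  y <- series[[outcome]][rows]
  cb <- unclass(crossbasis)[rows, , drop = FALSE]

  sm <- do.call(cbind, lapply(c("humidity", "pm10", "so2", "no2"), function(v)
    confounder_smooth(series[[v]][rows], df = 3L, name = v)))
  dw <- stats::model.matrix(~dow, data = droplevels(series[rows, , drop = FALSE]))
  dw <- dw[, -1L, drop = FALSE]  # reference-coded weekday indicators
  flags <- cbind(holiday = series$holiday[rows],
                 influenza = series$influenza[rows])
  st <- droplevels(strata[rows])
  stm <- if (nlevels(st) > 1L) {
    m <- stats::model.matrix(~st)[, -1L, drop = FALSE]
    colnames(m) <- paste0("strata.", levels(st)[-1L])
    m
  } else NULL

  X <- cbind("(Intercept)" = 1, cb, sm, dw, flags, stm)
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L,
                        function(col) diff(range(col)) > 0))
  dropped <- colnames(X)[!keep]
  cb_keep <- keep[1L + seq_len(ncol(cb))]
  if (!all(cb_keep))
    stop("cross-basis columns constant on the used rows: ",
         paste(colnames(cb)[!cb_keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design is rank deficient; aliased columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]],
               collapse = ", "))
  list(y = y, X = X, rows = rows, strata = st,
       cb_index = 1L + seq_len(ncol(cb)), dropped = dropped)
}

#' Fit an overdispersed (quasi-Poisson) log-linear model
#'
#' Poisson log-link fit by iteratively reweighted least squares, with the
#' dispersion estimated from the Pearson statistic,
#' \eqn{\hat\phi = \chi^2_P / (n - p)}, and the coefficient covariance scaled
#' as \eqn{\hat\phi (X'WX)^{-1}}. The Poisson log-likelihood, residual
#' deviance and QAIC are reported alongside.
#'
#' @param y non-negative integer counts.
#' @param X full-rank design matrix (including the intercept).
#' @param epsilon,maxit IRLS convergence control: relative deviance change
#'   below \code{epsilon} (default 1e-9) within \code{maxit} iterations.
#' @return an object of class \code{"cc_fit"}: \code{coefficients},
#'   \code{covariance}, \code{dispersion}, \code{loglik}, \code{deviance},
#'   \code{qaic}, \code{n_used}, \code{rank}, \code{fitted}.
#' @export
fit_quasipoisson <- function(y, X, epsilon = 1e-9, maxit = 100L) {
  if (any(y < 0)) stop("negative counts")
  X <- as.matrix(X)
  fit <- stats::glm.fit(X, y, family = stats::poisson(),
                        control = stats::glm.control(epsilon = epsilon,
                                                     maxit = maxit))
  if (!fit$converged)
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.6g)",
                 fit$iter, fit$deviance))
  p <- fit$rank
  if (p < ncol(X))
    stop("design not full rank inside the IRLS fit")
  n <- length(y)
  mu <- fit$fitted.values
  pearson <- sum((y - mu)^2 / mu)
  phi <- if (n > p) pearson / (n - p) else NaN
  p1 <- seq_len(p)
  cov_unscaled <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  piv <- fit$qr$pivot[p1]
  covariance <- matrix(NA_real_, p, p)
  covariance[piv, piv] <- cov_unscaled
  covariance <- phi * covariance
  dimnames(covariance) <- list(colnames(X), colnames(X))
  coefs <- fit$coefficients
  names(coefs) <- colnames(X)
  loglik <- sum(stats::dpois(y, mu, log = TRUE))
  structure(list(coefficients = coefs, covariance = covariance,
                 dispersion = phi, loglik = loglik,
                 deviance = fit$deviance, qaic = -2 * loglik + 2 * phi * p,
                 n_used = n, rank = p, fitted = mu, iter = fit$iter),
            class = "cc_fit")
}

#' Quasi-Poisson Akaike information criterion
#'
#' \eqn{QAIC = -2 \log L + 2 \hat\phi p}, the AIC for quasi-Poisson models
#' with the penalty inflated by the estimated dispersion; reduces to the
#' ordinary AIC when \eqn{\hat\phi = 1}.
#'
#' @param fit a \code{"cc_fit"}.
#' @return numeric QAIC.
#' @export
qaic <- function(fit) {
  stopifnot(inherits(fit, "cc_fit"))
  -2 * fit$loglik + 2 * fit$dispersion * fit$rank
}

#' Conditional Poisson fit with stratum intercepts eliminated
#'
#' Maximises the Poisson likelihood profiled over the stratum intercepts
#' (equivalently, the within-stratum multinomial likelihood of the
#' case-crossover) by Newton-Raphson. The slope estimates and their
#' dispersion-scaled covariance coincide with those from the stratified
#' indicator fit; strata whose total count is zero carry no information and
#' are dropped.
#'
#' @param y counts.
#' @param X design matrix WITHOUT intercept and WITHOUT stratum indicators.
#' @param strata stratum factor aligned with \code{y}.
#' @param tol convergence tolerance on the maximum score component.
#' @param maxit maximum Newton iterations.
#' @return an object of class \code{"cc_condfit"}: \code{coefficients},
#'   \code{covariance} (dispersion-scaled), \code{dispersion},
#'   \code{loglik_conditional}, \code{n_used}.
#' @export
fit_conditional <- function(y, X, strata, tol = 1e-10, maxit = 50L) {
  if (any(y < 0)) stop("negative counts")
  X <- as.matrix(X)
  strata <- droplevels(factor(strata))
  tot <- tapply(y, strata, sum)
  keep_s <- names(tot)[tot > 0]
  keep <- strata %in% keep_s
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  strata <- droplevels(strata[keep])
  si <- as.integer(strata)
  Ys <- as.vector(tapply(y, strata, sum))
  p <- ncol(X)
  beta <- numeric(p)
  xty <- crossprod(X, y)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    eta_max <- as.vector(tapply(eta, strata, max))[si]
    ew <- exp(eta - eta_max)
    denom <- as.vector(rowsum(ew, si))
    w <- ew / denom[si]                     # within-stratum probabilities
    ll <- sum(y * eta) - sum(Ys * (log(denom) + as.vector(tapply(eta, strata, max))))
    M1 <- rowsum(w * X, si)                 # S x p stratum-weighted means
    score <- xty - crossprod(M1, Ys)
    WX <- X * (Ys[si] * w)
    info <- crossprod(X, WX) - crossprod(M1 * sqrt(Ys))
    step <- solve(info, score)
    # step halving on the conditional log-likelihood
    ok <- FALSE
    for (h in 0:20) {
      beta_new <- beta + drop(step) / 2^h
      eta_n <- drop(X %*% beta_new)
      em <- as.vector(tapply(eta_n, strata, max))
      dn <- as.vector(rowsum(exp(eta_n - em[si]), si))
      ll_new <- sum(y * eta_n) - sum(Ys * (log(dn) + em))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) stop("conditional fit: step halving failed")
    beta <- beta_new
    if (max(abs(score)) < tol || abs(ll_new - ll_old) < tol * (abs(ll) + 1))
      break
    ll_old <- ll_new
  }
  # dispersion and covariance on the final weights
  eta <- drop(X %*% beta)
  em <- as.vector(tapply(eta, strata, max))
  ew <- exp(eta - em[si])
  w <- ew / as.vector(rowsum(ew, si))[si]
  mu <- Ys[si] * w
  n <- length(y)
  phi <- sum((y - mu)^2 / mu) / (n - p - nlevels(strata))
  M1 <- rowsum(w * X, si)
  info <- crossprod(X, X * mu) - crossprod(M1 * sqrt(Ys))
  covariance <- phi * solve(info)
  dimnames(covariance) <- list(colnames(X), colnames(X))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, covariance = covariance,
                 dispersion = phi, loglik_conditional = ll_new,
                 n_used = n, fitted = mu),
            class = "cc_condfit")
}

#' Natural cubic spline of time for the time-series comparison design
#'
#' Smooth control for season and trend in the conventional time-series
#' alternative to the case-crossover: a natural cubic spline of the day index
#' with \code{round(df_per_year * n_years)} degrees of freedom.
#'
#' @param dates consecutive Date vector.
#' @param df_per_year degrees of freedom per year (7 in the design
#'   comparison).
#' @return basis matrix with one row per day.
#' @export
time_spline_design <- function(dates, df_per_year = 7) {
  stopifnot(df_per_year > 0)
  n <- length(dates)
  n_years <- n / 365.25
  df <- max(1L, as.integer(round(df_per_year * n_years)))
  idx <- seq_len(n)
  m <- if (df == 1L) matrix(idx - mean(idx), ncol = 1L)
  else unclass(splines::ns(idx, df = df, intercept = FALSE))
  attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  colnames(m) <- paste0("time.s", seq_len(ncol(m)))
  m
}

#' Fit a case-crossover DLNM in one step
#'
#' Convenience wrapper: builds the cross-basis for the chosen temperature
#' measure, the strata and the full covariate design, and fits the
#' quasi-Poisson model. The returned fit carries the realized cross-basis
#' spec and the position of the cross-basis block, which the effect-summary
#' functions need.
#'
#' @param series a [as_daily_series()] table.
#' @param cb_spec a [crossbasis_spec()].
#' @param outcome death-count column to model.
#' @param measure temperature column used as the exposure.
#' @param strata a [strata_spec()] (time-stratified case-crossover), or a
#'   numeric matrix of time-smooth columns from [time_spline_design()] for
#'   the time-series comparison design.
#' @return a \code{"cc_fit"} with elements \code{spec} (realized
#'   [crossbasis_spec()]) and \code{cb_index} added.
#' @export
fit_ccdlnm <- function(series, cb_spec, outcome = "nonaccidental",
                       measure = "tmean",
                       strata = strata_spec("calendar_month")) {
  cb <- build_crossbasis(series[[measure]], cb_spec)
  if (inherits(strata, "strata_spec")) {
    st <- make_strata(series$date, strata)
    d <- build_design(series, cb, st, outcome = outcome)
  } else {
    # time-series design: replace stratum indicators by a smooth of time
    st <- factor(rep("all", nrow(series)))
    d <- build_design(series, cb, st, outcome = outcome)
    tm <- as.matrix(strata)[d$rows, , drop = FALSE]
    d$X <- cbind(d$X, tm)
  }
  fit <- fit_quasipoisson(d$y, d$X)
  fit$spec <- attr(cb, "spec")
  fit$cb_index <- d$cb_index
  fit$rows <- d$rows
  fit$outcome <- outcome
  fit$measure <- measure
  fit
}
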