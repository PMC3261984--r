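# Effect summaries of a fitted cross-basis model: relative-risk surfaces over
# temperature and lag, one-dimensional slices, and cumulative effects over
# lag windows with delta-method confidence intervals.

cb_block <- function(fit) {
  if (is.null(fit$cb_index) || is.null(fit$spec))
    stop("fit carries no cross-basis block; use fit_ccdlnm()")
  list(beta = fit$coefficients[fit$cb_index],
       V = fit$covariance[fit$cb_index, fit$cb_index, drop = FALSE])
}

#' Predict the relative-risk surface over temperature and lag
#'
#' Evaluates the fitted log relative risk \eqn{w(x, l)'\hat\beta} and its
#' delta-method standard error on a grid of temperatures and integer lags,
#' relative to the centering temperature (RR = 1 at the center, every lag).
#' Temperatures beyond the spline's boundary knots are evaluated by the
#' basis' linear extrapolation and flagged.
#'
#' @param fit a \code{"cc_fit"} from [fit_ccdlnm()].
#' @param temp_grid numeric temperatures; default 0.1 degree steps over the
#'   basis range.
#' @param lag_grid integer lags; default \code{0:max_lag}.
#' @return an object of class \code{"effect_surface"}: \code{temperatures},
#'   \code{lags}, matrices \code{log_rr}, \code{se}, \code{rr},
#'   \code{center}, and logical \code{extrapolated} per temperature.
#' @export
predict_surface <- function(fit, temp_grid = NULL, lag_grid = NULL) {
  stopifnot(inherits(fit, "cc_fit"))
  spec <- fit$spec
  blk <- cb_block(fit)
  if (is.null(lag_grid)) lag_grid <- 0:spec$lag$max_lag
  if (is.null(temp_grid)) {
    rng <- if (inherits(spec$exposure, "spline_spec"))
      spec$exposure$boundary_knots
    else c(spec$exposure$cold_threshold - 5, spec$exposure$hot_threshold + 5)
    temp_grid <- seq(rng[1L], rng[2L], by = 0.1)
  }
  extrapolated <- if (inherits(spec$exposure, "spline_spec"))
    temp_grid < spec$exposure$boundary_knots[1L] |
      temp_grid > spec$exposure$boundary_knots[2L]
  else rep(FALSE, length(temp_grid))
  if (any(extrapolated))
    warning("temperatures outside the basis boundary evaluated by linear extrapolation")
  log_rr <- matrix(0, length(temp_grid), length(lag_grid))
  se <- matrix(0, length(temp_grid), length(lag_grid))
  dR <- exposure_basis(temp_grid, spec$exposure)
  dR <- sweep(dR, 2L, as.vector(exposure_basis(spec$center, spec$exposure)))
  B <- lag_basis(spec$lag, lags = lag_grid)
  J <- ncol(dR); K <- ncol(B)
  for (li in seq_along(lag_grid)) {
    # weight rows for all temperatures at this lag, exposure-major columns
    W <- dR[, rep(seq_len(J), each = K), drop = FALSE] *
      matrix(rep(B[li, ], J), nrow(dR), J * K, byrow = TRUE)
    log_rr[, li] <- W %*% blk$beta
    se[, li] <- sqrt(pmax(rowSums((W %*% blk$V) * W), 0))
  }
  dimnames(log_rr) <- dimnames(se) <-
    list(format(temp_grid), paste0("lag", lag_grid))
  structure(list(temperatures = temp_grid, lags = lag_grid,
                 log_rr = log_rr, se = se, rr = exp(log_rr),
                 center = spec$center, extrapolated = extrapolated),
            class = "effect_surface")
}

grid_match <- function(grid, value, what) {
  i <- which(abs(grid - value) < 1e-8)
  if (length(i) != 1L) {
    near <- grid[which.min(abs(grid - value))]
    stop(sprintf("%s %.6g is not on the grid (nearest grid value: %.6g)",
                 what, value, near))
  }
  i
}

#' Per-lag relative-risk curve at one temperature
#'
#' Extracts the lag profile of the surface at the requested temperature,
#' which must be on the surface grid (no silent interpolation). For
#' double-threshold models, evaluating 1 degree beyond a threshold gives the
#' per-degree-exceedance lag curve.
#'
#' @param surface an \code{"effect_surface"}.
#' @param at_temperature temperature on the surface grid.
#' @return data.frame: \code{lag}, \code{rr}, \code{lo95}, \code{hi95},
#'   \code{log_rr}, \code{se}.
#' @export
lag_slice <- function(surface, at_temperature) {
  stopifnot(inherits(surface, "effect_surface"))
  i <- grid_match(surface$temperatures, at_temperature, "temperature")
  z <- stats::qnorm(0.975)
  lr <- surface$log_rr[i, ]; s <- surface$se[i, ]
  data.frame(lag = surface$lags, rr = exp(lr),
             lo95 = exp(lr - z * s), hi95 = exp(lr + z * s),
             log_rr = unname(lr), se = unname(s), row.names = NULL)
}

#' Relative risk across temperature at one lag
#'
#' @param surface an \code{"effect_surface"}.
#' @param at_lag integer lag on the surface grid.
#' @return data.frame: \code{temperature}, \code{rr}, \code{lo95},
#'   \code{hi95}, \code{log_rr}, \code{se}.
#' @export
temp_slice <- function(surface, at_lag) {
  stopifnot(inherits(surface, "effect_surface"))
  i <- grid_match(surface$lags, at_lag, "lag")
  z <- stats::qnorm(0.975)
  lr <- surface$log_rr[, i]; s <- surface$se[, i]
  data.frame(temperature = surface$temperatures, rr = exp(lr),
             lo95 = exp(lr - z * s), hi95 = exp(lr + z * s),
             log_rr = unname(lr), se = unname(s), row.names = NULL)
}

#' Cumulative effect over a lag window
#'
#' Sums the fitted log relative risks over the lag window into a single
#' linear combination of coefficients, so the point estimate and its
#' delta-method variance come from one weight vector. Reported as a percent
#' increase in mortality, \eqn{100(\exp(\sum_l \log RR_l) - 1)}, with a 95%
#' normal-theory interval on the log-RR scale. The estimand is either the
#' effect at a given temperature relative to the center, or (for
#' double-threshold models) the effect per 1 degree Celsius decrease below
#' the cold threshold / increase above the hot threshold.
#'
#' @param fit a \code{"cc_fit"} from [fit_ccdlnm()].
#' @param estimand \code{list(at_temperature = x)}, or the strings
#'   \code{"per_degree_below_cold"} / \code{"per_degree_above_hot"}
#'   (threshold exposure only).
#' @param lag_range integer pair \code{c(l0, l1)} within \code{0..max_lag}.
#' @return an object of class \code{"cumulative_effect"}: \code{lag_range},
#'   \code{estimand}, \code{log_rr}, \code{se}, \code{percent_increase},
#'   \code{ci95} (percent scale), \code{p_value} (two-sided z-test),
#'   \code{significant} (p < 0.05).
#' @export
cumulative_effect <- function(fit, estimand, lag_range) {
  stopifnot(inherits(fit, "cc_fit"))
  spec <- fit$spec
  at <- if (is.list(estimand)) {
    estimand$at_temperature
  } else if (identical(estimand, "per_degree_below_cold")) {
    if (!inherits(spec$exposure, "threshold_spec"))
      stop("per-degree estimands need a threshold exposure basis")
    spec$exposure$cold_threshold - 1
  } else if (identical(estimand, "per_degree_above_hot")) {
    if (!inherits(spec$exposure, "threshold_spec"))
      stop("per-degree estimands need a threshold exposure basis")
    spec$exposure$hot_threshold + 1
  } else stop("unknown estimand")
  w <- cumulative_weights(spec, at, lag_range)
  blk <- cb_block(fit)
  est <- drop(w %*% blk$beta)
  se <- sqrt(max(drop(w %*% blk$V %*% w), 0))
  z <- stats::qnorm(0.975)
  pval <- if (se > 0) 2 * stats::pnorm(-abs(est / se)) else as.numeric(est != 0)
  structure(list(lag_range = as.integer(lag_range), estimand = estimand,
                 log_rr = est, se = se,
                 percent_increase = 100 * (exp(est) - 1),
                 ci95 = 100 * (exp(c(est - z * se, est + z * se)) - 1),
                 p_value = pval, significant = pval < 0.05),
            class = "cumulative_effect")
}

#' @export
print.cumulative_effect <- function(x, ...) {
  lab <- if (is.list(x$estimand))
    sprintf("at %.1f C", x$estimand$at_temperature) else x$estimand
  cat(sprintf("Cumulative effect (%s), lags %d-%d: %.2f%% (95%% CI %.2f, %.2f)%s\n",
              lab, x$lag_range[1L], x$lag_range[2L], x$percent_increase,
              x$ci95[1L], x$ci95[2L], if (x$significant) " *" else ""))
  invisible(x)
}
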