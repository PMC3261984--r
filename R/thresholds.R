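# Grid search for the cold/hot threshold pair of the double-threshold DLNM,
# minimizing the residual deviance of the full stratified model.

#' Candidate threshold grid
#'
#' Regular grid from \code{lo} to \code{hi} in steps of \code{step},
#' inclusive of both endpoints (e.g. -5.0 to 5.0 by 0.1 gives 101
#' candidates).
#'
#' @param lo,hi grid endpoints in degrees Celsius.
#' @param step positive step.
#' @return numeric vector of candidate thresholds.
#' @export
threshold_grid <- function(lo, hi, step) {
  if (step <= 0) stop("'step' must be positive")
  if (lo > hi) stop("'lo' must not exceed 'hi'")
  k <- round((hi - lo) / step)
  lo + step * 0:k
}

# Precompute everything of the design that does not depend on the
# thresholds: the lagged exposure matrix, the lag basis, and the covariate
# block. Each candidate pair then costs one hinge transform, two matrix
# products and one IRLS fit.
threshold_search_context <- function(series, outcome, measure, lag, strata) {
  x <- series[[measure]]
  L <- lag$max_lag
  n <- length(x)
  if (n <= L) stop("series too short for the lag structure")
  rows <- (L + 1L):n
  XL <- sapply(0:L, function(l) x[rows - l])          # |rows| x (L+1)
  B <- lag_basis(lag)                                  # (L+1) x K
  st <- make_strata(series$date, strata)
  # covariate block via a dummy linear cross-basis (replaced per cell)
  dummy <- crossbasis_spec(spline_spec(1L), lag)
  cbd <- build_crossbasis(x, dummy)
  d <- build_design(series, cbd, st, outcome = outcome)
  Xcov <- d$X[, -d$cb_index, drop = FALSE]
  list(y = d$y, Xcov = Xcov, XL = XL, B = B, lag = lag, rows = rows)
}

fit_threshold_cell <- function(ctx, cold, hot, start = NULL) {
  TC <- pmax(cold - ctx$XL, 0) %*% ctx$B
  TH <- pmax(ctx$XL - hot, 0) %*% ctx$B
  K <- ncol(ctx$B)
  cbcols <- cbind(TC, TH)
  colnames(cbcols) <- c(paste0("cb.cold.l", seq_len(K)),
                        paste0("cb.hot.l", seq_len(K)))
  X <- cbind(cbcols, ctx$Xcov)
  fit <- suppressWarnings(
    stats::glm.fit(X, ctx$y, family = stats::poisson(), start = start,
                   control = stats::glm.control(epsilon = 1e-9, maxit = 100)))
  if ((!fit$converged || fit$rank < ncol(X)) && !is.null(start))
    fit <- suppressWarnings(
      stats::glm.fit(X, ctx$y, family = stats::poisson(),
                     control = stats::glm.control(epsilon = 1e-9, maxit = 100)))
  if (!fit$converged || fit$rank < ncol(X)) return(NULL)
  fit
}

#' Exhaustive threshold search by residual deviance
#'
#' Refits the full double-threshold model (cross-basis, covariate smooths,
#' day-of-week, holiday, influenza and stratum indicators) at every
#' cold/hot candidate pair and returns the pair minimizing the residual
#' deviance. Ties are broken deterministically towards the smallest cold and
#' then the smallest hot threshold. Cells where the fit fails are flagged
#' and excluded from the minimization.
#'
#' @param series a [as_daily_series()] table.
#' @param outcome death-count column.
#' @param cold_grid,hot_grid numeric candidate vectors (see
#'   [threshold_grid()]); every cold candidate must lie below every hot
#'   candidate.
#' @param lag a [lag_spec()].
#' @param strata a [strata_spec()].
#' @param measure temperature column searched over.
#' @return an object of class \code{"threshold_search"}: \code{best} (a
#'   [threshold_spec()]), \code{deviance_grid} (data.frame cold, hot,
#'   residual_deviance, failed), \code{n_fits}.
#' @export
search_thresholds <- function(series, outcome = "nonaccidental",
                              cold_grid, hot_grid,
                              lag = lag_spec(27L, 4L),
                              strata = strata_spec("calendar_month"),
                              measure = "tmean") {
  if (max(cold_grid) >= min(hot_grid))
    stop("cold grid must lie entirely below the hot grid")
  ctx <- threshold_search_context(series, outcome, measure, lag, strata)
  grid <- expand.grid(cold = cold_grid, hot = hot_grid,
                      KEEP.OUT.ATTRS = FALSE)
  dev <- rep(NA_real_, nrow(grid))
  start <- NULL
  for (i in seq_len(nrow(grid))) {
    f <- fit_threshold_cell(ctx, grid$cold[i], grid$hot[i], start = start)
    if (!is.null(f)) {
      dev[i] <- f$deviance
      start <- f$coefficients
    }
  }
  finish_search(grid, dev, refine = NULL)
}

finish_search <- function(grid, dev, refine) {
  failed <- is.na(dev)
  if (all(failed)) stop("threshold search failed at every grid cell")
  dg <- data.frame(cold = grid$cold, hot = grid$hot,
                   residual_deviance = dev, failed = failed)
  ok <- which(!failed)
  # deterministic tie-break: smallest deviance, then smallest cold, then hot
  o <- ok[order(dev[ok], grid$cold[ok], grid$hot[ok])]
  best <- o[1L]
  structure(list(best = threshold_spec(grid$cold[best], grid$hot[best]),
                 deviance_grid = dg, n_fits = nrow(grid),
                 min_deviance = dev[best], refine = refine),
            class = "threshold_search")
}

#' Coarse-to-fine threshold search
#'
#' A faster two-stage search: a coarse pass over the full ranges, then a
#' fine pass restricted to +/- one coarse step around the coarse optimum.
#' Matches the exhaustive search whenever the deviance surface is unimodal;
#' on multimodal surfaces it may settle in the wrong basin, so the
#' exhaustive mode remains the reference.
#'
#' @inheritParams search_thresholds
#' @param cold_range,hot_range length-2 numeric ranges in degrees Celsius.
#' @param coarse_step,fine_step grid steps of the two passes.
#' @return a \code{"threshold_search"}; \code{n_fits} counts both passes and
#'   \code{refine} records the fine-pass window.
#' @export
coarse_to_fine <- function(series, outcome = "nonaccidental",
                           cold_range = c(-5, 5), hot_range = c(19, 29),
                           coarse_step = 1, fine_step = 0.1,
                           lag = lag_spec(27L, 4L),
                           strata = strata_spec("calendar_month"),
                           measure = "tmean") {
  ctx <- threshold_search_context(series, outcome, measure, lag, strata)
  run <- function(cg, hg, start) {
    grid <- expand.grid(cold = cg, hot = hg, KEEP.OUT.ATTRS = FALSE)
    dev <- rep(NA_real_, nrow(grid))
    for (i in seq_len(nrow(grid))) {
      f <- fit_threshold_cell(ctx, grid$cold[i], grid$hot[i], start = start)
      if (!is.null(f)) { dev[i] <- f$deviance; start <- f$coefficients }
    }
    list(grid = grid, dev = dev)
  }
  c1 <- run(threshold_grid(cold_range[1L], cold_range[2L], coarse_step),
            threshold_grid(hot_range[1L], hot_range[2L], coarse_step), NULL)
  coarse <- finish_search(c1$grid, c1$dev, refine = NULL)
  cw <- c(max(cold_range[1L], coarse$best$cold_threshold - coarse_step),
          min(cold_range[2L], coarse$best$cold_threshold + coarse_step))
  hw <- c(max(hot_range[1L], coarse$best$hot_threshold - coarse_step),
          min(hot_range[2L], coarse$best$hot_threshold + coarse_step))
  c2 <- run(threshold_grid(cw[1L], cw[2L], fine_step),
            threshold_grid(hw[1L], hw[2L], fine_step), NULL)
  grid <- rbind(c1$grid, c2$grid)
  dev <- c(c1$dev, c2$dev)
  res <- finish_search(grid, dev,
                       refine = list(cold_window = cw, hot_window = hw))
  res
}
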