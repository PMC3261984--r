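# Cross-basis construction: the tensor of an exposure basis and a lag basis,
# giving the design-matrix block whose coefficients describe the full
# exposure-lag-response surface.

#' Specify a cross-basis
#'
#' Combines an exposure basis (natural cubic spline or double threshold) with
#' a lag basis into the recipe for the cross-basis block of the regression
#' design. The centering temperature is the reference against which relative
#' risks are computed; by convention the median of the observed series.
#'
#' @param exposure a [spline_spec()] or [threshold_spec()].
#' @param lag a [lag_spec()].
#' @param center centering temperature in degrees Celsius, or \code{NA} to
#'   take the median of the series when the basis is built.
#' @return an object of class \code{"crossbasis_spec"}.
#' @export
crossbasis_spec <- function(exposure, lag, center = NA_real_) {
  if (!inherits(exposure, "spline_spec") && !inherits(exposure, "threshold_spec"))
    stop("'exposure' must be a spline_spec or threshold_spec")
  stopifnot(inherits(lag, "lag_spec"))
  structure(list(exposure = exposure, lag = lag, center = center),
            class = "crossbasis_spec")
}

# Complete a crossbasis_spec against observed exposures: fill boundary knots
# from the data range, default interior knots to equal spacing, and default
# the centering value to the observed median.
realize_spec <- function(spec, x) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  ex <- spec$exposure
  if (inherits(ex, "spline_spec") && is.null(ex$boundary_knots)) {
    ex <- spline_spec(ex$df, interior_knots = ex$interior_knots,
                      boundary_knots = range(x))
  }
  if (is.na(spec$center)) spec$center <- stats::median(x)
  spec$exposure <- ex
  spec
}

#' Build the cross-basis design block for a daily exposure series
#'
#' Entry for day \code{t} and column \code{(j, k)} is
#' \deqn{\sum_{l=0}^{L} R_j(x_{t-l}) B_k(l),}
#' where \eqn{R_j} are the exposure-basis columns and \eqn{B_k} the lag-basis
#' columns. The first \code{max_lag} rows have incomplete exposure history;
#' they are filled with \code{NA} and flagged so that model fitting excludes
#' them rather than imputing.
#'
#' @param x numeric vector of daily exposures (one value per consecutive day).
#' @param spec a [crossbasis_spec()]; spline boundary knots and the centering
#'   value are completed from \code{x} if unset.
#' @return a numeric matrix of class \code{"crossbasis"} with attributes
#'   \code{spec} (the realized spec) and \code{valid_from} (1-based index of
#'   the first complete row, \code{max_lag + 1}).
#' @export
build_crossbasis <- function(x, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  L <- spec$lag$max_lag
  n <- length(x)
  if (n <= L)
    stop(sprintf("series of length %d is too short for max_lag %d", n, L))
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("non-finite exposure value at index %d", bad[1L]))
  spec <- realize_spec(spec, x)
  R <- exposure_basis(x, spec$exposure)            # n x J
  B <- lag_basis(spec$lag)                         # (L+1) x K
  J <- ncol(R); K <- ncol(B)
  cb <- matrix(0, n, J * K)
  for (l in 0:L) {
    rows <- (l + 1L):n
    Rl <- R[rows - l, , drop = FALSE]
    # exposure-major ordering: columns (j-1)*K + k
    cb[rows, ] <- cb[rows, ] + Rl[, rep(seq_len(J), each = K), drop = FALSE] *
      rep(B[l + 1L, ], J)[col(cb[rows, , drop = FALSE])]
  }
  if (L > 0L) cb[seq_len(L), ] <- NA_real_
  colnames(cb) <- paste0("cb.", rep(colnames(R), each = K), ".",
                         rep(colnames(B), J))
  structure(cb, spec = spec, valid_from = L + 1L, class = c("crossbasis", "matrix"))
}

#' Coefficient weights for the effect at one temperature and lag
#'
#' Returns the vector \eqn{w(x, l)} with components
#' \eqn{[R_j(x) - R_j(x_0)] B_k(l)} (centering value \eqn{x_0}), so that the
#' fitted log relative risk at temperature \code{at} and lag \code{lag} is
#' \code{sum(w * beta)} and its variance the quadratic form of \code{w} with
#' the coefficient covariance block.
#'
#' @param spec a realized [crossbasis_spec()] (as stored on a built
#'   cross-basis or a fit).
#' @param at temperature in degrees Celsius.
#' @param lag integer lag in \code{0..max_lag}.
#' @return numeric weight vector of length \code{n_exposure_cols * lag_df}.
#' @export
crossbasis_weights <- function(spec, at, lag) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  if (length(lag) != 1L || lag < 0L || lag > spec$lag$max_lag)
    stop("lag out of range 0..max_lag")
  dR <- exposure_basis(at, spec$exposure) -
    exposure_basis(spec$center, spec$exposure)
  B <- lag_basis(spec$lag, lags = lag)
  as.vector(t(outer(as.vector(dR), as.vector(B))))  # exposure-major
}

#' Summed coefficient weights over a lag window
#'
#' The cumulative (overall) effect over lags \code{l0..l1} is the sum of the
#' per-lag log relative risks; its weight vector is the sum of the per-lag
#' weight vectors, an exact identity used by [cumulative_effect()].
#'
#' @inheritParams crossbasis_weights
#' @param lag_range integer pair \code{c(l0, l1)} within \code{0..max_lag}.
#' @return numeric weight vector.
#' @export
cumulative_weights <- function(spec, at, lag_range) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  lag_range <- as.integer(lag_range)
  if (length(lag_range) != 2L || lag_range[1L] > lag_range[2L])
    stop("empty lag range")
  if (lag_range[1L] < 0L || lag_range[2L] > spec$lag$max_lag)
    stop("lag range outside 0..max_lag")
  lags <- lag_range[1L]:lag_range[2L]
  dR <- exposure_basis(at, spec$exposure) -
    exposure_basis(spec$center, spec$exposure)
  B <- lag_basis(spec$lag, lags = lags)
  Bsum <- colSums(B)
  as.vector(t(outer(as.vector(dR), Bsum)))
}
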