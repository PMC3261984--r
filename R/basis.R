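# One-dimensional basis constructions for the exposure and lag dimensions:
# natural cubic splines with explicit knots, linear-threshold (hockey-stick)
# transforms, and the knot-placement rules used for temperature and lag.

#' Specify a natural cubic spline basis
#'
#' A spline specification fixes the interior and boundary knots of a natural
#' cubic spline so that the identical basis can be evaluated on the observed
#' series and, later, on arbitrary prediction values. The number of basis
#' columns (without intercept) equals the number of interior knots plus one,
#' which is the degrees of freedom \code{df}.
#'
#' @param df positive integer; number of basis columns.
#' @param interior_knots strictly increasing numeric vector of interior knots,
#'   strictly inside \code{boundary_knots}. Defaults to equally spaced knots
#'   via [equally_spaced_knots()] when \code{boundary_knots} is given.
#' @param boundary_knots length-2 numeric; the range over which the spline is
#'   cubic. Values beyond it are extrapolated linearly. May be left \code{NULL}
#'   and completed from data by [build_crossbasis()].
#' @return an object of class \code{"spline_spec"}.
#' @seealso [ns_basis()], [threshold_spec()], [lag_spec()]
#' @export
spline_spec <- function(df, interior_knots = NULL, boundary_knots = NULL) {
  df <- as.integer(df)
  if (length(df) != 1L || is.na(df) || df < 1L)
    stop("'df' must be a positive integer")
  if (!is.null(boundary_knots)) {
    if (length(boundary_knots) != 2L || !all(is.finite(boundary_knots)) ||
        boundary_knots[1L] >= boundary_knots[2L])
      stop("'boundary_knots' must be two finite increasing values")
    if (is.null(interior_knots))
      interior_knots <- equally_spaced_knots(boundary_knots[1L],
                                             boundary_knots[2L], df)
  }
  if (!is.null(interior_knots)) {
    if (length(interior_knots) != df - 1L)
      stop(sprintf("a %d-df natural spline needs %d interior knots, got %d",
                   df, df - 1L, length(interior_knots)))
    if (df > 2L && any(diff(interior_knots) <= 0))
      stop("'interior_knots' must be strictly increasing")
    if (!is.null(boundary_knots) && length(interior_knots) &&
        (min(interior_knots) <= boundary_knots[1L] ||
         max(interior_knots) >= boundary_knots[2L]))
      stop("interior knots must lie strictly inside the boundary knots")
  }
  structure(list(df = df, interior_knots = interior_knots,
                 boundary_knots = boundary_knots),
            class = "spline_spec")
}

#' Specify a double-threshold (hockey-stick) exposure basis
#'
#' Encodes the assumption that log-mortality is linear in temperature below a
#' cold threshold and above a hot threshold, and flat in the comfort band
#' between them. The two basis columns are the cold exceedance
#' \eqn{\max(c - x, 0)} and the hot exceedance \eqn{\max(x - h, 0)}, so a
#' coefficient on the cold column is the log relative risk per 1 degree
#' Celsius decrease below the cold threshold.
#'
#' @param cold_threshold,hot_threshold temperatures in degrees Celsius with
#'   \code{cold_threshold < hot_threshold}.
#' @return an object of class \code{"threshold_spec"}.
#' @export
threshold_spec <- function(cold_threshold, hot_threshold) {
  if (!is.finite(cold_threshold) || !is.finite(hot_threshold))
    stop("thresholds must be finite")
  if (cold_threshold >= hot_threshold)
    stop("'cold_threshold' must be below 'hot_threshold'")
  structure(list(cold_threshold = cold_threshold,
                 hot_threshold = hot_threshold),
            class = "threshold_spec")
}

#' Specify the lag basis of a cross-basis
#'
#' The lag dimension runs over integer lags \code{0..max_lag}. Two kinds are
#' supported: \code{"ns_log"}, a natural cubic spline in lag with an intercept
#' column and knots placed at equal intervals on the log-lag scale (so a 4-df
#' lag basis is intercept + 3 spline columns with 2 interior knots); and
#' \code{"indicator"}, one column per lag, an unconstrained parameterization
#' used mainly as a testing oracle.
#'
#' @param max_lag non-negative integer, maximum lag in days.
#' @param df positive integer, number of lag-basis columns (ignored for
#'   \code{kind = "indicator"}, which always has \code{max_lag + 1} columns).
#' @param knots optional numeric knots on the raw lag axis, strictly inside
#'   \code{(0, max_lag)}; default [log_spaced_lag_knots()].
#' @param kind \code{"ns_log"} or \code{"indicator"}.
#' @return an object of class \code{"lag_spec"}.
#' @export
lag_spec <- function(max_lag, df = 4L, knots = NULL,
                     kind = c("ns_log", "indicator")) {
  kind <- match.arg(kind)
  max_lag <- as.integer(max_lag)
  if (is.na(max_lag) || max_lag < 0L) stop("'max_lag' must be >= 0")
  if (kind == "indicator") {
    df <- max_lag + 1L
    knots <- numeric(0)
  } else {
    df <- as.integer(df)
    if (is.na(df) || df < 1L) stop("'df' must be a positive integer")
    if (is.null(knots)) knots <- log_spaced_lag_knots(max(max_lag, 1L), df)
    if (length(knots) && (min(knots) <= 0 || max(knots) >= max_lag))
      stop("lag knots must lie strictly inside (0, max_lag)")
  }
  structure(list(max_lag = max_lag, df = df, knots = knots, kind = kind),
            class = "lag_spec")
}

#' Equally spaced interior knots over a range
#'
#' Splits \code{[lo, hi]} into \code{df} equal sub-intervals and returns the
#' \code{df - 1} interior break points, the placement rule used for the
#' temperature spline (equal spacing over the temperature range rather than
#' quantiles, to keep flexibility in the tails of the distribution).
#'
#' @param lo,hi range endpoints, \code{lo < hi}.
#' @param df positive integer; \code{df < 2} yields no interior knots.
#' @return numeric vector of \code{max(df - 1, 0)} knots, excluding endpoints.
#' @examples
#' equally_spaced_knots(0, 10, 2)    # 5
#' equally_spaced_knots(-11, 31, 5)  # -2.6  5.8 14.2 22.6
#' @export
equally_spaced_knots <- function(lo, hi, df) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("invalid range: 'lo' must be strictly below 'hi'")
  df <- as.integer(df)
  if (df < 2L) return(numeric(0))
  seq(lo, hi, length.out = df + 1L)[-c(1L, df + 1L)]
}

#' Lag knots at equal intervals on the log scale
#'
#' Places \code{df - 2} knots at \code{exp} of equally spaced points between
#' \code{log(1)} and \code{log(max_lag)}, giving denser knots at short lags
#' where lag effects change fastest. The lag basis carries an intercept
#' column, so a \code{df}-column lag basis needs \code{df - 2} interior knots
#' for its spline part. Lag 0 is covered by the basis but carries no knot.
#'
#' @param max_lag integer \code{>= 1}.
#' @param df positive integer; \code{df <= 2} yields no knots.
#' @return numeric vector of knots in \code{(0, max_lag)}.
#' @examples
#' log_spaced_lag_knots(27, 4)  # 3 and 9 (27^(1/3), 27^(2/3))
#' @export
log_spaced_lag_knots <- function(max_lag, df) {
  max_lag <- as.integer(max_lag)
  if (is.na(max_lag) || max_lag < 1L)
    stop("invalid range: 'max_lag' must be >= 1")
  df <- as.integer(df)
  if (df <= 2L) return(numeric(0))
  exp(seq(log(1), log(max_lag), length.out = df)[-c(1L, df)])
}

#' Evaluate a natural cubic spline basis
#'
#' Evaluates the natural cubic spline basis defined by a [spline_spec()] at
#' arbitrary values. Columns are continuous with continuous first and second
#' derivatives at the knots; beyond the boundary knots the second derivative
#' is zero, so every column extrapolates linearly. With no interior knots
#' (\code{df = 1}) the single column is affine in \code{x}.
#'
#' @param x numeric vector; values outside the boundary knots are allowed.
#' @param spec a [spline_spec()] with boundary knots set.
#' @return numeric matrix, \code{length(x)} rows and \code{spec$df} columns.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  if (is.null(spec$boundary_knots))
    stop("spec has no boundary knots; realize it against data first")
  if (length(x) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = spec$df))
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("non-finite exposure value at index %d", bad[1L]))
  m <- if (spec$df == 1L && length(spec$interior_knots) == 0L)
    splines::ns(x, knots = NULL, Boundary.knots = spec$boundary_knots,
                intercept = FALSE)
  else
    splines::ns(x, knots = spec$interior_knots,
                Boundary.knots = spec$boundary_knots, intercept = FALSE)
  m <- unclass(m)
  attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

#' Evaluate the double-threshold basis
#'
#' Returns the two-column hinge basis: column \code{cold} is
#' \code{pmax(cold_threshold - x, 0)} and column \code{hot} is
#' \code{pmax(x - hot_threshold, 0)}. Both vanish on the comfort band
#' between the thresholds.
#'
#' @param x numeric vector of temperatures.
#' @param spec a [threshold_spec()].
#' @return numeric matrix with columns \code{cold} and \code{hot}.
#' @examples
#' threshold_basis(c(-1, 14, 30), threshold_spec(0.8, 24.9))
#' @export
threshold_basis <- function(x, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("non-finite exposure value at index %d", bad[1L]))
  cbind(cold = pmax(spec$cold_threshold - x, 0),
        hot  = pmax(x - spec$hot_threshold, 0))
}

# Evaluate whichever exposure basis the spec describes.
exposure_basis <- function(x, spec) {
  if (inherits(spec, "spline_spec")) ns_basis(x, spec)
  else if (inherits(spec, "threshold_spec")) threshold_basis(x, spec)
  else stop("exposure spec must be a 'spline_spec' or 'threshold_spec'")
}

n_exposure_cols <- function(spec) {
  if (inherits(spec, "spline_spec")) spec$df else 2L
}

#' Evaluate the lag basis on the integer lag grid
#'
#' @param spec a [lag_spec()].
#' @param lags integer lags at which to evaluate; default \code{0:max_lag}.
#' @return matrix with \code{length(lags)} rows and \code{spec$df} columns.
#' @export
lag_basis <- function(spec, lags = 0:spec$max_lag) {
  stopifnot(inherits(spec, "lag_spec"))
  if (any(lags < 0 | lags > spec$max_lag))
    stop("lags out of range 0..max_lag")
  if (spec$kind == "indicator") {
    m <- matrix(0, length(lags), spec$max_lag + 1L)
    m[cbind(seq_along(lags), lags + 1L)] <- 1
  } else if (spec$df == 1L) {
    m <- matrix(1, length(lags), 1L)
  } else {
    sp <- if (length(spec$knots))
      splines::ns(lags, knots = spec$knots,
                  Boundary.knots = c(0, spec$max_lag), intercept = FALSE)
    else
      splines::ns(lags, df = 1L, Boundary.knots = c(0, spec$max_lag),
                  intercept = FALSE)
    m <- cbind(1, unclass(sp))
    attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  }
  colnames(m) <- paste0("l", seq_len(ncol(m)))
  m
}
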