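#' Circular distance between angles
#'
#' Minimal absolute angular difference on a circle of the given period.
#' For orientation (axial data) the period is 180 degrees.
#'
#' @param a,b Angles in degrees (vectorized).
#' @param period Circle period in degrees (positive).
#' @return Distances in `[0, period / 2]`.
#' @examples
#' circular_distance(10, 170)  # 20
#' @export
circular_distance <- function(a, b, period = 180) {
  if (!is_scalar(period) || period <= 0)
    stop("`period` must be a positive number", call. = FALSE)
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Uniformly sampled curve on a circular domain
#'
#' Carrier for aligned channel response functions and aligned posteriors:
#' values sampled at evenly spaced offsets on a circle of the stated period.
#'
#' @param offsets Offsets in degrees, uniformly spaced (any order; stored
#'   sorted ascending).
#' @param values Curve values, same length as `offsets`.
#' @param period Circular period in degrees (180 for orientation).
#' @return An object of class `circular_curve` with fields `offsets`,
#'   `values`, `period`, `step`.
#' @export
circular_curve <- function(offsets, values, period = 180) {
  if (!is.numeric(offsets) || !is.numeric(values) ||
      length(offsets) != length(values) || length(offsets) < 2L)
    stop("`offsets` and `values` must be numeric vectors of equal length >= 2",
         call. = FALSE)
  if (!is_scalar(period) || period <= 0)
    stop("`period` must be positive", call. = FALSE)
  ord <- order(offsets)
  offsets <- offsets[ord]
  values <- values[ord]
  steps <- diff(offsets)
  step <- period / length(offsets)
  if (any(abs(steps - step) > 1e-6 * period))
    stop("`offsets` must be uniformly spaced over the circular domain",
         call. = FALSE)
  structure(list(offsets = offsets, values = values, period = period,
                 step = step),
            class = "circular_curve")
}

#' @export
print.circular_curve <- function(x, ...) {
  cat(sprintf("Circular curve: %d points, step %g deg, period %g deg\n",
              length(x$values), x$step, x$period))
  invisible(x)
}

#' Local maxima of a circular curve
#'
#' Indices (into the sorted offsets) where the value strictly exceeds both
#' circular neighbours.  A plateau of equal values that exceeds the values on
#' both sides counts once, at its first index in scan order.  A constant
#' curve has no local maxima.
#'
#' @param x A [circular_curve()] or a plain numeric vector (treated as
#'   circular).
#' @return Sorted integer indices of the local maxima.
#' @examples
#' local_maxima(c(0, 1, 0, 0.5, 0, 0, 0, 0))  # indices 2 and 4
#' @export
local_maxima <- function(x) {
  v <- if (inherits(x, "circular_curve")) x$values else x
  if (!is.numeric(v)) stop("`x` must be numeric or a circular_curve", call. = FALSE)
  n <- length(v)
  if (n < 3L) stop("need at least 3 points on the circle", call. = FALSE)
  differs <- v != c(v[n], v[-n])      # v[i] != v[i - 1] (circular)
  if (!any(differs)) return(integer(0))  # constant curve
  start <- which(differs)[1L]         # rotate so index 1 begins a run
  rot <- ((start - 1 + 0:(n - 1)) %% n) + 1
  r <- rle(v[rot])
  nr <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in seq_len(nr)) {
    prev <- r$values[if (i == 1L) nr else i - 1L]
    nxt <- r$values[if (i == nr) 1L else i + 1L]
    if (r$values[i] > prev && r$values[i] > nxt)
      out <- c(out, min(rot[starts[i]:ends[i]]))
  }
  sort(out)
}

#' Angular separation between the two peaks of a bimodal curve
#'
#' @param x A [circular_curve()] with exactly two local maxima (otherwise an
#'   error reporting the modality).
#' @return Circular distance in degrees between the two peak offsets.
#' @export
peak_separation <- function(x) {
  stopifnot(inherits(x, "circular_curve"))
  idx <- local_maxima(x)
  if (length(idx) != 2L)
    stop(sprintf("curve has %d local maxima; peak separation requires exactly 2",
                 length(idx)), call. = FALSE)
  circular_distance(x$offsets[idx[1]], x$offsets[idx[2]], period = x$period)
}

#' Full width at half maximum of a circular curve
#'
#' Width of the region around the global maximum where the curve stays at or
#' above `(max + min) / 2`, with linear interpolation between grid points.
#' Intended for unimodal curves such as aligned posteriors; a constant curve
#' (no half-height crossing) is an error.
#'
#' @param x A [circular_curve()].
#' @return Width in degrees.
#' @export
fwhm <- function(x) {
  stopifnot(inherits(x, "circular_curve"))
  v <- x$values
  n <- length(v)
  if (diff(range(v)) <= 0)
    stop("curve is constant: no half-height crossing", call. = FALSE)
  level <- (max(v) + min(v)) / 2
  peak <- which.max(v)
  arm <- function(dir) {
    # walk from the peak in direction dir (+1 forward, -1 backward) until
    # the curve drops below the half level, interpolating the crossing
    for (s in seq_len(n - 1L)) {
      i_prev <- ((peak - 1 + dir * (s - 1)) %% n) + 1
      i <- ((peak - 1 + dir * s) %% n) + 1
      if (v[i] < level) {
        frac <- (v[i_prev] - level) / (v[i_prev] - v[i])
        return((s - 1 + frac) * x$step)
      }
    }
    stop("curve never drops below half height", call. = FALSE)
  }
  arm(1L) + arm(-1L)
}
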