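#' Periodic trapezoidal quadrature over one cardiac cycle
#'
#' Integrates a sampled T-periodic signal over one full period with the
#' trapezoidal rule, closing the cycle with an explicit wrap-around segment
#' from the last sample back to the first (shifted by one period). The
#' sample grid may be non-uniform.
#'
#' @param times numeric vector of sample times (s), strictly increasing,
#'   all within `[0, period)`.
#' @param values numeric vector (one value per time) or matrix with one row
#'   per time.
#' @param period cycle period T (s).
#' @return the integral over one period: a scalar for vector input, a vector
#'   of per-column integrals for matrix input.
#' @examples
#' t <- seq(0, 0.8, length.out = 65)[-65]
#' cycle_integral(t, sin(2 * pi * t / 0.8)^2, 0.8) # = T/2
#' @export
cycle_integral <- function(times, values, period) {
  w <- cycle_weights(times, period)
  if (is.matrix(values)) {
    stopifnot(nrow(values) == length(times))
    as.vector(crossprod(values, w))
  } else {
    stopifnot(length(values) == length(times))
    sum(values * w)
  }
}

#' Quadrature weights of the period-closing trapezoidal rule
#'
#' Returns weights `w` such that `sum(w * f(times))` equals the periodic
#' trapezoidal integral of `f` over one cycle. Having the rule as a weight
#' vector lets whole per-node fields be integrated with one matrix product.
#'
#' @inheritParams cycle_integral
#' @return numeric vector of weights, summing to `period`.
#' @export
cycle_weights <- function(times, period) {
  n <- length(times)
  if (n < 2L) stop("need at least 2 time samples")
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  if (times[1] < 0 || times[n] >= period) {
    stop("sample times must lie within [0, period)")
  }
  dt <- c(diff(times), period - times[n] + times[1])
  # weight of sample j is half the span of its two adjacent segments
  (dt + c(dt[n], dt[-n])) / 2
}

cycle_mean <- function(times, values, period) {
  cycle_integral(times, values, period) / period
}
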