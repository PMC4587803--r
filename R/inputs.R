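#' Input signal constructors
#'
#' Time-dependent input signals (stimulation profiles) are plain R functions
#' of time. Discontinuous profiles must declare their breakpoints so that the
#' integrator is restarted at each discontinuity; the constructors below
#' attach them automatically as the `"breakpoints"` attribute.
#'
#' @param value constant signal level.
#' @param times knot times, strictly increasing.
#' @param values signal values at the knots (same length as `times`).
#' @return a function `u(t)`; piecewise constructors carry a
#'   `"breakpoints"` attribute consumed by [simulateExperiment()].
#' @examples
#' u <- piecewiseLinear(c(0, 1, 3, 5), c(0, 1, 1, 0))
#' u(2)
#' @name inputSignals
NULL

#' @rdname inputSignals
#' @export
constantInput <- function(value = 0) {
  force(value)
  function(t) rep(value, length.out = length(t))
}

#' @rdname inputSignals
#' @export
piecewiseLinear <- function(times, values) {
  stopifnot(length(times) == length(values), !is.unsorted(times, strictly = TRUE))
  f <- stats::approxfun(times, values, rule = 2)
  attr(f, "breakpoints") <- times
  f
}

#' @rdname inputSignals
#' @export
piecewiseConstant <- function(times, values) {
  stopifnot(length(times) == length(values), !is.unsorted(times, strictly = TRUE))
  f <- stats::approxfun(times, values, method = "constant", rule = 2)
  attr(f, "breakpoints") <- times
  f
}

inputBreakpoints <- function(inputs, t_max) {
  bp <- unlist(lapply(inputs, attr, "breakpoints"), use.names = FALSE)
  sort(unique(bp[is.finite(bp) & bp > 0 & bp < t_max]))
}
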