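#' Time-gridded learning-investment strategy
#'
#' A control schedule specifies the learning-investment rate `u(t)` on an
#' ordered time grid spanning the whole lifespan, together with the rule
#' used to evaluate it between grid points.  Piecewise-linear interpolation
#' is the default; piecewise-constant (each value held on the right-open
#' interval to the next grid point) is available because bang-bang
#' strategies are naturally piecewise-constant.
#'
#' @param times Strictly increasing time grid; must start at 0 and end at
#'   the lifespan `T_max` of the problem it is used with.
#' @param values Learning investment rates at the grid points.
#' @param interpolation `"linear"` or `"constant"`.
#' @return An object of class `control_schedule`.
#' @seealso [constant_control()], [bang_bang_control()],
#'   [simulate_strategy()]
#' @export
#' @examples
#' cs <- control_schedule(c(0, 10, 20), c(1, 0.5, 0))
#' control_function(cs)(5)
control_schedule <- function(times, values,
                             interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 2L && !(length(times) == 1L))
    stop("a control schedule needs at least one grid point")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (times[1] != 0)
    stop("the control grid must start at t = 0")
  if (any(!is.finite(values)))
    stop("control values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 interpolation = interpolation),
            class = "control_schedule")
}

#' A constant strategy u(t) = c
#' @param value The constant learning investment rate.
#' @param T_max Lifespan the schedule covers.
#' @return A [control_schedule()].
#' @export
constant_control <- function(value, T_max) {
  control_schedule(c(0, T_max), c(value, value), interpolation = "constant")
}

#' A single-switch bang-bang strategy
#'
#' Full investment at the ceiling up to the switch time, zero afterwards.
#'
#' @param t_switch Switch time in `[0, T_max]`.
#' @param T_max Lifespan.
#' @param ceiling Upper control level before the switch.
#' @return A [control_schedule()].
#' @export
bang_bang_control <- function(t_switch, T_max, ceiling = 1) {
  if (t_switch < 0 || t_switch > T_max)
    stop("t_switch must lie within [0, T_max]")
  if (t_switch == 0) return(constant_control(0, T_max))
  if (t_switch == T_max) return(constant_control(ceiling, T_max))
  control_schedule(c(0, t_switch, T_max), c(ceiling, 0, 0),
                   interpolation = "constant")
}

#' Evaluate a control schedule as a function of time
#'
#' @param control A [control_schedule()].
#' @return A function `u(t)`, vectorized over `t`; evaluation outside the
#'   grid returns the nearest endpoint value.
#' @export
control_function <- function(control) {
  stopifnot(inherits(control, "control_schedule"))
  if (length(control$times) == 1L) {
    v <- control$values
    return(function(t) rep(v, length(t)))
  }
  if (control$interpolation == "linear") {
    stats::approxfun(control$times, control$values, method = "linear",
                     rule = 2)
  } else {
    stats::approxfun(control$times, control$values, method = "constant",
                     f = 0, rule = 2)
  }
}

#' @export
print.control_schedule <- function(x, ...) {
  cat(sprintf("Control schedule: %d grid points on [%g, %g], %s interpolation\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$interpolation))
  cat(sprintf("  u range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}
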