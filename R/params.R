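#' Model parameters for the lifetime exploration-exploitation model
#'
#' Bundles the six constants of the life-history model: a subject gains
#' energy at rate `f_max * L / (L + k_L)` from its current knowledge `L`,
#' pays a fixed maintenance cost `m`, converts invested energy into
#' knowledge with efficiency `alpha`, loses knowledge at proportional rate
#' `m_L`, and lives for `T_max` time units.
#'
#' All parameters must be strictly positive.  Values outside the ranges the
#' model was studied over (`f_max` in \[0.5, 10\], `k_L` in \[0.001, 10\],
#' `alpha` in \[0.5, 10\], `m_L` in \[0.01, 1\], `T_max` in \[5, 100\], and
#' `m` fixed at 0.02) are accepted with a warning rather than rejected.
#'
#' @param f_max Maximal energy intake rate (energy/time), reached as
#'   knowledge saturates.
#' @param k_L Half-saturation knowledge level (knowledge units): the amount
#'   of knowledge at which intake is `f_max / 2`.  Proxies spatial
#'   heterogeneity of the environment.
#' @param m Energy maintenance cost rate (energy/time).
#' @param alpha Learning efficiency: knowledge gained per unit of energy
#'   invested (knowledge/energy).
#' @param m_L Knowledge decay ("forgetting") rate (1/time).  Proxies
#'   temporal unpredictability.
#' @param T_max Life duration (time units).
#'
#' @return An object of class `model_params` (a named list).
#' @seealso [boundary_constraints()], [optimal_strategy()]
#' @export
#' @examples
#' p <- model_params()           # the baseline parameter set
#' energy_rate(E = 5.5, L = 1, u = 0, p)
model_params <- function(f_max = 1, k_L = 1, m = 0.02, alpha = 1,
                         m_L = 0.08, T_max = 20) {
  p <- list(f_max = f_max, k_L = k_L, m = m, alpha = alpha,
            m_L = m_L, T_max = T_max)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    if (v <= 0)
      stop("parameter '", nm, "' must be strictly positive")
  }
  ranges <- .param_ranges()
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (p[[nm]] < r[1] || p[[nm]] > r[2])
      warning("parameter '", nm, "' = ", p[[nm]],
              " lies outside the studied range [", r[1], ", ", r[2], "]",
              call. = FALSE)
  }
  structure(p, class = "model_params")
}

# Studied ranges (m has a single studied value, treated as [m, m]).
.param_ranges <- function() {
  list(f_max = c(0.5, 10), k_L = c(0.001, 10), m = c(0.02, 0.02),
       alpha = c(0.5, 10), m_L = c(0.01, 1), T_max = c(5, 100))
}

#' @export
print.model_params <- function(x, ...) {
  cat("Lifetime exploration-exploitation model parameters:\n")
  cat(sprintf("  f_max = %-8g maximal intake rate (E/t)\n", x$f_max))
  cat(sprintf("  k_L   = %-8g half-saturation knowledge (L)\n", x$k_L))
  cat(sprintf("  m     = %-8g maintenance cost (E/t)\n", x$m))
  cat(sprintf("  alpha = %-8g learning efficiency (L/E)\n", x$alpha))
  cat(sprintf("  m_L   = %-8g knowledge decay rate (1/t)\n", x$m_L))
  cat(sprintf("  T_max = %-8g life duration (t)\n", x$T_max))
  invisible(x)
}

#' Boundary and constraint values for the optimization problem
#'
#' Initial state, survival floor, and control bounds.  The defaults are the
#' standard problem setup: the subject starts with energy 5.5 and no
#' knowledge, must keep its energy at or above the survival floor
#' `E_min = 5` at all times, and may invest in learning at a rate between 0
#' and 1 energy units per time unit.
#'
#' The effective upper bound on the learning investment is
#' `min(u_max, f_max)`: expenditure on exploration can never exceed the
#' maximal energy acquisition rate.  Use [control_ceiling()] to obtain it.
#'
#' @param E0 Initial energy (must exceed `E_min`).
#' @param L0 Initial knowledge (must be at least `L_min`).
#' @param E_min Survival energy floor: the trajectory is infeasible if
#'   energy ever falls below this level.
#' @param L_min Knowledge floor (0: knowledge cannot be negative).
#' @param u_min Lower bound on the learning investment rate (energy/time).
#' @param u_max Upper bound on the learning investment rate (energy/time).
#'
#' @return An object of class `boundary_constraints` (a named list).
#' @export
#' @examples
#' bc <- boundary_constraints()
#' control_ceiling(bc, model_params())
boundary_constraints <- function(E0 = 5.5, L0 = 0, E_min = 5, L_min = 0,
                                 u_min = 0, u_max = 1) {
  bc <- list(E0 = E0, L0 = L0, E_min = E_min, L_min = L_min,
             u_min = u_min, u_max = u_max)
  for (nm in names(bc)) {
    v <- bc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("boundary value '", nm, "' must be a single finite number")
  }
  if (bc$E0 <= bc$E_min)
    stop("initial energy E0 must exceed the survival floor E_min")
  if (bc$L0 < bc$L_min)
    stop("initial knowledge L0 must be at least L_min")
  if (bc$u_min < 0) stop("u_min must be non-negative")
  if (bc$u_max <= bc$u_min) stop("u_max must exceed u_min")
  structure(bc, class = "boundary_constraints")
}

#' @export
print.boundary_constraints <- function(x, ...) {
  cat("Boundary constraints:\n")
  cat(sprintf("  E0 = %g, L0 = %g (initial state)\n", x$E0, x$L0))
  cat(sprintf("  E_min = %g (survival floor), L_min = %g\n",
              x$E_min, x$L_min))
  cat(sprintf("  u in [%g, %g]\n", x$u_min, x$u_max))
  invisible(x)
}

#' Effective upper bound on the learning investment rate
#'
#' Exploration expenditure per unit time is bounded both by the declared
#' control bound `u_max` and by the maximal energy acquisition rate
#' `f_max`; the binding ceiling is the smaller of the two.
#'
#' @param bc A [boundary_constraints()] object.
#' @param params A [model_params()] object.
#' @return The effective control ceiling `min(u_max, f_max)`.
#' @export
control_ceiling <- function(bc, params) {
  min(bc$u_max, params$f_max)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  do.call(model_params, as.list(x))
}

as_boundary_constraints <- function(x) {
  if (inherits(x, "boundary_constraints")) return(x)
  do.call(boundary_constraints, as.list(x))
}
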