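# Adjoint (costate) machinery. With Hamiltonian
#   H = lambda_E * (f_max L/(L+k_L) - m - u) + lambda_L * (alpha u - m_L L)
#       + eta * (E - E_min),
# the adjoint equations are
#   dlambda_E/dt = -eta            (eta >= 0, nonzero only on the floor arc)
#   dlambda_L/dt = -lambda_E * f_max k_L/(L+k_L)^2 + lambda_L * m_L
# with terminal conditions lambda_E(T) = 1, lambda_L(T) = 0 for a terminal-
# energy objective. Off the floor arc lambda_E is constant. On the floor
# arc the control is interior, so the switching function
#   sigma = alpha * lambda_L - lambda_E
# must vanish there, which pins lambda_E = alpha * lambda_L and determines
# the constraint multiplier eta implicitly.

#' Estimate costate trajectories along a solved strategy
#'
#' Integrates the adjoint equations backward from the terminal conditions
#' `lambda_E(T) = 1`, `lambda_L(T) = 0` along the solution mesh (classical
#' RK4 on each mesh interval).  On the interval where the survival floor
#' `E = E_min` is active, the interior-control stationarity condition
#' `alpha * lambda_L = lambda_E` is imposed and the floor multiplier is
#' recovered from the implied slope of `lambda_E`.
#'
#' @param sol A `life_ocp` object from [optimal_strategy()], or any list
#'   with `times`, `E`, `L` vectors plus `params` and `bc`.
#' @param params Model parameters; defaults to those stored in `sol`.
#' @param floor_tol Activity tolerance: the floor is considered active
#'   where `E - E_min < floor_tol`.
#' @return A data.frame with columns `time`, `lambda_E`, `lambda_L`,
#'   `sigma` (the switching function `alpha*lambda_L - lambda_E`) and
#'   `floor_active`.
#' @export
estimate_costates <- function(sol, params = sol$params, floor_tol = 1e-4) {
  times <- sol$times
  E <- sol$E; L <- sol$L
  bc <- sol$bc
  if (is.null(times) || length(times) < 2L) stop("solution has no mesh")
  if (min(E) < bc$E_min - 1e-4 || min(L) < bc$L_min - 1e-4)
    stop("cannot estimate costates for an infeasible solution")
  n1 <- length(times)
  p <- params

  Lfun <- stats::approxfun(times, L, rule = 2)
  active <- (E - bc$E_min) < floor_tol
  # restrict to the (at most one) contiguous active arc containing the
  # longest run; isolated touch points are ignored
  runs <- rle(active)
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    main <- keep[which.max(runs$lengths[keep])]
    active <- rep(FALSE, n1)
    if (runs$lengths[main] >= 2L) active[starts[main]:ends[main]] <- TRUE
  }

  lam_E <- numeric(n1); lam_L <- numeric(n1)
  lam_E[n1] <- 1; lam_L[n1] <- 0

  # backward RK4 for dlambda_L/dt = -lambda_E*a(L) + lambda_L*m_L with
  # lambda_E either frozen (free arc) or equal to alpha*lambda_L (floor arc)
  step_free <- function(lE, lL, t0, t1) {
    hh <- t1 - t0
    f <- function(t, y) -lE * intake_slope(Lfun(t), p) + y * p$m_L
    k1 <- f(t1, lL)
    k2 <- f(t1 - hh / 2, lL - hh / 2 * k1)
    k3 <- f(t1 - hh / 2, lL - hh / 2 * k2)
    k4 <- f(t0, lL - hh * k3)
    lL - hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  step_floor <- function(lL, t0, t1) {
    hh <- t1 - t0
    f <- function(t, y) y * (p$m_L - p$alpha * intake_slope(Lfun(t), p))
    k1 <- f(t1, lL)
    k2 <- f(t1 - hh / 2, lL - hh / 2 * k1)
    k3 <- f(t1 - hh / 2, lL - hh / 2 * k2)
    k4 <- f(t0, lL - hh * k3)
    lL - hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  for (i in seq(n1 - 1L, 1L)) {
    on_floor <- active[i] && active[i + 1L]
    if (on_floor) {
      lam_L[i] <- step_floor(lam_L[i + 1L], times[i], times[i + 1L])
      lam_E[i] <- p$alpha * lam_L[i]
    } else {
      lam_E[i] <- lam_E[i + 1L]
      lam_L[i] <- step_free(lam_E[i + 1L], lam_L[i + 1L],
                            times[i], times[i + 1L])
    }
  }
  data.frame(time = times, lambda_E = lam_E, lambda_L = lam_L,
             sigma = p$alpha * lam_L - lam_E, floor_active = active)
}

#' Switching function of the learning-investment control
#'
#' The Hamiltonian is linear in the control `u`, with coefficient
#' `sigma(t) = alpha * lambda_L(t) - lambda_E(t)`: the marginal value of
#' knowledge bought by one unit of energy, minus the marginal value of the
#' energy itself.  Pontryagin's maximum principle demands `u` at the
#' ceiling where `sigma > 0`, `u = 0` where `sigma < 0`, and permits
#' interior (singular or constrained) control only where `sigma = 0`.
#'
#' @param sol A `life_ocp` object with costates (see
#'   [estimate_costates()]; [optimal_strategy()] attaches them).
#' @param t Time point(s) within `[0, T_max]`.
#' @return `sigma(t)`, linearly interpolated on the solution mesh.
#' @export
switching_function <- function(sol, t) {
  if (any(t < 0 | t > sol$params$T_max))
    stop("t outside [0, T_max]")
  cs <- sol$costates
  if (is.null(cs)) cs <- estimate_costates(sol)
  stats::approx(cs$time, cs$sigma, xout = t, rule = 2)$y
}

#' Check a solution against Pontryagin's bang-bang rule
#'
#' At every mesh point outside the active survival-floor arc, outside
#' self-declared singular regions (`|sigma| <= tol`), and outside a
#' 2-point boundary layer around phase junctions, the control must obey
#' the bang-bang rule: `sigma > tol` implies `u` at the ceiling,
#' `sigma < -tol` implies `u = 0`.  The check passes when at least 95% of
#' the examined points comply.
#'
#' @param sol A `life_ocp` object (or any solution-like list with `times`,
#'   `E`, `L`, `u`, `params`, `bc`).
#' @param tol Dead-band half-width on `sigma` inside which a point is
#'   treated as singular (default 0.02).
#' @param u_tol Tolerance for "at the bound", as a fraction of the control
#'   ceiling (default 0.02).
#' @param pass_fraction Minimal compliant fraction (default 0.95).
#' @return A list of class `pmp_report`: `pass`, `fraction`, `n_checked`,
#'   `n_violations`, `violation_times`, and `sigma_terminal`.
#' @export
check_pmp <- function(sol, tol = 0.02, u_tol = 0.02, pass_fraction = 0.95) {
  cs <- sol$costates
  if (is.null(cs)) cs <- estimate_costates(sol)
  p <- sol$params; bc <- sol$bc
  ceiling_u <- control_ceiling(bc, p)
  u <- sol$u
  sigma <- cs$sigma
  n1 <- length(sol$times)

  excluded <- cs$floor_active
  # 2-point layer around junctions, marked by regime changes of u
  at_top <- u > ceiling_u * (1 - u_tol)
  at_zero <- u < ceiling_u * u_tol
  regime <- ifelse(cs$floor_active, 0L,
                   ifelse(at_top, 1L, ifelse(at_zero, 2L, 3L)))
  jumps <- which(diff(regime) != 0L)
  for (j in jumps) {
    layer <- max(1L, j - 1L):min(n1, j + 2L)
    excluded[layer] <- TRUE
  }

  idx <- which(!excluded)
  ok <- rep(TRUE, length(idx))
  s_i <- sigma[idx]; u_i <- u[idx]
  ok[s_i > tol & u_i < ceiling_u * (1 - u_tol)] <- FALSE
  ok[s_i < -tol & u_i > ceiling_u * u_tol] <- FALSE

  fraction <- if (length(idx)) mean(ok) else 1
  structure(list(pass = fraction >= pass_fraction,
                 fraction = fraction,
                 n_checked = length(idx),
                 n_violations = sum(!ok),
                 violation_times = sol$times[idx[!ok]],
                 sigma_terminal = sigma[n1],
                 tol = tol, u_tol = u_tol,
                 pass_fraction = pass_fraction),
            class = "pmp_report")
}

#' @export
print.pmp_report <- function(x, ...) {
  cat(sprintf(
    "Pontryagin bang-bang consistency: %s (%.1f%% of %d points, %d violations)\n",
    if (x$pass) "PASS" else "FAIL", 100 * x$fraction, x$n_checked,
    x$n_violations))
  cat(sprintf("  terminal switching value sigma(T) = %.4f (theory: -1)\n",
              x$sigma_terminal))
  invisible(x)
}
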