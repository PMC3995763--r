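# Backward dynamic programming on a discretized time-state grid with a
# finite control menu: an independent, brute-force check on the
# collocation solver. One explicit Euler step per stage per control;
# bilinear interpolation of the value function between grid nodes; states
# that fall below the survival floor die.
#
# Death is encoded as zero terminal surplus rather than -Inf: every
# alive value is at least E_min > 0, so dying is still strictly
# dominated, while bilinear interpolation near the floor degrades
# gracefully instead of poisoning neighbouring states with -Inf (the
# Euler discretization kills some floor-adjacent grid nodes that are
# survivable in continuous time).

DP_DEATH <- 0

#' Grid specification for the dynamic-programming oracle
#'
#' @param n_t Number of time steps (at least 50).
#' @param E_grid Strictly increasing energy levels spanning
#'   `[E_min, E_upper]`.
#' @param L_grid Strictly increasing knowledge levels from 0 up to at
#'   least the reachable fixed point `alpha * ceiling / m_L`.
#' @param u_levels Finite control menu; must contain 0 and the ceiling.
#' @return An object of class `dp_grid`.
#' @details The defaults (chosen when `dp_solve` is called without a
#'   grid) are 200 time steps, 80 energy levels on `[E_min, 15]`, 80
#'   knowledge levels on `[0, 1.25 * alpha * ceiling / m_L]`, and 11
#'   equispaced control levels.
#' @export
dp_grid <- function(n_t, E_grid, L_grid, u_levels) {
  if (n_t < 50L) stop("n_t must be at least 50")
  if (is.unsorted(E_grid, strictly = TRUE) ||
      is.unsorted(L_grid, strictly = TRUE))
    stop("state grids must be strictly increasing")
  structure(list(n_t = as.integer(n_t), E_grid = E_grid, L_grid = L_grid,
                 u_levels = sort(u_levels)), class = "dp_grid")
}

default_dp_grid <- function(params, bc) {
  ceiling_u <- control_ceiling(bc, params)
  L_upper <- 1.25 * params$alpha * ceiling_u / params$m_L
  E_upper <- max(15, bc$E0 + params$f_max * params$T_max / 2)
  dp_grid(n_t = 200L,
          E_grid = seq(bc$E_min, E_upper, length.out = 80L),
          L_grid = seq(0, L_upper, length.out = 80L),
          u_levels = seq(0, ceiling_u, length.out = 11L))
}

#' Solve the life-history problem by backward dynamic programming
#'
#' Computes the value function `V(t, E, L)` (maximal attainable terminal
#' energy) backward from `V(T_max, E, L) = E` on a rectangular grid, then
#' rolls the greedy policy forward from the initial state.  Energy is
#' clamped to "death" below the survival floor; values above the top of
#' the energy grid are linearly extrapolated from the top edge (the value
#' function is asymptotically linear in banked energy).
#'
#' This is a deliberately simple, independent construction: its only role
#' is to bound and validate [optimal_strategy()], which it should match
#' within a few percent of terminal energy on default grids.
#'
#' @param params,bc Model parameters and boundary constraints.
#' @param grid A [dp_grid()]; a default grid is built when `NULL`.
#' @return An object of class `dp_solution`: `value` (the `V(0, , )`
#'   slice), `grid`, `rollout` (data.frame `time`, `E`, `L`, `u`),
#'   `objective` (terminal energy of the greedy rollout), `params`, `bc`.
#' @export
#' @examples
#' \donttest{
#' dp <- dp_solve(model_params(), boundary_constraints())
#' dp$objective
#' }
dp_solve <- function(params, bc = boundary_constraints(), grid = NULL) {
  params <- as_model_params(params)
  bc <- as_boundary_constraints(bc)
  if (is.null(grid)) grid <- default_dp_grid(params, bc)
  stopifnot(inherits(grid, "dp_grid"))
  p <- params
  Eg <- grid$E_grid; Lg <- grid$L_grid; ug <- grid$u_levels
  nE <- length(Eg); nL <- length(Lg)
  if (bc$E0 < Eg[1] || bc$E0 > Eg[nE] || bc$L0 < Lg[1] || bc$L0 > Lg[nL])
    stop("initial state lies outside the DP grid")
  dt <- p$T_max / grid$n_t
  dE <- diff(Eg); dL <- diff(Lg)

  intake <- p$f_max * Lg / (Lg + p$k_L)   # per L level

  # interpolate V at (Enext[j,k], Lnext[k]); linear extrapolation above
  # the top energy row, death below the floor
  interp_next <- function(V, u) {
    Lnext <- Lg + dt * (p$alpha * u - p$m_L * Lg)
    Lnext <- pmin(pmax(Lnext, Lg[1]), Lg[nL])
    kL <- pmin(findInterval(Lnext, Lg), nL - 1L)
    wL <- (Lnext - Lg[kL]) / dL[kL]
    cE <- dt * (intake - p$m - u)          # energy increment per L level
    W <- matrix(DP_DEATH, nE, nL)
    for (k in seq_len(nL)) {
      Enext <- Eg + cE[k]
      alive <- Enext >= bc$E_min
      jE <- pmin(pmax(findInterval(Enext, Eg), 1L), nE - 1L)
      wE <- (Enext - Eg[jE]) / dE[jE]      # may exceed 1 above the top row
      v1 <- V[jE, kL[k]] * (1 - wE) + V[jE + 1L, kL[k]] * wE
      v2 <- V[jE, kL[k] + 1L] * (1 - wE) + V[jE + 1L, kL[k] + 1L] * wE
      W[, k] <- ifelse(alive, v1 * (1 - wL[k]) + v2 * wL[k], DP_DEATH)
    }
    W
  }

  # greedy forward rollout from the initial state
  interp_state <- function(V, E, L) {
    E <- min(max(E, Eg[1]), Eg[nE] + (Eg[nE] - Eg[1]))  # allow top extrap
    L <- min(max(L, Lg[1]), Lg[nL])
    jE <- min(max(findInterval(E, Eg), 1L), nE - 1L)
    kL <- min(findInterval(L, Lg), nL - 1L)
    wE <- (E - Eg[jE]) / dE[jE]; wL <- (L - Lg[kL]) / dL[kL]
    (V[jE, kL] * (1 - wE) + V[jE + 1L, kL] * wE) * (1 - wL) +
      (V[jE, kL + 1L] * (1 - wE) + V[jE + 1L, kL + 1L] * wE) * wL
  }

  # recompute value slices forward as needed (memory-light: store all)
  # n_t slices of 80x80 doubles is ~10 MB at defaults, so keep them
  slices <- vector("list", grid$n_t + 1L)
  slices[[grid$n_t + 1L]] <- matrix(Eg, nE, nL)
  for (it in seq_len(grid$n_t)) {
    V <- slices[[grid$n_t + 2L - it]]
    best <- matrix(DP_DEATH, nE, nL)
    for (u in ug) best <- pmax(best, interp_next(V, u))
    slices[[grid$n_t + 1L - it]] <- best
  }

  E <- bc$E0; L <- bc$L0
  roll <- data.frame(time = numeric(grid$n_t + 1L), E = NA_real_,
                     L = NA_real_, u = NA_real_)
  roll$time <- seq(0, p$T_max, length.out = grid$n_t + 1L)
  for (it in seq_len(grid$n_t)) {
    Vnext <- slices[[it + 1L]]
    vals <- vapply(ug, function(u) {
      En <- E + dt * (p$f_max * L / (L + p$k_L) - p$m - u)
      Ln <- L + dt * (p$alpha * u - p$m_L * L)
      if (En < bc$E_min) return(DP_DEATH)
      interp_state(Vnext, En, Ln)
    }, 0)
    u <- ug[which.max(vals)]
    roll$E[it] <- E; roll$L[it] <- L; roll$u[it] <- u
    E <- E + dt * (p$f_max * L / (L + p$k_L) - p$m - u)
    L <- L + dt * (p$alpha * u - p$m_L * L)
  }
  roll$E[grid$n_t + 1L] <- E; roll$L[grid$n_t + 1L] <- L
  roll$u[grid$n_t + 1L] <- 0

  structure(list(value = slices[[1L]], grid = grid, rollout = roll,
                 objective = E, params = params, bc = bc),
            class = "dp_solution")
}

#' @export
print.dp_solution <- function(x, ...) {
  g <- x$grid
  cat("Dynamic-programming oracle solution\n")
  cat(sprintf("  grid: %d time steps, %d x %d states, %d control levels\n",
              g$n_t, length(g$E_grid), length(g$L_grid),
              length(g$u_levels)))
  cat(sprintf("  greedy-rollout terminal energy: %.6f\n", x$objective))
  invisible(x)
}

#' Compare a collocation solution with the DP oracle
#'
#' @param sol A `life_ocp` fit.
#' @param dp A `dp_solution` for the same parameters.
#' @param objective_tol Maximal relative objective gap (default 0.05).
#' @param policy_tol Maximal sup-distance between the greedy policy and
#'   `u*` sampled on the DP time grid, as a fraction of the control
#'   ceiling (default 0.25).  Both policies are smoothed with a moving
#'   average of width `T_max / 20` before comparison, because a greedy
#'   finite-menu policy approximates interior (singular) controls by
#'   duty-cycling between adjacent menu levels: only its local average is
#'   meaningful.  A 2-step layer around phase junctions, where the two
#'   discretizations legitimately place switches one cell apart, is
#'   excluded.
#' @return A list of class `dp_comparison`: `objective_gap` (relative),
#'   `policy_sup_distance`, `pass`, and the thresholds used.
#' @export
compare_with_ocp <- function(sol, dp, objective_tol = 0.05,
                             policy_tol = 0.25) {
  if (!isTRUE(all.equal(unclass(sol$params)[names(sol$params)],
                        unclass(dp$params)[names(dp$params)],
                        tolerance = 1e-12)))
    stop("parameter mismatch between the OCP solution and the DP result")
  if (!isTRUE(all.equal(unclass(sol$bc), unclass(dp$bc),
                        tolerance = 1e-12)))
    stop("boundary-constraint mismatch between the two solutions")

  gap <- abs(dp$objective - sol$objective) / abs(sol$objective)

  ceiling_u <- control_ceiling(sol$bc, sol$params)
  tgrid <- dp$rollout$time
  u_ocp <- stats::approx(sol$times, sol$u, tgrid, rule = 2)$y
  u_dp <- dp$rollout$u
  # moving-average smoothing over a window of T_max / 20
  win <- max(1L, round(length(tgrid) / 20))
  smooth_u <- function(u) as.numeric(stats::filter(u, rep(1 / win, win),
                                                   sides = 2))
  us_ocp <- smooth_u(u_ocp); us_dp <- smooth_u(u_dp)
  # exclude a layer around junctions of the smoothed OCP control
  regime <- function(u) ifelse(u > ceiling_u * 0.9, 2L,
                               ifelse(u < ceiling_u * 0.1, 0L, 1L))
  jumps <- which(diff(regime(us_ocp)) != 0L)
  excl <- is.na(us_ocp) | is.na(us_dp)
  half <- win %/% 2 + 2L
  for (j in jumps)
    excl[max(1L, j - half):min(length(tgrid), j + half + 1L)] <- TRUE
  dist <- if (all(excl)) 0 else
    max(abs(us_ocp[!excl] - us_dp[!excl])) / ceiling_u

  structure(list(objective_gap = gap, policy_sup_distance = dist,
                 objective_tol = objective_tol, policy_tol = policy_tol,
                 pass = gap <= objective_tol && dist <= policy_tol,
                 dp_objective = dp$objective,
                 ocp_objective = sol$objective),
            class = "dp_comparison")
}

#' @export
print.dp_comparison <- function(x, ...) {
  cat(sprintf(
    "OCP vs DP oracle: %s\n  objective %.6f (OCP) vs %.6f (DP rollout): relative gap %.4f (tol %.2f)\n  policy sup-distance %.3f of ceiling (tol %.2f)\n",
    if (x$pass) "PASS" else "FAIL", x$ocp_objective, x$dp_objective,
    x$objective_gap, x$objective_tol, x$policy_sup_distance, x$policy_tol))
  invisible(x)
}
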