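#' Options for the optimal-control solver
#'
#' Controls the direct-collocation transcription and its augmented-
#' Lagrangian solution.  The defaults are sized for a fully resolved
#' baseline solve (a few tens of seconds); use [reduced_options()] inside
#' large parameter sweeps.
#'
#' @param mesh_size Number of collocation intervals on the final
#'   refinement round (at least 20).
#' @param refine_rounds Number of mesh rounds: the problem is first solved
#'   on `mesh_size / 2^(refine_rounds-1)` intervals and the mesh is doubled
#'   (warm-started) until `mesh_size` is reached.
#' @param tol NLP feasibility tolerance: maximal allowed collocation
#'   defect / path-constraint violation.
#' @param n_starts Number of multistart initial guesses (the first is the
#'   deterministic ceiling-to-zero ramp; the rest add seeded smooth
#'   perturbations).
#' @param seed Seed for the multistart perturbations.
#' @param eps_schedule Decreasing schedule of H1 control-smoothing weights
#'   for the regularization continuation; must end in 0.
#' @param inner_maxit,factr,lmm L-BFGS-B settings for the inner solves.
#' @param max_outer Maximal augmented-Lagrangian iterations per
#'   continuation stage.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(mesh_size = 400L, refine_rounds = 2L,
                           tol = 1e-8, n_starts = 1L, seed = 1L,
                           eps_schedule = c(1e-2, 1e-4, 0),
                           inner_maxit = 5000L, factr = 1e3, lmm = 20L,
                           max_outer = 40L) {
  if (mesh_size < 20L) stop("mesh_size must be at least 20")
  if (tol <= 0) stop("tol must be positive")
  if (refine_rounds < 1L) stop("refine_rounds must be at least 1")
  if (utils::tail(eps_schedule, 1) != 0)
    stop("eps_schedule must end at 0 (unregularized problem)")
  structure(list(mesh_size = as.integer(mesh_size),
                 refine_rounds = as.integer(refine_rounds),
                 tol = tol, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), eps_schedule = eps_schedule,
                 inner_maxit = as.integer(inner_maxit), factr = factr,
                 lmm = as.integer(lmm), max_outer = as.integer(max_outer)),
            class = "solver_options")
}

#' Reduced-accuracy solver options for parameter sweeps
#'
#' A cheaper configuration (coarser mesh, single round, shorter
#' continuation) that resolves the phase structure reliably while keeping
#' multi-cell sweeps fast.
#'
#' @param mesh_size Collocation intervals (default 60).
#' @param ... Further overrides passed to [solver_options()].
#' @return A `solver_options` object.
#' @export
reduced_options <- function(mesh_size = 60L, ...) {
  defaults <- list(mesh_size = mesh_size, refine_rounds = 1L, tol = 1e-7,
                   eps_schedule = c(1e-2, 0), inner_maxit = 2000L,
                   factr = 1e4, max_outer = 30L)
  args <- utils::modifyList(defaults, list(...))
  do.call(solver_options, args)
}

# interpolate a coarse solution onto a finer mesh as a warm start
hs_warm_start <- function(sol, times_old, times_new, n_new, p, bc) {
  ix <- hs_index(n_new)
  z <- numeric(ix$len)
  z[ix$E] <- stats::approx(times_old, sol$E, times_new, rule = 2)$y
  z[ix$L] <- stats::approx(times_old, sol$L, times_new, rule = 2)$y
  z[ix$u] <- stats::approx(times_old, sol$u, times_new, rule = 2)$y
  mid <- (times_new[1:n_new] + times_new[2:(n_new + 1L)]) / 2
  z[ix$um] <- stats::approx(times_old, sol$u, mid, rule = 2)$y
  ceiling_u <- control_ceiling(bc, p)
  iu <- c(ix$u, ix$um)
  z[iu] <- pmin(pmax(z[iu], bc$u_min), ceiling_u)
  z[ix$E] <- pmax(z[ix$E], bc$E_min)
  z[ix$L] <- pmax(z[ix$L], bc$L_min)
  z[ix$E[1]] <- bc$E0; z[ix$L[1]] <- bc$L0
  z
}

# seeded smooth multistart perturbations of the ramp guess
multistart_guess <- function(k, times, ceiling_u, seed) {
  T_max <- times[length(times)]
  base <- seq(ceiling_u, 0, length.out = length(times))
  if (k == 1L) return(base)
  set.seed(seed + k - 1L)
  pert <- numeric(length(times))
  for (mode in 1:3)
    pert <- pert + stats::rnorm(1) / mode *
      sin(mode * pi * times / T_max)
  pmin(pmax(base + 0.3 * ceiling_u * pert, 0), ceiling_u)
}

#' Solve for the optimal lifetime exploration-exploitation strategy
#'
#' Computes the learning-investment schedule `u*(t)` that maximizes the
#' subject's energy at the end of its lifespan, subject to the survival
#' floor `E(t) >= E_min` and the control bounds
#' `u in [u_min, min(u_max, f_max)]`.  The continuous problem is
#' transcribed by direct Hermite-Simpson collocation on a uniform mesh
#' (states and controls at the nodes, controls also at interval midpoints;
#' the survival floor is imposed at nodes and midpoints alike) and solved
#' as a nonlinear program by an augmented-Lagrangian method with L-BFGS-B
#' inner iterations and a vanishing control-smoothing continuation.
#' Costates are recovered by backward integration of the adjoint equations
#' along the converged trajectory.
#'
#' @param params A [model_params()] object (or a plain list of the six
#'   parameters).
#' @param bc A [boundary_constraints()] object.
#' @param options A [solver_options()] object.
#' @return An object of class `life_ocp` with components
#'   \describe{
#'     \item{times, E, L, u}{the solution mesh, states and control}
#'     \item{objective}{terminal energy `E(T_max)`}
#'     \item{control}{the optimal strategy as a [control_schedule()]}
#'     \item{costates}{adjoint estimates and switching function
#'       (see [estimate_costates()])}
#'     \item{feasibility}{a [check_feasibility()] report on the mesh}
#'     \item{diagnostics}{solver status, maximal defect, mesh sizes and
#'       per-round objectives, multistart objectives}
#'   }
#' @seealso [classify_phases()], [check_pmp()], [dp_solve()]
#' @export
#' @examples
#' \donttest{
#' fit <- optimal_strategy(model_params(), boundary_constraints(),
#'                         reduced_options())
#' print(fit)
#' plot(fit)
#' }
optimal_strategy <- function(params = model_params(),
                             bc = boundary_constraints(),
                             options = solver_options()) {
  params <- as_model_params(params)
  bc <- as_boundary_constraints(bc)
  stopifnot(inherits(options, "solver_options"))
  p <- params
  ceiling_u <- control_ceiling(bc, p)

  n_seq <- as.integer(options$mesh_size %/%
                        2^((options$refine_rounds - 1L):0L))
  n_seq <- pmax(n_seq, 20L)

  # round 1, possibly multistarted
  n <- n_seq[1]
  times <- seq(0, p$T_max, length.out = n + 1L)
  best <- NULL
  start_objs <- numeric(options$n_starts)
  for (k in seq_len(options$n_starts)) {
    u0 <- multistart_guess(k, times, ceiling_u, options$seed)
    z0 <- hs_initial_z(times, u0, n, p, bc)
    cand <- hs_solve_nlp(z0, n, diff(times), p, bc, tol = options$tol,
                         max_outer = options$max_outer,
                         inner_maxit = options$inner_maxit,
                         factr = options$factr,
                         eps_schedule = options$eps_schedule,
                         lmm = options$lmm)
    start_objs[k] <- cand$objective
    if (is.null(best) || cand$objective > best$objective) best <- cand
  }
  sol <- best
  round_objs <- sol$objective
  mesh_sizes <- n

  # refinement rounds: double the mesh, warm start, keep the better fit
  for (nn in n_seq[-1]) {
    times_new <- seq(0, p$T_max, length.out = nn + 1L)
    z0 <- hs_warm_start(sol, times, times_new, nn, p, bc)
    cand <- hs_solve_nlp(z0, nn, diff(times_new), p, bc, tol = options$tol,
                         max_outer = options$max_outer,
                         inner_maxit = options$inner_maxit,
                         factr = options$factr,
                         eps_schedule = options$eps_schedule,
                         lmm = options$lmm)
    if (cand$objective < sol$objective - 1e-3) {
      # warm start trapped in a worse basin: retry cold
      u0 <- seq(ceiling_u, 0, length.out = nn + 1L)
      cand2 <- hs_solve_nlp(hs_initial_z(times_new, u0, nn, p, bc), nn,
                            diff(times_new), p, bc, tol = options$tol,
                            max_outer = options$max_outer,
                            inner_maxit = options$inner_maxit,
                            factr = options$factr,
                            eps_schedule = options$eps_schedule,
                            lmm = options$lmm)
      if (cand2$objective > cand$objective) cand <- cand2
    }
    times <- times_new
    sol <- cand
    round_objs <- c(round_objs, sol$objective)
    mesh_sizes <- c(mesh_sizes, nn)
  }

  nr <- length(round_objs)
  mesh_converged <- nr < 2L ||
    abs(round_objs[nr] - round_objs[nr - 1L]) < 1e-4

  control <- control_schedule(times, pmin(pmax(sol$u, bc$u_min), ceiling_u),
                              interpolation = "linear")
  fit <- structure(
    list(params = params, bc = bc, options = options,
         times = times, E = sol$E, L = sol$L, u = sol$u, um = sol$um,
         objective = sol$objective, control = control,
         diagnostics = list(status = sol$status,
                            max_defect = sol$max_defect,
                            mesh_sizes = mesh_sizes,
                            round_objectives = round_objs,
                            mesh_converged = mesh_converged,
                            multistart_objectives = start_objs,
                            outer_iterations = sol$outer_iters)),
    class = "life_ocp")

  fit$costates <- tryCatch(estimate_costates(fit),
                           error = function(e) NULL)
  traj <- data.frame(time = times, E = sol$E, L = sol$L, u = sol$u)
  fit$feasibility <- check_feasibility(traj, control = NULL, bc = bc,
                                       params = params, tol = 1e-4)
  if (sol$status != "converged")
    warning("NLP did not converge (max defect ", signif(sol$max_defect, 3),
            "); inspect $diagnostics", call. = FALSE)
  fit
}

#' Terminal energies of a fixed suite of benchmark strategies
#'
#' Forward-simulates never-learning (`u = 0`), always-learning (`u` at the
#' ceiling), and single-switch bang-bang strategies over a grid of switch
#' times, discarding infeasible ones (those that breach the survival
#' floor).  The optimal strategy must dominate every member of this suite.
#'
#' @param params,bc Model parameters and boundary constraints.
#' @param n_switch Number of switch times on `(0, T_max)` (default 20).
#' @return A data.frame with columns `strategy`, `t_switch`, `feasible`,
#'   `terminal_energy`.
#' @export
heuristic_benchmark <- function(params, bc = boundary_constraints(),
                                n_switch = 20L) {
  params <- as_model_params(params)
  bc <- as_boundary_constraints(bc)
  ceiling_u <- control_ceiling(bc, params)
  strategies <- list(list(name = "never_learn", t_switch = NA_real_,
                          control = constant_control(0, params$T_max)),
                     list(name = "always_learn", t_switch = NA_real_,
                          control = constant_control(ceiling_u,
                                                     params$T_max)))
  for (ts in seq(0, params$T_max,
                 length.out = n_switch + 2L)[2:(n_switch + 1L)])
    strategies <- c(strategies, list(list(
      name = "bang_bang", t_switch = ts,
      control = bang_bang_control(ts, params$T_max, ceiling_u))))

  rows <- lapply(strategies, function(s) {
    tr <- simulate_strategy(params, bc, s$control)
    rep <- check_feasibility(tr, s$control, bc, params, tol = 1e-6)
    data.frame(strategy = s$name, t_switch = s$t_switch,
               feasible = is_feasible(rep),
               terminal_energy = terminal_energy(tr))
  })
  do.call(rbind, rows)
}

#' @export
print.life_ocp <- function(x, ...) {
  d <- x$diagnostics
  cat("Optimal lifetime exploration-exploitation strategy\n")
  cat(sprintf("  lifespan T_max = %g, control ceiling = %g\n",
              x$params$T_max, control_ceiling(x$bc, x$params)))
  cat(sprintf("  terminal energy (objective): %.6f\n", x$objective))
  cat(sprintf("  solver: %s, mesh %s, max constraint violation %.2e\n",
              d$status, paste(d$mesh_sizes, collapse = " -> "),
              d$max_defect))
  seg <- tryCatch(classify_phases(x), error = function(e) NULL)
  if (!is.null(seg)) {
    cat("  knowledge phases:\n")
    for (i in seq_len(nrow(seg$segments)))
      cat(sprintf("    %-13s [%6.3f, %6.3f]\n", seg$segments$label[i],
                  seg$segments$t_start[i], seg$segments$t_end[i]))
  }
  invisible(x)
}

#' @export
summary.life_ocp <- function(object, ...) {
  x <- object
  pmp <- tryCatch(check_pmp(x), error = function(e) NULL)
  seg <- tryCatch(classify_phases(x), error = function(e) NULL)
  out <- list(objective = x$objective, params = x$params, bc = x$bc,
              diagnostics = x$diagnostics,
              feasible = is_feasible(x$feasibility),
              min_energy = min(x$E), max_knowledge = max(x$L),
              u0 = x$u[1], uT = x$u[length(x$u)],
              pmp = pmp, segmentation = seg)
  class(out) <- "summary.life_ocp"
  out
}

#' @export
print.summary.life_ocp <- function(x, ...) {
  cat("Lifetime exploration-exploitation optimal control fit\n\n")
  print(x$params)
  cat(sprintf("\nObjective (terminal energy): %.6f\n", x$objective))
  cat(sprintf("Feasible: %s;  min E = %.6f;  max L = %.6f\n",
              x$feasible, x$min_energy, x$max_knowledge))
  cat(sprintf("u*(0) = %.4f;  u*(T) = %.4f\n", x$u0, x$uT))
  if (!is.null(x$segmentation)) {
    cat("\nKnowledge phases:\n")
    print(x$segmentation)
  }
  if (!is.null(x$pmp)) {
    cat("\n")
    print(x$pmp)
  }
  invisible(x)
}

#' @export
coef.life_ocp <- function(object, ...) {
  unlist(object$params)
}

#' Evaluate the fitted optimal strategy and states at arbitrary times
#'
#' @param object A `life_ocp` fit.
#' @param newdata Optional data.frame with a `time` column (or a numeric
#'   vector of times); defaults to the solution mesh.
#' @param ... Unused.
#' @return A data.frame with columns `time`, `E`, `L`, `u` (and `sigma`
#'   when costates are available), linearly interpolated on the mesh.
#' @export
predict.life_ocp <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times
       else if (is.data.frame(newdata)) newdata$time
       else as.numeric(newdata)
  if (any(t < 0 | t > object$params$T_max))
    stop("prediction times outside [0, T_max]")
  out <- data.frame(
    time = t,
    E = stats::approx(object$times, object$E, t, rule = 2)$y,
    L = stats::approx(object$times, object$L, t, rule = 2)$y,
    u = stats::approx(object$times, object$u, t, rule = 2)$y)
  if (!is.null(object$costates))
    out$sigma <- stats::approx(object$costates$time, object$costates$sigma,
                               t, rule = 2)$y
  out
}

#' @export
fitted.life_ocp <- function(object, ...) {
  data.frame(time = object$times, E = object$E, L = object$L, u = object$u)
}

#' @export
residuals.life_ocp <- function(object, ...) {
  n <- length(object$times) - 1L
  hs_defects(c(object$E, object$L, object$u, object$um), n,
             diff(object$times), object$params)
}

#' Plot a fitted optimal strategy
#'
#' Two stacked panels: states (energy and knowledge) and the optimal
#' learning investment, with the knowledge phases shaded.
#'
#' @param x A `life_ocp` fit.
#' @param shade_phases Shade and label the classified knowledge phases.
#' @param ... Passed to `matplot` for the state panel.
#' @export
plot.life_ocp <- function(x, shade_phases = TRUE, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1),
                      mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  seg <- if (shade_phases)
    tryCatch(classify_phases(x), error = function(e) NULL) else NULL
  shades <- c(establishment = "#d0e1f9", accumulation = "#c8e6c9",
              maintenance = "#ffe0b2", exploitation = "#ffcdd2")

  panel_shade <- function(ylim) {
    if (is.null(seg)) return()
    for (i in seq_len(nrow(seg$segments)))
      graphics::rect(seg$segments$t_start[i], ylim[1],
                     seg$segments$t_end[i], ylim[2],
                     col = shades[[seg$segments$label[i]]], border = NA)
    graphics::abline(v = seg$segments$t_end[-nrow(seg$segments)],
                     lty = 2, col = "grey40")
  }

  ylim1 <- range(x$E, x$L)
  graphics::plot(NA, xlim = range(x$times), ylim = ylim1,
                 xlab = "", ylab = "state", ...)
  panel_shade(ylim1)
  graphics::lines(x$times, x$E, col = "blue", lwd = 2)
  graphics::lines(x$times, x$L, col = "darkgreen", lwd = 2, lty = 2)
  graphics::legend("topleft", c("energy E", "knowledge L"),
                   col = c("blue", "darkgreen"), lty = c(1, 2), lwd = 2,
                   bty = "n")

  ylim2 <- c(0, max(x$u) * 1.05 + 1e-9)
  graphics::plot(NA, xlim = range(x$times), ylim = ylim2,
                 xlab = "time", ylab = "u*(t)")
  panel_shade(ylim2)
  graphics::lines(x$times, x$u, col = "red", lwd = 2)
  invisible(x)
}
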