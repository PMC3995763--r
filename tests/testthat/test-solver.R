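test_that("the optimal strategy dominates the heuristic comparison suite", {
  fit <- baseline_fit_reduced()
  hb <- heuristic_benchmark(baseline_params(), baseline_bc())
  best <- max(hb$terminal_energy[hb$feasible])
  expect_gt(fit$objective, best - 1e-3)
  # the suite itself behaves as expected: never-learning is feasible,
  # always-learning is not
  expect_true(hb$feasible[hb$strategy == "never_learn"])
  expect_false(hb$feasible[hb$strategy == "always_learn"])
})

test_that("solution invariants hold on the baseline fit", {
  fit <- baseline_fit()
  # objective is the terminal state
  expect_equal(fit$objective, fit$E[length(fit$E)], tolerance = 1e-6)
  # feasibility at 1e-4
  expect_true(is_feasible(fit$feasibility))
  # defects are resolved
  expect_lt(fit$diagnostics$max_defect, 1e-6)
  expect_identical(fit$diagnostics$status, "converged")
})

test_that("doubling the mesh leaves the baseline objective unchanged", {
  fit <- baseline_fit()
  ro <- fit$diagnostics$round_objectives
  expect_identical(fit$diagnostics$mesh_sizes,
                   c(fit$options$mesh_size %/% 2L, fit$options$mesh_size))
  expect_lt(abs(ro[2] - ro[1]), 1e-4)
  expect_true(fit$diagnostics$mesh_converged)
})

test_that("multistart initial guesses agree on the baseline objective", {
  fit <- suppressWarnings(
    optimal_strategy(baseline_params(), baseline_bc(),
                     reduced_options(n_starts = 5L, seed = 7L)))
  objs <- fit$diagnostics$multistart_objectives
  expect_length(objs, 5L)
  expect_lt(diff(range(objs)), 1e-3)
})

test_that("the collocation objective matches a semi-analytic arc-structure
           benchmark", {
  # Independent construction of the baseline optimum from its known arc
  # structure: ceiling arc until the floor is hit, floor-riding arc
  # until L reaches the singular level L* = sqrt(alpha f_max k_L / m_L)
  # - k_L, singular arc holding L*, then u = 0; the one free junction
  # time is found by line search. Uses only quadrature/root finding,
  # none of the collocation machinery.
  p <- baseline_params(); bc <- baseline_bc()
  intake <- function(L) p$f_max * L / (L + p$k_L)
  Lstar <- sqrt(p$alpha * p$f_max * p$k_L / p$m_L) - p$k_L
  us <- p$m_L * Lstar / p$alpha
  gs <- intake(Lstar) - p$m - us
  Lt <- function(t) (p$alpha / p$m_L) * (1 - exp(-p$m_L * t))
  Et <- function(t) bc$E0 - (p$m + 1) * t +
    integrate(function(s) intake(Lt(s)), 0, t, rel.tol = 1e-12)$value
  t1 <- uniroot(function(t) Et(t) - bc$E_min, c(0.1, 2),
                tol = 1e-12)$root
  t2 <- t1 + integrate(function(L)
    1 / (p$alpha * (intake(L) - p$m) - p$m_L * L),
    Lt(t1), Lstar, rel.tol = 1e-12)$value
  obj <- function(t3) bc$E_min + gs * (t3 - t2) - p$m * (p$T_max - t3) +
    integrate(function(s) intake(Lstar * exp(-p$m_L * (s - t3))),
              t3, p$T_max, rel.tol = 1e-12)$value
  ref <- optimize(obj, c(t2, p$T_max), maximum = TRUE,
                  tol = 1e-10)$objective

  fit <- baseline_fit()
  expect_lt(abs(fit$objective - ref), 5e-4)
  # and the solved phase boundaries sit near the analytic junctions
  seg <- classify_phases(fit)$segments
  expect_lt(abs(seg$t_end[1] - t1), 0.2)   # establishment -> accumulation
  expect_lt(abs(seg$t_end[2] - t2), 1.0)   # accumulation -> maintenance
})

test_that("costates satisfy the terminal conditions and adjoint structure", {
  fit <- baseline_fit()
  cs <- fit$costates
  n <- nrow(cs)
  expect_equal(cs$lambda_E[n], 1)
  expect_equal(cs$lambda_L[n], 0)
  expect_equal(cs$sigma[n], -1)
  # off the floor arc lambda_E is constant (= 1 after the arc)
  after <- cs$time > 10
  expect_true(all(abs(cs$lambda_E[after] - 1) < 1e-10))
  # the shadow price of knowledge is strictly positive before the end
  before_T <- cs$time > 10 & cs$time < fit$params$T_max - 0.5
  expect_true(all(cs$lambda_L[before_T] > 0))
  # costates are undefined for infeasible trajectories
  p <- fit$params; bc <- fit$bc
  tr <- simulate_strategy(p, bc, constant_control(1, p$T_max))
  bad <- list(times = tr$time, E = tr$E, L = tr$L, u = tr$u,
              params = p, bc = bc)
  expect_error(estimate_costates(bad), "infeasible")
})

test_that("the switching function separates the control arcs", {
  fit <- baseline_fit()
  expect_equal(switching_function(fit, fit$params$T_max), -1,
               tolerance = 1e-8)
  # establishment arc: investing must not look bad (sigma >= 0 up to tol)
  expect_gt(switching_function(fit, 0.1), -0.02)
  # maintenance (singular) arc: sigma ~ 0
  expect_lt(abs(switching_function(fit, 7)), 0.05)
  # exploitation arc: sigma decisively negative
  expect_lt(switching_function(fit, 15), -0.1)
  expect_error(switching_function(fit, -1), "outside")
  expect_error(switching_function(fit, 21), "outside")
})

test_that("the Pontryagin consistency check passes on the optimum and
           fails on corrupted solutions", {
  fit <- baseline_fit()
  expect_true(check_pmp(fit)$pass)

  # corrupt the final arc: add 0.3 to u after t = 10 and re-simulate
  # that tail from the solved state at t = 10 (re-simulating the whole
  # life would drift off the floor-riding arc and confound the check)
  p <- fit$params; bc <- fit$bc
  i0 <- which(fit$times >= 10)[1]
  tail_t <- fit$times[i0:length(fit$times)]
  p_tail <- suppressWarnings(
    model_params(p$f_max, p$k_L, p$m, p$alpha, p$m_L,
                 T_max = max(tail_t) - tail_t[1]))
  bc_tail <- boundary_constraints(E0 = fit$E[i0], L0 = fit$L[i0],
                                  E_min = bc$E_min)
  u_tail <- pmin(fit$u[i0:length(fit$u)] + 0.3, 1)
  tr <- simulate_strategy(p_tail, bc_tail,
                          control_schedule(tail_t - tail_t[1], u_tail),
                          step = 0.01)
  keep <- seq(1L, nrow(tr), by = 10L)
  bad <- list(
    times = c(fit$times[1:(i0 - 1L)], tr$time[keep] + tail_t[1]),
    E = c(fit$E[1:(i0 - 1L)], tr$E[keep]),
    L = c(fit$L[1:(i0 - 1L)], tr$L[keep]),
    u = c(fit$u[1:(i0 - 1L)], tr$u[keep]),
    params = p, bc = bc)
  expect_false(check_pmp(bad)$pass)

  # a never-learning "solution" violates sigma > 0 near the start
  tr0 <- simulate_strategy(p, bc, constant_control(0, p$T_max))
  lazy <- list(times = tr0$time, E = tr0$E, L = tr0$L,
               u = rep(0, nrow(tr0)), params = p, bc = bc)
  expect_false(check_pmp(lazy)$pass)
})

test_that("the survival floor binds on one contiguous interval only", {
  fit <- baseline_fit()
  active <- fit$E - fit$bc$E_min < 1e-4
  # arc entry/exit nodes sit mid-transition a few 1e-4 above the floor;
  # close single-point gaps before counting contiguous runs
  n <- length(active)
  interior <- 2:(n - 1L)
  active[interior] <- active[interior] |
    (active[interior - 1L] & active[interior + 1L])
  runs <- rle(active)
  expect_identical(sum(runs$values), 1L)
  # strictly above the floor after the constrained arc ends
  last_active <- max(which(active))
  expect_true(all(fit$E[(last_active + 1L):n] > fit$bc$E_min + 1e-4))
})

test_that("solver options validate their invariants", {
  expect_error(solver_options(mesh_size = 10), "at least 20")
  expect_error(solver_options(tol = 0), "positive")
  expect_error(solver_options(eps_schedule = c(1e-2, 1e-3)), "end at 0")
})

test_that("the fit object supports the standard S3 interface", {
  fit <- baseline_fit_reduced()
  expect_named(coef(fit),
               c("f_max", "k_L", "m", "alpha", "m_L", "T_max"))
  pr <- predict(fit, newdata = c(0, 5, 20))
  expect_equal(pr$time, c(0, 5, 20))
  expect_equal(pr$E[1], fit$bc$E0)
  expect_error(predict(fit, newdata = 25), "outside")
  expect_lt(max(abs(residuals(fit))), 1e-6)
  ft <- fitted(fit)
  expect_identical(nrow(ft), length(fit$times))
  expect_output(print(fit), "terminal energy")
  expect_output(print(summary(fit)), "Knowledge phases")
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
})
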