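test_that("with only u = 0 available the rollout matches the closed form", {
  p <- model_params(); bc <- boundary_constraints()
  g <- dp_grid(n_t = 100L, E_grid = seq(5, 8, length.out = 40),
               L_grid = seq(0, 1, length.out = 20), u_levels = 0)
  dp <- dp_solve(p, bc, g)
  # no learning possible: E(T) = E0 - m T exactly (linear dynamics)
  expect_equal(dp$objective, bc$E0 - p$m * p$T_max, tolerance = 1e-9)
  expect_true(all(dp$rollout$u == 0))
})

test_that("the value function is monotone in both states", {
  p <- model_params(); bc <- boundary_constraints()
  g <- dp_grid(n_t = 60L, E_grid = seq(5, 12, length.out = 40),
               L_grid = seq(0, 16, length.out = 40),
               u_levels = seq(0, 1, length.out = 6))
  dp <- dp_solve(p, bc, g)
  V <- dp$value
  expect_true(all(diff(V) >= -1e-9))        # along E
  expect_true(all(t(diff(t(V))) >= -1e-9))  # along L
})

test_that("refining the grid does not lose terminal energy", {
  p <- model_params(); bc <- boundary_constraints()
  coarse <- dp_grid(n_t = 100L, E_grid = seq(5, 15, length.out = 40),
                    L_grid = seq(0, 15.625, length.out = 40),
                    u_levels = seq(0, 1, length.out = 6))
  fine <- dp_grid(n_t = 200L, E_grid = seq(5, 15, length.out = 80),
                  L_grid = seq(0, 15.625, length.out = 80),
                  u_levels = seq(0, 1, length.out = 11))
  o1 <- dp_solve(p, bc, coarse)$objective
  o2 <- dp_solve(p, bc, fine)$objective
  # finer menus and grids weakly dominate, up to discretization noise
  expect_gt(o2, o1 - 0.05)
})

test_that("the DP value at the initial state dominates every heuristic", {
  dp <- baseline_dp()
  hb <- heuristic_benchmark(baseline_params(), baseline_bc())
  best <- max(hb$terminal_energy[hb$feasible])
  g <- dp$grid
  jE <- findInterval(baseline_bc()$E0, g$E_grid)
  wE <- (baseline_bc()$E0 - g$E_grid[jE]) / diff(g$E_grid)[jE]
  v0 <- dp$value[jE, 1] * (1 - wE) + dp$value[jE + 1, 1] * wE
  expect_gt(v0, best - 0.1)
})

test_that("DP grid specification validates its invariants", {
  expect_error(dp_grid(n_t = 10, E_grid = 1:2, L_grid = 1:2,
                       u_levels = 0), "at least 50")
  expect_error(dp_grid(n_t = 60, E_grid = c(2, 1), L_grid = 1:2,
                       u_levels = 0), "strictly increasing")
  expect_error(
    dp_solve(model_params(),
             boundary_constraints(E0 = 20),
             dp_grid(n_t = 60, E_grid = seq(5, 15, length.out = 20),
                     L_grid = seq(0, 10, length.out = 20),
                     u_levels = c(0, 1))),
    "outside the DP grid")
})

test_that("comparing a solution against its own policy gives zero gap", {
  fit <- baseline_fit_reduced()
  fake <- structure(
    list(objective = fit$objective,
         rollout = data.frame(time = fit$times, E = fit$E, L = fit$L,
                              u = fit$u),
         params = fit$params, bc = fit$bc, grid = NULL),
    class = "dp_solution")
  cmp <- compare_with_ocp(fit, fake)
  expect_equal(cmp$objective_gap, 0)
  expect_lt(cmp$policy_sup_distance, 1e-9)
  expect_true(cmp$pass)
})

test_that("the comparison guards against mismatched inputs", {
  fit <- baseline_fit_reduced()
  dp <- baseline_dp()
  expect_error(
    compare_with_ocp(
      suppressWarnings(optimal_strategy(model_params(T_max = 10),
                                        baseline_bc(),
                                        reduced_options(mesh_size = 40L))),
      dp),
    "mismatch")
  cmp <- compare_with_ocp(fit, dp)
  expect_true(cmp$objective_gap >= 0)
  expect_output(print(cmp), "objective")
})
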