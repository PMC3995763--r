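test_that("rate laws reproduce hand-computed values", {
  p <- model_params()
  # zero knowledge: no intake, pure maintenance loss
  expect_equal(energy_rate(5.5, L = 0, u = 0, p), -0.02)
  # half-saturation: f_max * 1/(1+1) - m
  expect_equal(energy_rate(5.5, L = 1, u = 0, p), 0.48)
  # saturation limit: intake -> f_max, so rate -> f_max - m - u
  expect_equal(energy_rate(5.5, L = 1e9, u = 1, p), 1 - 0.02 - 1,
               tolerance = 1e-6)
  expect_equal(knowledge_rate(L = 0, u = 0, p), 0)
  expect_equal(knowledge_rate(L = 0, u = 1, p), 1)
  # fixed point L* = alpha u / m_L for any constant u
  for (u in c(0.1, 0.5, 1))
    expect_equal(knowledge_rate(L = p$alpha * u / p$m_L, u = u, p), 0)
})

test_that("rate laws reject negative states and controls", {
  p <- model_params()
  expect_error(energy_rate(5, L = -1, u = 0, p), "non-negative")
  expect_error(energy_rate(5, L = 0, u = -0.1, p), "non-negative")
  expect_error(knowledge_rate(L = -1, u = 0, p), "non-negative")
})

test_that("energy rate is increasing in L, decreasing in u, bounded", {
  p <- model_params(f_max = 2, k_L = 0.7)
  L <- seq(0, 50, length.out = 200)
  r <- energy_rate(5, L, u = 0.3, p)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < p$f_max - p$m))
  u <- seq(0, 1, length.out = 50)
  expect_true(all(diff(energy_rate(5, L = 2, u, p)) < 0))
})

test_that("parameter constructor validates and warns out-of-range", {
  expect_error(model_params(f_max = -1), "strictly positive")
  expect_error(model_params(T_max = 0), "strictly positive")
  expect_warning(model_params(f_max = 20), "outside the studied range")
  expect_warning(model_params(m = 0.5), "outside the studied range")
  expect_silent(model_params())
})

test_that("boundary constraints enforce their invariants", {
  expect_error(boundary_constraints(E0 = 4.9), "must exceed")
  expect_error(boundary_constraints(L0 = -1), "at least")
  expect_error(boundary_constraints(u_max = 0), "exceed u_min")
  bc <- boundary_constraints()
  expect_equal(control_ceiling(bc, model_params()), 1)
  expect_equal(control_ceiling(bc, model_params(f_max = 0.5)), 0.5)
})

test_that("simulation matches the closed form for u = 0", {
  p <- model_params(); bc <- boundary_constraints()
  tr <- simulate_strategy(p, bc, constant_control(0, p$T_max))
  expect_true(all(tr$L == 0))
  expect_lt(max(abs(tr$E - (bc$E0 - p$m * tr$time))), 1e-6)
  expect_equal(terminal_energy(tr), 5.1, tolerance = 1e-9)
})

test_that("simulation matches the exponential closed form for constant u", {
  p <- model_params(); bc <- boundary_constraints()
  for (cu in c(0.2, 1)) {
    tr <- simulate_strategy(p, bc, constant_control(cu, p$T_max))
    Lexact <- (p$alpha * cu / p$m_L) * (1 - exp(-p$m_L * tr$time))
    expect_lt(max(abs(tr$L - Lexact)), 1e-6)
    # spot checks at mid-life and end of life
    for (tq in c(p$T_max / 2, p$T_max)) {
      i <- which.min(abs(tr$time - tq))
      expect_equal(tr$L[i],
                   (p$alpha * cu / p$m_L) * (1 - exp(-p$m_L * tq)),
                   tolerance = 1e-6)
    }
  }
})

test_that("constant-u knowledge converges monotonically to its fixed point", {
  p <- model_params(); bc <- boundary_constraints()
  cu <- 0.5
  tr <- simulate_strategy(p, bc, constant_control(cu, p$T_max))
  Lstar <- p$alpha * cu / p$m_L
  expect_true(all(diff(tr$L) > 0))
  expect_true(all(tr$L < Lstar))
})

test_that("halving the integration step leaves terminal energy unchanged", {
  p <- model_params(); bc <- boundary_constraints()
  ctrl <- control_schedule(c(0, 5, 20), c(1, 0.3, 0))
  e1 <- terminal_energy(simulate_strategy(p, bc, ctrl,
                                          step = p$T_max / 2000))
  e2 <- terminal_energy(simulate_strategy(p, bc, ctrl,
                                          step = p$T_max / 4000))
  expect_lt(abs(e1 - e2), 1e-8)
})

test_that("terminal energy is the last energy entry", {
  tr <- data.frame(time = c(0, 1), E = c(5.5, 6.2), L = c(0, 1),
                   u = c(1, 1))
  expect_equal(terminal_energy(tr), 6.2)
  # degenerate single-point trajectory: the initial state is terminal
  expect_equal(terminal_energy(data.frame(time = 0, E = 5.5, L = 0)),
               5.5)
  expect_error(terminal_energy(data.frame()), "empty")
})

test_that("feasibility checking flags each constraint separately", {
  p <- model_params(); bc <- boundary_constraints()
  # never-learn baseline stays feasible (E ends at 5.1 >= 5)
  tr0 <- simulate_strategy(p, bc, constant_control(0, p$T_max))
  expect_true(is_feasible(check_feasibility(tr0, NULL, bc, p)))
  # all-in learning crashes through the floor early: E'(0) = -1.02
  ctrl1 <- constant_control(1, p$T_max)
  tr1 <- simulate_strategy(p, bc, ctrl1)
  rep1 <- check_feasibility(tr1, ctrl1, bc, p)
  expect_false(is_feasible(rep1))
  expect_true("E" %in% rep1$quantity)
  # out-of-bounds control value
  ctrl2 <- control_schedule(c(0, 20), c(1.5, 1.5))
  rep2 <- check_feasibility(tr0, ctrl2, bc, p)
  expect_true("u_high" %in% rep2$quantity)
})

test_that("control schedules interpolate as declared", {
  lin <- control_schedule(c(0, 10, 20), c(1, 0.5, 0))
  expect_equal(control_function(lin)(5), 0.75)
  con <- control_schedule(c(0, 10, 20), c(1, 0.5, 0),
                          interpolation = "constant")
  f <- control_function(con)
  expect_equal(f(9.99), 1)     # right-open: value held from the left node
  expect_equal(f(10), 0.5)
  expect_error(control_schedule(c(1, 2), c(0, 0)), "start at t = 0")
  expect_error(control_schedule(c(0, 0), c(0, 0)), "strictly increasing")
})
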