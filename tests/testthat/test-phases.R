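test_that("a constructed four-segment strategy is labeled a,b,c,d with the
           right fractions", {
  traj <- synthetic_four_phase()
  seg <- classify_phases(traj, params = baseline_params(),
                         bc = baseline_bc())
  expect_identical(seg$segments$label,
                   c("establishment", "accumulation", "maintenance",
                     "exploitation"))
  fr <- phase_fractions(seg)
  # phase boundaries are placed at cell midpoints, so the nominal
  # fractions are recovered to within half a grid step over the lifespan
  expect_lt(max(abs(fr - c(0.1, 0.4, 0.3, 0.2))), 0.05 / 2 / 20 + 1e-12)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_identical(seg$n_forced_merges, 0L)
})

test_that("classification is idempotent on rule-built trajectories", {
  traj <- synthetic_four_phase()
  s1 <- classify_phases(traj, params = baseline_params(),
                        bc = baseline_bc())
  s2 <- classify_phases(traj, params = baseline_params(),
                        bc = baseline_bc())
  expect_identical(s1$segments, s2$segments)
})

test_that("a never-learning life is a single exploitation phase", {
  p <- baseline_params(); bc <- baseline_bc()
  tr <- simulate_strategy(p, bc, constant_control(0, p$T_max))
  seg <- classify_phases(as.data.frame(tr), params = p, bc = bc)
  expect_identical(seg$segments$label, "exploitation")
  expect_equal(seg$segments$t_start, 0)
  expect_equal(seg$segments$t_end, p$T_max)
  fr <- phase_fractions(seg)
  expect_equal(unname(fr["exploitation"]), 1)
  expect_equal(unname(fr["maintenance"]), 0)
})

test_that("segments are contiguous, ordered and cover the lifespan", {
  fit <- baseline_fit_reduced()
  seg <- classify_phases(fit)
  s <- seg$segments
  expect_equal(s$t_start[1], 0)
  expect_equal(s$t_end[nrow(s)], fit$params$T_max)
  if (nrow(s) > 1)
    expect_equal(s$t_start[-1], s$t_end[-nrow(s)])
  ord <- match(s$label,
               c("establishment", "accumulation", "maintenance",
                 "exploitation"))
  expect_true(all(diff(ord) > 0))
  expect_equal(sum(phase_fractions(seg)), 1, tolerance = 1e-12)
})

test_that("classification refuses infeasible and empty trajectories", {
  p <- baseline_params(); bc <- baseline_bc()
  ctrl <- constant_control(1, p$T_max)
  tr <- simulate_strategy(p, bc, ctrl)   # dives below the floor
  expect_error(classify_phases(as.data.frame(tr), params = p, bc = bc),
               "infeasible")
  expect_error(classify_phases(data.frame(), params = p, bc = bc),
               "empty")
})

test_that("fractions account for absent phases with zeros", {
  p <- baseline_params(); bc <- baseline_bc()
  tr <- simulate_strategy(p, bc, constant_control(0, p$T_max))
  seg <- classify_phases(as.data.frame(tr), params = p, bc = bc)
  fr <- phase_fractions(seg)
  expect_named(fr, c("establishment", "accumulation", "maintenance",
                     "exploitation"))
  expect_equal(sum(fr == 0), 3L)
})
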