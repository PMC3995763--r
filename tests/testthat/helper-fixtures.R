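# Shared fixtures. The full-accuracy baseline solve is expensive, so it
# is computed once per test session and memoized; everything that only
# needs the qualitative solution uses the reduced-accuracy solve.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

baseline_params <- function() model_params()
baseline_bc <- function() boundary_constraints()

# full-accuracy baseline fit (default solver options)
baseline_fit <- function() memoize("baseline_fit", {
  suppressWarnings(optimal_strategy(baseline_params(), baseline_bc(),
                                    solver_options()))
})

# reduced-accuracy baseline fit for structure-level checks
baseline_fit_reduced <- function() memoize("baseline_fit_reduced", {
  suppressWarnings(optimal_strategy(baseline_params(), baseline_bc(),
                                    reduced_options()))
})

baseline_dp <- function() memoize("baseline_dp", {
  dp_solve(baseline_params(), baseline_bc())
})

# one draw from the studied parameter box (log-uniform for the
# scale-like parameters)
draw_params <- function() {
  suppressWarnings(model_params(
    f_max = stats::runif(1, 0.5, 10),
    k_L = exp(stats::runif(1, log(0.001), log(10))),
    alpha = stats::runif(1, 0.5, 10),
    m_L = exp(stats::runif(1, log(0.01), log(1))),
    T_max = stats::runif(1, 5, 100)))
}

# the synthetic four-segment strategy used to pin down the classifier:
# each segment satisfies exactly one labeling rule
synthetic_four_phase <- function() {
  p <- baseline_params(); bc <- baseline_bc()
  tt <- seq(0, 20, by = 0.05)
  u <- numeric(length(tt)); E <- numeric(length(tt)); L <- numeric(length(tt))
  est <- tt < 2; acc <- tt >= 2 & tt < 10
  mnt <- tt >= 10 & tt < 16; xpl <- tt >= 16
  L[est] <- 0.5 * tt[est]; L[acc] <- 1 + (tt[acc] - 2) / 8
  L[mnt] <- 2; L[xpl] <- 2 * exp(-p$m_L * (tt[xpl] - 16))
  u[est] <- 1
  u[acc] <- p$f_max * L[acc] / (L[acc] + p$k_L) - p$m
  u[mnt] <- p$m_L * L[mnt] / p$alpha
  u[xpl] <- 0
  E[est] <- 5.4; E[acc] <- 5; E[mnt] <- 6; E[xpl] <- 7
  data.frame(time = tt, E = E, L = L, u = u)
}
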