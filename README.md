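# explife

Optimal lifetime exploration–exploitation strategies by optimal control.

Organisms, people and organizations all face the same scheduling
problem: energy spent learning about the environment cannot be spent
exploiting it, yet exploitation is only as good as the knowledge behind
it. `explife` implements a minimal life-history model of this
trade-off and computes the optimal learning schedule over a lifetime.

## The model

Two states — energy `E(t)` and knowledge `L(t)` — and one control, the
learning-investment rate `u(t)`:

    dE/dt = f_max · L/(L + k_L) − m − u        (intake saturates with knowledge)
    dL/dt = α·u − m_L·L                        (learning minus forgetting)

The strategy `u*(t)` maximizes terminal energy `E(T_max)` subject to a
survival floor `E(t) ≥ E_min` and bounds `u ∈ [0, min(u_max, f_max)]`.
The solver uses direct Hermite–Simpson collocation with an
augmented-Lagrangian NLP (analytic gradients, vanishing
control-smoothing continuation for the singular arc), recovers costates
by backward adjoint integration, and audits the solution against
Pontryagin's maximum principle and an independent dynamic-programming
oracle.

Optimal lives decompose into at most four phases in a fixed order —
knowledge **establishment** (all-in exploration), **accumulation**
(learning while pinned at the survival floor), **maintenance** (holding
knowledge at its optimal level), and **exploitation** (zero investment)
— and the package classifies solved trajectories accordingly and sweeps
the phase diagram over lifespan and environmental parameters.

## Worked example

```r
library(explife)

fit <- optimal_strategy(model_params(), boundary_constraints())
print(fit)
#> Optimal lifetime exploration-exploitation strategy
#>   lifespan T_max = 20, control ceiling = 1
#>   terminal energy (objective): 13.554213
#>   solver: converged, mesh 200 -> 400, max constraint violation 3.73e-09
#>   knowledge phases:
#>     establishment [ 0.000,  0.625]
#>     accumulation  [ 0.625,  5.625]
#>     maintenance   [ 5.625,  9.425]
#>     exploitation  [ 9.425, 20.000]
```

The subject spends its initial reserves learning at full tilt until it
hits the survival floor at `t ≈ 0.63`, then learns as fast as intake
allows while riding the floor, holds knowledge at the singular level
`L* = √(α·f_max·k_L/m_L) − k_L ≈ 2.54` while banking energy, and stops
investing entirely for the final half of its life. Its lifetime surplus
is `13.55` energy units — against `5.1` for a subject that never
learns (`heuristic_benchmark()` evaluates such comparison strategies).

```r
plot(fit)        # states and control with shaded phases
check_pmp(fit)
#> Pontryagin bang-bang consistency: PASS (100.0% of 311 points, 0 violations)
#>   terminal switching value sigma(T) = -1.0000 (theory: -1)
compare_with_ocp(fit, dp_solve(model_params()))
#> OCP vs DP oracle: PASS
#>   objective 13.554213 (OCP) vs 13.513387 (DP rollout): relative gap 0.0030 (tol 0.05)
#>   policy sup-distance 0.197 of ceiling (tol 0.25)
sweep_parameter("T_max")  # phase diagram vs lifespan
```

A thin command-line tool wraps the same functions:

```sh
Rscript inst/cli/explife solve --set T_max=10 --out results/
Rscript inst/cli/explife simulate --strategy constant:0 --out results/
```

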