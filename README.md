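# aggdiffenv

Aggregation–diffusion dynamics in heterogeneous environments, in one
spatial dimension.

## What this package is for

Aggregation–diffusion equations link the movement mechanisms of organisms —
diffusive exploration, nonlocal attraction to conspecifics, and drift up a
resource gradient — to the space-use patterns that emerge from them. They
are used for animal home ranges and herds as much as for cellular
aggregates forming along chemical gradients. Most analysis of these models
assumes a homogeneous environment; this package is for the heterogeneous
case, where self-attraction and resource attraction combine (sometimes
counter-intuitively) to set the size and shape of an aggregation.

The dimensionless model on $[-1,1]$, for density $u(x,t)$ with conserved
mass $p$, self-attraction strength $\gamma$ and landscape $A(x)$, is

$$\partial_t u = \partial_x\big(u\,\partial_x[\,u - \gamma K*u - A\,]\big)$$

for quadratic diffusion with interaction kernel $K$, together with its
local fourth-order approximation (replace $K*u$ by
$u + \tfrac{\sigma^2}{2}u''$) and a linear-diffusion variant. For
$\gamma > 1$ and a single clump of resources
$A(x) = a_n[1+\cos(n\pi x)]$ on $|x|<1/n$, steady aggregations supported on
$[-r,r]$ have the closed form

$$u_*(x) = \alpha_0 + \alpha_n[1+\cos(n\pi x)] + Q\cos(\pi x/r_0),
\qquad r_0 = \pi\sqrt{\tfrac{\gamma\sigma^2}{2(\gamma-1)}},$$

with $(\alpha_0, Q)$ pinned by mass and continuity. Minimising the
associated energy functional over the single free half-width $r$ predicts
the emergent pattern in a fraction of a second, where time-stepping the PDE
takes minutes; the package provides both routes plus the diagnostics that
tie them together (widths, peak counts, parameter sweeps, mass/positivity/
energy-dissipation audits).

## Worked example

```r
library(aggdiffenv)

params <- model_params(gamma = 2, sigma = 0.1, p = 1)
env    <- clump_env(n = 1, amplitude = 1)

# analytic route: minimum-energy single aggregation
fit <- minimise_energy(params, env)
#> r* = 0.2993  width = 0.5985  peak = 3.3170  energy = -5.4728
# (with amplitude = 0 this returns r* = r0 = 0.3142 exactly)

# how aggregation width depends on resource-clump width 2/n
sweep_parameter(params, env, "n", c(2, 4, 6, 8, 12, 16))
#>   value r_star  width peak_height energy
#> 1     2 0.2773 0.5547       3.557 -5.182
#> 2     4 0.2528 0.5055       3.923 -4.423
#> 3     6 0.2337 0.4674       3.928 -3.721
#> 4     8 0.2376 0.4753       3.784 -3.228
#> 5    12 0.2507 0.5013       3.564 -2.683
#> 6    16 0.2610 0.5220       3.442 -2.405

# PDE route: same answer from time-stepping the fourth-order model
grid <- make_grid(0.01)
u0   <- make_initial_condition("flat_min", grid, gamma = 2, sigma = 0.1)
cfg  <- solver_config("quadratic_local4", gamma = 2, sigma = 0.1, env = env,
                      dt = 3e-8, tol = 1e-8, max_time = 2)
sim  <- run_to_steady(u0, grid, cfg)
max(abs(sim$u - candidate_value(fit$sol, grid$x)))
#> converged: TRUE at t = 0.021; L-inf gap to analytic = 0.0018
```

Read the sweep bottom-up: the aggregation is *narrowest and tallest at the
intermediate clump width* $n = 6$ — clumps narrower than that make the
aggregation slightly wider again, because the self-attraction range takes
over from the resource edge in setting the support. The PDE run confirms
the analytic minimiser to well within a grid cell.

A command-line front end covers the same ground
(`minimise`, `energy-curve`, `simulate`, `sweep`, `validate`):

```sh
Rscript -e 'aggdiffenv::run_cli()' minimise --gamma 2 --sigma 0.1 \
        --n 1 --amplitude 1 --log fit.json --out profile.csv
```

## Layout

- `R/` — landscapes, kernels, steady-state families, energy functionals and
  minimisation, solver front end, metrics/sweeps, config/CLI.
- `src/solver.cpp` — positivity-preserving upwind finite-volume stepper for
  the three schemes, with per-step mass/energy/positivity tracking.
- `vignettes/energy-minimisation.Rmd` — the model, its assumptions, the
  numerical choices, and the package's design decisions.
- `tests/testthat/` — unit, property and acceptance suites.
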