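---
title: "Aggregation–diffusion in heterogeneous environments: models, steady states, and energy minimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregation–diffusion in heterogeneous environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggdiffenv)
```

## The models

`aggdiffenv` studies the space-use patterns of a population of organisms (or
cells) whose movement combines three mechanisms: diffusion, nonlocal
attraction to conspecifics, and drift up the gradient of a fixed resource
landscape $A(x)$. After non-dimensionalisation onto the unit half-period
domain $[-1, 1]$ (see `nondimensionalise()`), the quadratic-diffusion model
with a Laplace interaction kernel $K_m(x) = \tfrac{m}{2} e^{-m|x|}$ reads

$$\partial_t u = \partial_x\!\big(u\, \partial_x [\, u - \gamma K_m\!*u - A \,]\big),$$

and replacing $K*u$ by its second-order expansion
$u + \tfrac{\sigma^2}{2} u''$ (valid for any symmetric kernel with standard
deviation $\sigma$) gives the local fourth-order, Cahn–Hilliard-type variant

$$\partial_t u = \partial_x\!\big(u\, \partial_x [\, (1-\gamma) u -
\tfrac{\gamma\sigma^2}{2} u'' - A \,]\big).$$

Here $\gamma$ is the self-attraction strength relative to diffusion, and
$\gamma = 1$ is the Turing threshold above which a flat state aggregates
spontaneously. Both equations conserve the total mass
$p = \int u \,\mathrm{d}x$. A linear-diffusion variant
($\partial_t u = \partial_x[\partial_x u - u\,\partial_x(\gamma K*u + A)]$)
is available in the solver for comparison; it admits no closed-form steady
states because its steady-state relation involves $\ln u$.

## Steady states on a connected support component

For $\gamma \ne 1$ and bounded support, every steady state restricted to a
connected component of its support is a particular part tracking the
landscape plus a homogeneous part of the self-attraction:
`proposition_solution()` evaluates the full family for a Fourier landscape.
Each landscape mode $n$ enters multiplied by `mode_factor()`:
$2 / (2(1-\gamma) + \gamma\sigma^2 n^2\pi^2)$ in the fourth-order family and
$(n^2\pi^2 + m^2)/(n^2\pi^2 + m^2(1-\gamma))$ in the Laplace family. The
homogeneous part oscillates at the intrinsic frequency
$w = \sqrt{2(\gamma-1)/(\gamma\sigma^2)}$ (fourth-order; $m\sqrt{\gamma-1}$
for Laplace) when $\gamma > 1$, and is a pair of real exponentials when
$\gamma < 1$. The $\gamma < 1$ branch is implemented for completeness of the
classification but excluded from minimisation, which targets the aggregating
regime. When a landscape mode hits the intrinsic frequency the mode factor's
denominator vanishes (resonance); the solution family printed here
degenerates and the package raises a classed error rather than returning a
secular solution. The guard triggers at $|{\rm denominator}| < 10^{-9}$.

On a flat landscape the minimum-energy state is the half-cosine bump
$(p/2r_0)[1 + \cos(\pi x / r_0)]$ with half-width
$r_0 = \pi\sqrt{\gamma\sigma^2 / (2(\gamma-1))}$ (`homogeneous_minimiser()`,
`r0_of()`); note $w = \pi/r_0$.

## The single-clump candidate family

For a landscape consisting of one clump of attractive resources,
$A(x) = a_n[1+\cos(n\pi x)]$ on $|x| < 1/n$, the package searches the
symmetric single-aggregation ansatz supported on $[-r, r]$:

$$u_*(x) = \alpha_0 + \alpha_n[1 + \cos(n\pi x)] + Q\cos(w x),$$

with the clump term present only on $|x| < 1/n$ and the constant
$\alpha_n$ fixed by the mode factor. The remaining constants
$(\alpha_0, Q)$ are determined *simultaneously* by the mass constraint
$\int u_* = p$ and continuity $u_*(\pm r) = 0$; although these constraints
can be written sequentially, each involves both unknowns, so
`build_candidate()` solves them as a $2\times2$ linear system. The odd
amplitude ($P \sin$) is fixed at zero: the search is restricted to profiles
symmetric about the origin, matching the symmetric landscapes considered.
A candidate is *admissible* only if it is non-negative; `is_admissible()`
scans a 4096-point grid and polishes every interior critical point of the
two-cosine sum by bracketed root finding on $u_*'$, declaring failure below
$-10^{-12}$ (the tolerance separates round-off from genuine negativity —
narrow negative dips near the support edge are otherwise easy to miss).

### The two branches, and an honest caveat

When $r \le 1/n$ the ansatz satisfies the steady-state ODE
$c + A = (1-\gamma)u - \tfrac{\gamma\sigma^2}{2}u''$ exactly on the whole
support, with one constant $c$. When $r > 1/n$ the support extends past the
clump edge and the ansatz keeps the same $\alpha_0$ and $Q$ on both sides.
Matching the $\cos(n\pi x)$ coefficients inside the clump forces the mode
factor value of $\alpha_n$, and a short calculation then shows the
integration constant differs across $|x| = 1/n$ by
$\alpha_n \gamma\sigma^2 n^2\pi^2/2$: the two-branch profile is $C^1$ but
solves the ODE only piecewise, with an $O(1)$ jump in the drift potential at
the clump edge. It is therefore an approximate (weak) steady state off the
first branch. Two consequences are documented and tested:

* `steady_residual()` fits the free constant $c$ by least squares *per
  smooth piece*; with a single $c$ the residual of the printed family would
  be $O(\alpha_n\gamma\sigma^2 n^2\pi^2)$ for $r > 1/n$ by construction.
* the converged PDE state agrees with the minimum-energy candidate to grid
  resolution when $r^* < 1/n$, but is systematically a few percent wider
  when $r^* > 1/n$ (e.g. $\sim 0.03$–$0.04$ in width at
  $\Delta x = 10^{-2}$ for $n = 6, 16$ at default parameters). The
  qualitative conclusions drawn from the family (notably the
  non-monotonicity in $n$) are reproduced by the PDE runs regardless.

## Energy functionals

The fourth-order model dissipates

$$E_2[u] = \int u\big[(1-\gamma)u - 2A - \tfrac{\gamma\sigma^2}{2}u''\big]\mathrm{d}x,$$

and on the candidate family the per-piece ODE collapses $E_2$ to integrals
of products of cosines, which `energy_E2_closed()` evaluates in closed form;
`energy_E2_quadrature()` is the independent composite-Simpson route (exact
piecewise second derivatives for candidates, centred differences for
gridded states), and the two agree to round-off.

For the nonlocal model the package uses

$$E_1[u] = \int u\,[\,u - 2A - \gamma K_m\!*u\,]\,\mathrm{d}x,$$

whose variational derivative is $2[u - \gamma K*u - A]$, giving
$\mathrm{d}E_1/\mathrm{d}t = -2\int u\,(\partial_x[u - \gamma K*u - A])^2 \le 0$
along non-negative solutions. (A variant with $(1-\gamma)u^2$ as the local
term is sometimes written by analogy with $E_2$, but it does not satisfy
this dissipation identity — the $-\gamma u^2$ piece double-counts the local
part of the kernel — and it is unbounded below under concentration, which
would drive the half-width search to $r \to 0$. The form above is the one
whose decrease the solver verifies numerically.) On Laplace-family
candidates the convolution is evaluated semi-analytically
(`laplace_convolution()`: closed-form exponential-against-cosine integrals
per piece, checked against direct integration to $10^{-8}$), so the
Laplace-model energy needs no grid.

For the linear-diffusion scheme, which has no bounded-density analogue of
$E_1$/$E_2$, the solver tracks the standard free energy
$\int [\,2u\ln u - 2Au - \gamma u K\!*u\,]\mathrm{d}x$, which the same
calculation shows is dissipated.

## Minimisation over the half-width

`minimise_energy()` scans 1000 uniform half-widths on $(0, 1]$, discards
those with no admissible candidate (negativity, or a singular constraint
system — guarded at $|\det| < 10^{-9}$), and refines around the best grid
point by golden-section search to $|\Delta r| < 10^{-6}$. Ties in the
golden comparison shrink from the left so that a minimum sitting exactly on
an admissibility edge (the flat-landscape case, where the energy is flat to
round-off over $\pm 2\times10^{-6}$ around $r_0$) resolves to the edge. The
search is deterministic and takes well under a second per parameter set,
which is what makes the parameter sweeps (`sweep_parameter()`) cheap
relative to time-stepping the PDE. The returned minimum is global over the
*single-aggregation* family only; multi-bump configurations are reachable
only through the PDE solver and may have lower energy for some initial
conditions.

## The finite-volume solver

All three schemes use conservative upwind fluxes
$F_{i+1/2} = u_{\rm up}\,(\xi_{i+1}-\xi_i)/\Delta x$ on a uniform
cell-centred grid with zero-flux boundaries, where $\xi$ is the drift
potential of the scheme and $u_{\rm up}$ is the neighbour upwind of the
interface velocity; the linear scheme adds centred diffusive fluxes. Mass
therefore telescopes to round-off per step (asserted at $10^{-12}$), and a
cell at zero density cannot be driven negative, which is how the quadratic
schemes preserve positivity. Undershoots below $-10^{-12}$ are clipped with
the clipped mass redistributed proportionally and counted; cumulative
clipping beyond $10^{-8} p$ raises an instability error, as does any
non-finite value. Convergence to steady state uses the per-step sup-norm
rule $\max_x |u(x, t+\Delta t) - u(x, t)| < 10^{-8}$, with a simulated-time
cap after which the state is returned flagged not-converged.

Numerical choices worth knowing:

* Time stepping is fully explicit. The fourth-order scheme is then subject
  to a biharmonic stability bound $\Delta t \lesssim \Delta x^4 /
  (4\gamma\sigma^2 \max u)$ — about $4\times10^{-8}$ at $\Delta x = 0.01$,
  $\gamma = 2$, $\sigma = 0.1$ — which is stricter than the step sizes
  conventionally quoted for semi-implicit finite-volume schemes of this
  type. `check_stability()` estimates the bound and warns; the tests use
  $\Delta t = 3\times10^{-8}$ for fourth-order runs at $\Delta x = 0.01$.
* The convolution uses exact cell-averaged kernel weights (CDF
  differences), so the discrete kernel integrates to 1 up to the truncation
  tail ($30/m$ for the Laplace kernel, $e^{-30}\approx 10^{-13}$; exact for
  the top-hat), and convolution preserves mass of interior-supported
  densities to $10^{-12}$. Densities are zero-extended beyond the domain;
  this is this package's choice, appropriate because quadratic-diffusion
  states have compact interior support and linear-diffusion runs are
  monitored for boundary mass.
* $u''$ in the fourth-order drift potential uses centred differences with
  one-sided closures at the first and last cells.
* The energy series is evaluated every step inside the solver loop and its
  largest per-step increase is reported (`max_energy_increase`), so
  dissipation is auditable without storing every step.

## Initial conditions and what the synthetic runs establish

The generator provides the flat-landscape minimiser (`"flat_min"`, the standard
aggregated start), an offset Gaussian (mean 0.5, sd 0.05), and two- and
three-bump cosine profiles on $|x| < 1/2$ (`"cos4"`, `"cos6"`), all
normalised to mass $p$. Defaults throughout mirror the studied regimes:
$\gamma = 2$, $\sigma = 0.1$, $a_n = 1$, $p = 1$, $\Delta x = 0.01$. These
fixtures emulate the *dimensionless* single-species setting with a static
landscape; they do not emulate resource depletion, multiple species,
two-dimensional domains, or demographic change, so a green test establishes
properties of the movement model only.

Headline behaviours verified by the test suite: the minimum-energy width
$2r^*$ depends non-monotonically on the clump width $2/n$ (narrowest and
tallest aggregation at $n = 6$ among $n \in \{2,4,6,8,12,16\}$ at
defaults); $r^*$ decreases with $a_1$ and with $\gamma$ on a flat
landscape, but *increases* with $\gamma$ when resource attraction is strong
($a_n = 10^3$, all tested $n$); and both $\gamma$ and $p$ show saturation.
Two resource clumps stretch a centred aggregation at weak amplitude and
split it in two at strong amplitude; a narrow clump fails to merge a
three-bump start, illustrating dependence on initial conditions through
distinct local energy minima.

## Other design decisions

* The domain is fixed to $[-1, 1]$: the Fourier setting is 2-periodic after
  rescaling and all studied profiles fit inside. Dimensional inputs are
  converted with `nondimensionalise()`.
* Clump landscapes return exactly 0 outside their support so the advective
  forcing vanishes identically there.
* Fourier projection of landscapes uses periodic trapezoid quadrature with
  at least 8 points per retained mode (spectrally accurate on the smooth
  pieces).
* Configuration files are JSON (`load_config()`), with a strict schema:
  unknown keys are rejected and every applied default is reported.
* Exact resonance is an error, not a special case: secular solutions are
  outside the implemented family.

## Known limitations

* The two-branch candidate is approximate for $r > 1/n$ (see above).
* The singular threshold case $\gamma = 1$ is not implemented.
* Analytic machinery assumes quadratic diffusion; linear diffusion is
  numerical only, and widths of its everywhere-positive states are measured
  at a reference height ($u = 0.1$) rather than by support.
* The explicit fourth-order scheme is slow at fine grids; the package keeps
  it explicit for transparency of the positivity/dissipation mechanism
  rather than reproducing an implicit solver.
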