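---
title: "Methods: season maps, boundaries and maturation timing in pulsecr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: season maps, boundaries and maturation timing in pulsecr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pulsecr)
```

## The model and its assumptions

`pulsecr` implements a semi-discrete consumer–resource biomass model.
Within each growing season — fixed at unit length, which absorbs one time
scale into the parameterisation — four densities evolve continuously: the
resource `R`, juvenile consumer biomass `J`, adult biomass `A`, and the
reproductive energy storage `B` that adults accumulate instead of growing.
At the start of every season the storage is released in a single pulse as
newborn juvenile biomass (`J <- J + B`, `B <- 0`). The composition of one
season's ODE flow with this pulse is the *season map*; its fixed points on
post-pulse states `(R, J, A)` (storage is identically zero after the
pulse, so it is eliminated from the map's coordinates) are the model's
equilibria.

The biological assumptions worth keeping in mind:

* the resource grows semi-chemostat fashion, `R' = ρ(K_r − R)` absent
  consumers, so it cannot be overexploited to extinction;
* consumers feed with a *linear* (type I) functional response; juveniles
  attack at mass-specific rate `I_max`, adults at `θ I_max`, so `θ` tunes
  the energetic asymmetry between the stages;
* when net production `ν = σ·intake − Q` turns negative, somatic growth,
  maturation and storage accumulation cease and the deficit is added to
  mortality (`d = μ + max(0, −ν)`), conserving biomass exactly during
  starvation;
* maturation is a per-capita flux `γ(ν_j, μ)` chosen so the two-stage
  model is a consistent approximation of a fully size-structured one:
  `γ = (ν_j − μ)/(1 − z^(1 − μ/ν_j))` for `ν_j > 0`, zero otherwise,
  where `z` is the newborn:adult size ratio. Higher background mortality
  `μ` discounts survival to maturation and lowers the flux.

## Parameters

| symbol | meaning | unit | default |
|---|---|---|---|
| `rho` | resource turn-over rate | per unit time | 10 |
| `Kr` | maximum resource density | gram/L | 2 |
| `theta` | adult:juvenile intake ratio | – | *set per analysis* |
| `Imax` | juvenile mass-specific attack rate | per unit time | 100 |
| `Q` | mass-specific maintenance rate | per unit time | 10 |
| `sigma` | conversion efficiency | – | 0.5 |
| `mu` | background mortality rate | per unit time | *set per analysis* |
| `z` | newborn:adult size ratio | – | 0.1 |

`theta` and `mu` are the two axes of every analysis here, so
`cr_params()` refuses to default them. The remaining values are the
standard parameterisation for this model family; the juvenile starvation
threshold they imply is `R = Q/(σ I_max) = 0.2`, a tenth of `Kr`.
`Imax = 0` is allowed as a degenerate no-feeding case: the season then has
a closed-form solution (exponential decay of consumers, semi-chemostat
relaxation of the resource) used as an integration oracle in the tests.

## Numerical choices

**Integration.** The within-season field is compiled C (under `src/`),
integrated by `deSolve::lsoda` at `rtol = 1e-10`, `atol = 1e-12`. The
rates reach ~100 per unit time over a unit season, so the system is
moderately stiff; the starvation and maturation switches make the field
continuous but non-smooth, which is why tolerances are tight and why the
switches are handled *inside* the field (no event detection — the field
has no discontinuity to stop at). Season averages `J̄, Ā, B̄` ride along
as extra ODE components with derivatives `J, A, B`, rather than being
recovered from dense output by quadrature.

**The maturation singularity.** `γ` has a removable singularity at
`ν_j = μ`. The exponent is computed as `(ν_j − μ)/ν_j` — exact for nearby
arguments — and the denominator through `expm1`. Inside a guard band
`|ν_j − μ| ≤ 1e-8·μ` the limit `−ν_j/ln z` is used with its first-order
correction, so the two branches agree to near machine precision at the
hand-over; a grid test brackets both this point and `ν_j → 0⁺`.

**Fixed points and stability.** Attractors are found by forward iteration
(convergence: successive post-pulse states within `1e-9` in max-norm over
10 consecutive seasons; extinction: total consumer biomass below `1e-10`;
cap: 5000 seasons), then polished by a damped Newton iteration on
`Φ(x) − x` with a central finite-difference Jacobian (step
`1e-6·(1 + |x|)`) to residual `1e-10`. Multiplier moduli within `1e-6` of
1 are reported as `"marginal"` rather than silently classified. An
independent variational-equation Jacobian (analytic field Jacobian
transported across the season) is kept as a cross-check; the two routes
agree to `1e-5` relative in the tests.

**Boundaries.** The persistence boundary is found by bisection in `μ` to
width `1e-3` — matching the precision at which such boundary values are
meaningfully reported — with each trial warm-started from the last
persisting state so that the attractor branch is tracked up to its fold.
The invasion boundary is the root of the dominant multiplier of the
linearized season map at the resource-only equilibrium; because `R ≡ K_r`
there, the linearization has constant coefficients and the one-season
transition matrix is a matrix exponential (`Matrix::expm`), cross-checked
against direct integration of the linear system. Bistability is flagged
when the two boundaries differ by more than `5e-3` (five bisection
widths): a smaller gap is indistinguishable from bisection noise, and the
threshold also avoids mistaking the tiny alternative-stable-states sliver
at intermediate `θ` (see *Limitations*) for the headline Allee region.
The `μ` scan ceiling defaults to 20, scaled proportionally for `θ > 2`,
since both boundaries rise with `θ`.

**Persistence vs fixed points.** At low mortality and small `θ` (e.g.
`θ = 0.25`, `μ = 0.1`) the coexistence fixed point is unstable (dominant
multiplier ≈ 1.8) and the attractor is a cycle. Persistence for the
boundary bisection is therefore judged *dynamically*: extinction is
extinction, and a run that hits the season cap while retaining substantial
consumer biomass counts as persistence. `sweep_mu()` meanwhile continues
the fixed-point branch by Newton in that regime and reports its true
stability, which is what a bifurcation diagram of equilibria should show;
`find_attractor()` raises a classed condition (`pulsecr_no_convergence`)
rather than guessing when forward iteration finds neither a fixed point
nor extinction.

**Expected reproductive output.** For a newborn maturing at time `t_m`,

```
R0(tm) = γ(ν_j(R(tm)), μ) · exp(−μ + S(tm)) · (W(1) − W(tm)),
S(t) = ∫₀ᵗ [ν_j(R) − γ(ν_j(R), μ)] dτ,   W(t) = ∫₀ᵗ ν_a(R) dτ.
```

The grouping of the survival and growth terms is a design decision (the
factor `e^{−μ}` is whole-season background survival; `S` is cohort
per-capita growth net of maturation losses, *excluding* background
mortality; the post-maturation integral is undiscounted). It is the unique
reading consistent with the model's biomass bookkeeping: adult survival
`e^{−μ(t−t_m)}` combined with storage mortality `e^{−μ(1−t)}` collapses to
`e^{−μ(1−t_m)}`, and under it `∫₀¹ R0(t_m) dt_m` equals — exactly, in the
no-starvation regime — the end-of-season storage `b(1)` of a unit juvenile
cohort integrated against the same environment. The tests assert this
identity numerically in both environment modes, which is the strongest
validation available given that the formula's derivation is not
reproduced here. `S` and `W` are carried as additional ODE components
(one integration yields the whole curve on its `t_m` grid); the
cumulative curve uses trapezoidal quadrature on that grid. The two
environment modes are: *coupled* — the resource trajectory of the
converged fixed-point season, so `R(0) = R(1)`; *decoupled* — `R ≡ K_r`,
where `ν` and `γ` are constants and the closed form
`γ* e^{−μ} e^{(ν_j*−γ*) t_m} ν_a* (1 − t_m)` provides an independent
oracle (agreement to `1e-8` relative is enforced in the tests).

**Landmarks and grids.** `R0(t_m)` is evaluated on a 401-point uniform
`t_m` grid and cohort trajectories on 2001 points per season — fine enough
that local quadratic refinement of extrema and of crossings of `R0 = 1`
is accurate to well below the two decimals at which these landmarks are
reported. Within-season dense output defaults to 201 points. Boundary
bisections use the tolerances above; the bistability-onset bisection in
`θ` stops at `5e-3`.

**Degenerate inputs.** Negative state components and non-finite states
are rejected at the interface; `Imax = 0` is allowed (see above);
consumer-free states terminate iteration immediately as `"extinct"`
(pass `ext_tol = 0` in `cr_control()` to study pure resource relaxation);
the extinct fixed point `(K_r, 0, 0, 0)` is returned exactly, not
numerically.

## What the simulations do and do not show

All experiments are self-contained simulations of the model at its
standard parameterisation — there is no external data. Agreement of the
boundary locations, overcompensation directions and `R0` landmarks with
their reference values therefore validates the *implementation and the
model's internal logic*, not the model's fit to any real population. The
model abstracts away size distribution within stages (only `z` survives
of it), assumes a type I functional response, a single reproductive pulse
per season, equal maintenance and background mortality across stages, and
no consumer–consumer interactions beyond exploitative competition.

## Limitations

* Non-equilibrium attractors are detected and respected, but not
  continued: no Floquet analysis of cycles, no period-doubling tracking.
* The fold is located by bisection on attractor existence, not by a
  test-function-based limit-point continuation; accuracy is the bisection
  width, which is ample at the reported precision.
* For intermediate `θ` (roughly 0.33–0.75) there is a very small region
  where two *consumer–resource* equilibria coexist as alternative stable
  states. The bistability flag deliberately ignores gaps below `5e-3` and
  so does not chart this sliver; disagreement between initial conditions
  is still visible to a user who probes it with `find_attractor()`.
* `R0(t_m)` counts only the first reproduction event after birth, and its
  closed-form bookkeeping assumes the resource stays above the starvation
  thresholds — true at the parameters studied (asserted in the tests),
  but not enforced in general.
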