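# pulsecr

Stage-structured consumer–resource dynamics with pulsed seasonal
reproduction.

## The problem

Populations that reproduce once a year — a single pulse of offspring at the
start of each growing season — can collapse abruptly when background
mortality rises, even though individuals compete for food purely
exploitatively. `pulsecr` implements a semi-discrete biomass model for one
such consumer and its resource, and the numerical analyses that expose the
mechanism: a mortality-driven Allee effect rooted in the *timing of
juvenile maturation* within the season. It is aimed at theoretical
ecologists studying stage structure, biomass overcompensation and
bistability, and at anyone who needs a clean reference implementation of a
season map (ODE flow composed with a discrete pulse) and its bifurcation
analysis.

## The model

Within a season of unit length, resource density `R`, juvenile biomass `J`,
adult biomass `A` and reproductive energy storage `B` follow

    R' = ρ(K_r − R) − I_max R (J + θA)
    J' = ν_j⁺(R) J − γ(ν_j(R), μ) J − d_j(R) J
    A' = γ(ν_j(R), μ) J − d_a(R) A
    B' = ν_a⁺(R) A − d_a(R) B

with net biomass production `ν_j(R) = σ I_max R − Q` (juveniles) and
`ν_a(R) = σ θ I_max R − Q` (adults), starvation handled by clipping growth
at zero and adding the deficit to mortality (`d = μ + max(0, −ν)`), and a
resource-dependent maturation rate

    γ(ν_j, μ) = (ν_j − μ) / (1 − z^(1 − μ/ν_j)),   ν_j > 0,

which equals `−ν_j/ln z` at its removable singularity `ν_j = μ`. At each
season boundary adults release all storage as offspring:
`J ← J + B`, `B ← 0` (the reproduction pulse). Fixed points of the
resulting season map, their stability multipliers, persistence and invasion
boundaries in `μ`, and the expected end-of-season reproductive output
`R₀(t_m)` of a newborn maturing at time `t_m` are all computed by the
package. Default parameters: `ρ = 10`, `K_r = 2`, `I_max = 100`, `Q = 10`,
`σ = 0.5`, `z = 0.1`, with `θ` and `μ` chosen per analysis.

## A worked example

```r
library(pulsecr)

p <- cr_params(theta = 2, mu = 9)
find_attractor(p, season_state(1, 0.2, 0.2))    # high initial biomass
#> <cr_equilibrium> stable
#>   post-pulse state: R = 1.13326, J = 0.402843, A = 0.0294822, B = 0
#>   season averages:  Jbar = 0.091883, Abar = 0.0845351, Bbar = 0.386521
#>   multiplier moduli: 0.340104, 8.1983e-05, 2.95586e-08

find_attractor(p, season_state(1, 0.01, 0.01))$stability  # low biomass
#> [1] "extinct"
```

From high initial biomass the consumer settles on a stable coexistence
state (post-pulse juvenile biomass 0.40; most season-average consumer
biomass sits in the inert storage `B̄ = 0.39`, the signature of a
population close to its persistence boundary). From low initial biomass
the same parameters lead to extinction: an Allee effect. The boundary
machinery quantifies it:

```r
persistence_boundary(p)        # ≈ 9.877: highest mu with a coexistence attractor
invasion_boundary(p)           # ≈ 8.250: above this a rare consumer cannot invade
```

Between the two lies the bistable band. Life-history analysis at
`theta = 1, mu = 8` shows why: with consumer feedback on the resource
(`"coupled"`), maturation is delayed and the expected reproductive output
`R₀(t_m)` peaks late (`t_m ≈ 0.80`, exceeding 1 up to `t_m ≈ 0.96`),
whereas at maximum resource density (`"decoupled"`) individuals mature
early and `R₀` falls below 1 already at `t_m ≈ 0.23`:

```r
r0_features(r0_curve(cr_params(theta = 1, mu = 8), "coupled"))
#> # A tibble: 1 × 7
#>   mode     tm_min tm_max r0_max cross_up cross_down cumulative_total
#>   <chr>     <dbl>  <dbl>  <dbl>    <dbl>      <dbl>            <dbl>
#> 1 coupled  0.0651  0.799   2.30    0.511      0.955            0.990
```

Every result type has `autoplot()`, and equilibria have `tidy()`/`glance()`
methods. A thin command-line front end (`inst/cli/pulsecr.R`) exposes the
verbs `simulate`, `sweep`, `boundary`, `r0` and `cohort` with CSV/JSON
output.

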