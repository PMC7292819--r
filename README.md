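# binswitch

Population models routinely bolt an Allee effect onto logistic growth to
explain why sparse populations underperform or collapse, but the
*individual-level* mechanism behind a given Allee effect is usually left
unspecified. `binswitch` implements the **Binary Switch Model**: a
population of individuals on a hexagonal lattice whose proliferation and
death rates change abruptly when the number of occupied
nearest-neighbour sites `n` crosses a threshold `M`,

```
p_n = r,  d_n = r·α   for n ≤ M        (low local density)
p_n = R,  d_n = R·β   for n > M        (high local density)
```

with `α, β ∈ [0, 1]` and `M ∈ {0,…,5}`. In the well-mixed limit the
scaled density `C(t) ∈ [0, 1]` obeys the degree-six polynomial law

    (1/C) dC/dt = (1 − C) Σₙ γₙ C(5,n) Cⁿ (1 − C)⁵⁻ⁿ − γ₆ C⁶,
    γₙ = pₙ − 6 dₙ/(6 − n),  γ₆ = d₆,

which collapses exactly to logistic growth (carrying capacity `1 − α`)
when the switch is absent (`r = R`, `α = β`), and otherwise produces a
remarkably diverse family of Allee effects from just five parameters:
Weak, Strong, Reverse and Hyper-Allee regimes, an Extinction regime, and
their bifurcation boundaries (the Tangential Manifold with its
semi-stable double-root equilibria, the Triple Point, and the Junction
Point separating Extinction from Strong Allee behaviour).

The package is aimed at theoretical ecologists and cell-population
modellers who want to (i) analyse which growth regime a parameter set
produces, (ii) verify the continuum law against the underlying
stochastic lattice process, and (iii) calibrate the model to growth
curves and ask which threshold density the data support.

## What's inside

* **Growth law & trajectories** — `per_capita_rate()`, `growth_rate()`,
  `polynomial_coefficients()`, `solve_trajectory()` (adaptive RK45 on the
  exact polynomial; lsoda as an independent route), plus the classical
  logistic/Weak/Strong Allee reference models (`classic_rate()`).
* **Equilibria & regimes** — `find_equilibria()` (companion-matrix roots,
  multiplicity-aware clustering, one-sided boundary stability),
  `classify_regime()` (the full ten-label taxonomy), `regime_map()`.
* **Bifurcation structure in closed form** — `case1_beta()`/`case2_alpha()`
  and inverses, `tangential_R()`/`tangential_alpha()`,
  `tangential_point()` (independent linear-system route),
  `triple_point()`, `junction_point()`.
* **Stochastic lattice simulator** — `simulate_abm()`,
  `ensemble_density()`: exact Gillespie dynamics of the
  birth–death–movement exclusion process on a periodic hexagonal lattice
  (C++ core), whose ensemble mean reproduces the continuum law.
* **Calibration** — `sum_sq_error()`, `fit_for_M()`, `model_select()`
  (Nelder–Mead on transformed parameters, multi-start, exhaustive search
  over `M`), `generate_synthetic_growth()` (synthetic U87
  glioblastoma-style growth curves), `u87_reference_fits()`.
* **CLI** — `exec/binswitch` with subcommands
  `simulate | equilibria | regime | regime-map | manifold | abm | synth | fit`.

## Worked example

```r
library(binswitch)

p <- bsm_params(r = 1, R = 0.5, alpha = 0.2, beta = 0.1, M = 2)
find_equilibria(p)
#> Equilibria of the Binary Switch Model (r=1, R=0.5, alpha=0.2, beta=0.1, M=2)
#>      value multiplicity stability
#>  0.0000000            1  unstable
#>  0.9004665            1    stable
classify_regime(p)
#> [1] "WeakAllee"
```

The switch at `M = 2` deforms logistic growth without adding equilibria:
a Weak Allee effect with carrying state 0.900. Where does bistability
appear? At `α = 1` the Junction Point marks the critical high-density
rate `R` beyond which Extinction gives way to a Strong Allee effect:

```r
jp <- junction_point(4, 0.06)
#> Junction Point (M=4, beta=0.06): C=0.8520, R=7.0129
classify_regime(bsm_params(1, 1.3 * jp$R_junction, 1, 0.06, 4))
#> [1] "StrongAllee"
```

Calibration with model selection over the threshold, on synthetic data
generated at the reference U87 glioblastoma estimates (`M = 1` truth,
initial densities 0.02/0.06/0.2, 3-hourly sampling over 120 h, noise
sd 0.005):

```r
truth  <- bsm_theta(1, 0.0168, 0.0345, 0.0608, 0.0692, c(0.02, 0.06, 0.2))
curves <- generate_synthetic_growth(truth, sigma = 0.005, seed = 1)
model_select(curves, options = list(seed = 1))
#> Model selection over the threshold density M
#>  M       r         R     alpha     beta      sse converged
#>  0 0.01015 2.621e-02 4.807e-02 0.002632 0.003823     FALSE
#>  1 0.02260 3.499e-02 2.970e-01 0.071783 0.002311      TRUE
#>  2 0.01815 5.615e-02 2.254e-02 0.131397 0.003120     FALSE
#>  3 0.01977 1.291e-01 2.450e-02 0.151365 0.005804     FALSE
#>  4 0.02263 1.911e-01 3.760e-02 0.076043 0.014771     FALSE
#>  5 0.02360 2.572e-21 8.669e-10 1.000000 0.025412      TRUE
#> Selected M = 1 (SSE = 0.00231085)
```

The generating threshold is recovered, and the selected SSE sits at the
noise floor (123 points × 0.005² ≈ 0.0031). The high-density parameters
`R`, `β` come back tightly; `α` is weakly identified because low-density
data mostly constrain the product `r(1 − α)` — see the methods vignette
(`vignettes/binary-switch-model.Rmd`) for the full identifiability
discussion.

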