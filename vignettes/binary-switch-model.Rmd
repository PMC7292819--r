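---
title: "The Binary Switch Model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Binary Switch Model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binswitch)
```

## The model

The Binary Switch Model describes a crowded population living on a
hexagonal lattice in which each individual senses its local density as
the number `n` of occupied nearest-neighbour sites (0--6). Individuals
proliferate at rate `r` and die at rate `r * alpha` while `n <= M`, and
at rates `R` and `R * beta` once `n > M`; `M` in `{0,...,5}` is the
threshold density. In the well-mixed (mean-field) limit, the neighbour
count of a site at global density `C` is Binomial(6, `C`), a
proliferation attempt succeeds with probability `(6 - n)/6` (the chance
that the uniformly chosen target site is empty), and averaging the event
rates yields the continuum per-capita growth law

$$\frac{1}{C}\frac{dC}{dt} \;=\; (1-C)\sum_{n=0}^{5}\gamma_n\binom{5}{n}
C^{n}(1-C)^{5-n}\;-\;\gamma_6 C^{6},
\qquad
\gamma_n = p_n - \frac{6\,d_n}{6-n},\;\; \gamma_6 = d_6,$$

where `C` is the density as a fraction of the maximum packing density
(`C = 1` means every site is occupied) and time carries the units of the
rate constants (hours for the cell-biology data the calibration module
targets). With the binary switch substituted for `p_n`, `d_n`, the
right-hand side is a degree-six polynomial in `C` controlled by just
five parameters. Setting `r = R` and `alpha = beta` removes the switch
and collapses the law *exactly* to logistic growth with carrying
capacity `1 - alpha` — a property the test suite asserts to machine
precision, and a useful sanity anchor throughout.

`per_capita_rate()` evaluates the substituted (threshold) form directly;
`per_capita_rate_general()` evaluates the general-rate form above. The
two are independent code paths and the suite checks they agree to
`1e-12` across the parameter space, guarding against transcription slips
in either.

## Equilibria, stability, and the regime taxonomy

All equilibria are roots of the growth polynomial
(`polynomial_coefficients()` expands it exactly; the constant term is
identically zero, so extinction is always an equilibrium).
`find_equilibria()` obtains the interior roots from the companion matrix
(via `pracma::roots`) and polishes them by Newton iteration. Three
numerical choices matter:

* **Boundary one-sidedness.** Densities live in `[0, 1]`, so the
  equilibria at 0 and 1 are classified from the physical side only: the
  even-multiplicity "semi-stable" rule applies to interior roots alone.
  With `R = 0` the root at `C = 1` has multiplicity `6 - M`, yet the
  population simply converges to (or leaves) full packing from below.
* **Exact structural factors.** `C = 1` is an equilibrium precisely when
  the crowding death term `R * beta` vanishes. That is a parameter
  condition, not a numerical one, so the factor `(C-1)^m` is counted by
  successive differentiation and removed by synthetic division before
  any numerical root finding. Without this, the companion eigenvalues of
  a multiplicity-5 root scatter over ~`1e-3` and masquerade as spurious
  interior equilibria.
* **Tangency detection.** A double (or triple) root perturbs its
  companion eigenvalues by ~`eps^(1/m)`, often off the real axis. A
  near-real conjugate pair is accepted as a multiple root only if the
  polynomial *and* its derivative genuinely vanish at its real part
  (thresholds `1e-9` and `1e-7`, scaled); true complex pairs fail this
  and are discarded. Exact tangencies occupy measure-zero manifolds in
  parameter space — these tolerances are what make the manifold labels
  reachable in floating point, and their values are this package's
  choice (no reference tolerances exist for them).

`classify_regime()` maps the resulting (count, stability, multiplicity)
signature onto the model's taxonomy: Extinction, Logistic, Weak Allee,
Strong Allee, Reverse Allee (interior stable state with both 0 and 1
unstable, possible only when the high-density rates vanish), Hyper-Allee
(two distinct positive stable densities), and the boundary cases —
Positive/Negative Tangential Manifold, Triple Point, Junction Point.
`Logistic` is reported only on the exact no-switch condition
`r == R && alpha == beta`, never inferred from root structure, since any
Weak Allee law shares the logistic signature. A high-multiplicity root
*at the boundary* `C = 1` is reported as Weak Allee, not as a Triple
Point: the Triple Point is an interior tangency.

One fine point the implementation surfaced: for `M = 0` with
`alpha = 1`, the below-threshold block of the law vanishes identically
(only `n = 0` is below threshold, and its net coefficient is
`r(1 - alpha) = 0`), so the dynamics reduce exactly to the `r = 0` case.
The regime at `alpha = 1` is therefore governed by `beta` alone — Weak
Allee for `beta < 5/6`, Extinction for `beta >= 5/6` — rather than being
Extinction throughout, and the tests assert this reduced expectation.

## Closed-form bifurcation structure

For the three canonical slices of parameter space the package carries
closed forms, each verified against an independent route:

* **Case 1 (`r = 0`)**: `case1_beta()` (`f_M`) gives the death ratio
  producing a prescribed interior equilibrium; its inverse
  `case1_equilibrium()` exists for `beta < (5-M)/6`. Verified by
  substituting back into the reduced growth law (residual `< 1e-10` on
  500-point grids).
* **Case 2 (`R = 0`)**: `case2_alpha()` (`g_M`) and its inverse, the
  Reverse Allee slice. Same verification strategy.
* **Case 3 (`r`, `R > 0`)**: the Tangential Manifold
  `R = F_M(Ĉ, beta)`, `alpha = G_M(Ĉ, beta)` (`tangential_R()`,
  `tangential_alpha()`), the Triple Point relation `beta = H_M(C)` and
  the Junction Point relation `beta = J_M(C)`. Because long rational
  functions are exactly where transcription errors hide, the package
  *also* solves the defining 2x2 linear system numerically
  (`tangential_point()`; the per-capita law is linear in `R` and `alpha`
  separately) and the tests require both routes to agree to `1e-9`.
  `r` is normalised to 1 in this analysis; other values only rescale
  time and move no equilibria.

Inversions (`f_M^{-1}`, `H_M^{-1}`, `J_M^{-1}`) use bracketed bisection
(`uniroot` at tolerance `1e-13`) on the monotone domains the analysis
establishes. `regime_map()` classifies an `(alpha, R)` grid cell-by-cell
(default 201 x 201); worth knowing: for `M = 4` at small `beta` the
Hyper-Allee wedge sits at large `R` (order 10--20), outside the default
`R <= 3` window — pass a wider `R_grid` to see it.

## The lattice simulator

`simulate_abm()` is an exact (Gillespie) stochastic simulation of the
exclusion process on a periodic axial hexagonal lattice (neighbour
offsets `(1,0), (-1,0), (0,1), (0,-1), (1,-1), (-1,1)`, so every site
has degree 6 with no edge effects). Sites are bucketed by neighbour
count, giving O(1) event selection and incremental neighbour-count
updates; neighbour counts are re-evaluated at event execution time.
Proliferation and movement pick one of the six neighbour sites uniformly
and abort if it is occupied — this exclusion is what saturates the
density at 1. A site with all six neighbours occupied can never place a
daughter, so its (always-futile) proliferation attempts are dropped from
the event menu; this changes nothing dynamically and matches the
`(6-n)/6` mean-field success factor vanishing at `n = 6`.

The continuum law is the *well-mixed* limit, so agreement between the
ensemble mean and the ODE depends on motility. Measured on a 100 x 100
lattice in an `M = 2` switch regime, a motility of 10x the fastest
demographic rate still leaves ~0.06 of correlation-induced deviation;
at 100x it falls below ~0.01. The default motility is therefore 100x
`max(p, d)`, a deliberate choice of the well-mixed study condition
(configurable via `abm_config(motility = ...)`). The agreement tests use
20 replicates on a 100 x 100 lattice with a 0.02 density tolerance.
What passing shows: the simulator's aggregate event rates are the ones
the continuum law integrates. What it does not show: behaviour under
slow mixing or structured initial conditions (invasion fronts), which
the package deliberately does not model.

## Calibration and model selection

`sum_sq_error()` implements the combined least-squares objective: one
shared parameter set `(r, R, alpha, beta, M)` plus one *fitted* initial
density per curve, scored against all curves simultaneously — a single
mechanism must explain every initial condition. `fit_for_M()` minimises
it with Nelder--Mead simplex search on transformed parameters (log for
the rates, logit for the ratios and initial densities), so the search is
unconstrained while the model ranges are enforced; raw simplex steps
would otherwise exit `[0, 1]`. Because simplex search is local, each fit
restarts from jittered copies of the starting point (default 5,
deterministic under the option seed). `model_select()` profiles out the
discrete threshold by exhaustive search over `M = 0..5` and keeps the
minimum. Integration inside the objective uses an adaptive
Dormand--Prince 5(4) kernel on the exact polynomial right-hand side
(`rtol 1e-8`, `atol 1e-10`); `deSolve`'s lsoda is retained as an
independent integrator route and the two are cross-checked in the tests.

`generate_synthetic_growth()` emulates the experimental design of the
U87 glioblastoma monolayer experiments (Neufeld et al. 2017) that the
calibration machinery targets: three initial densities (0.02, 0.06,
0.2), observations every 3 h over 120 h, and additive homoscedastic
Gaussian noise (sd 0.005 by default) clipped to `[0, 1]`. Gaussian
homoscedastic noise is the implicit assumption of an unweighted
least-squares objective, and is stated here as exactly that — an
assumption. What the generator does *not* emulate: measurement-density-
dependent noise, temporal autocorrelation of imaging artefacts, or
plate-to-plate effects in the real assay; recovery results therefore
speak to identifiability under the stated noise model, not to the
quality of any particular laboratory pipeline.

`u87_reference_fits()` ships the per-threshold reference parameter
estimates for those curves (JSON fixture). The package's standard
recovery experiment uses the `M = 1` row as ground truth: across 10
seeds at the default design, model selection returns `M = 1` in every
seed, and the per-parameter recovery errors (bounds frozen from a
repeated-seed pilot run at the same conditions) show `R` and `beta`
tightly identified, `r` moderately, and `alpha` only weakly — at low
density the data constrain the product `r(1 - alpha)`, a classical
sloppiness that survives in the fitted values. Exact reproduction of the
reference estimates themselves is not promised: they derive from figure
data external to this package, and the original optimiser's starting
points are unknown.

## Problem sizes and degenerate inputs

The default test suite runs in about two minutes on one core: 2000
random parameter sets for the root-finder/scan cross-check, 500-point
grids for every closed form, 20 x (100 x 100) lattice realisations per
ABM regime, and 10 model-selection runs (each 6 thresholds x 5 restarts)
for the recovery experiment. The all-zero model (`r = R = 0`) has
identically zero growth and is rejected with an explicit error rather
than classified; an unrecognised equilibrium signature raises an error
carrying the signature (a bug sentinel — no such input is known).

## Known limitations

* One switch only: populations whose rates change at more than one
  density threshold are out of scope, as are alternative local-density
  measures (next-nearest neighbours, weighted kernels).
* No spatial PDE limit, invasion fronts, or basin-of-attraction
  machinery beyond 1-D interval logic.
* No uncertainty quantification for fits (no profile likelihood or
  bootstrap); the recovery experiment characterises identifiability at
  one noise level, not posterior uncertainty.
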