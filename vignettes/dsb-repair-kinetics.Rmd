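---
title: "Modelling DSB repair and gamma-H2AX focus kinetics with dsbkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DSB repair and gamma-H2AX focus kinetics with dsbkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbkin)
```

## The model

`dsbkin` models the molecular response at a single site of DNA
double-strand-break (DSB) damage. Three coupled quantities describe a site:

* `X(t)` — a telegraph damage indicator: 1 while a DSB is present, 0 after
  repair. The switch off is irreversible in the baseline model.
* `Y(t)` — the number of bound, activated diffusible repair molecules at
  the site. We call this pool "pATM" for brevity, but it stands for any
  diffusible species (ATM, ATR, DNA-PKcs, ...) that accumulates at damage
  and is necessary for repair.
* `Z(t)` — the number of phosphorylated H2AX histones (gamma-H2AX) at the
  site. gamma-H2AX is the measurable quantity: clusters of it are the foci
  counted under the microscope.

Six first-order rate constants (all h^-1) define a continuous-time Markov
jump process:

| event | hazard | effect |
|---|---|---|
| repair | `k1 Y X` | `X -> 0` |
| recruitment (damage-driven) | `k2 X` | `Y -> Y + 1` |
| recruitment (gamma-H2AX-driven) | `k3 Z` | `Y -> Y + 1` |
| dissociation | `k4 Y` | `Y -> Y - 1` |
| phosphorylation | `k5 Y` | `Z -> Z + 1` |
| dephosphorylation | `k6 Z` | `Z -> Z - 1` |

The `k3`/`k5` pair is a positive feedback loop: gamma-H2AX recruits pATM,
pATM makes more gamma-H2AX. Unphosphorylated H2AX is assumed abundant, so
no substrate pool is depleted and counts are unbounded non-negative
integers. After repair (`X = 0`) the `(Y, Z)` subsystem is linear; its zero
state is stable exactly when dissociation and dephosphorylation dominate
the feedback, `k3 k5 < k4 k6` (`stability_check()`). Both shipped
parameter sets — `mcf7_rates()` and `mda_mb_468_rates()`, fitted to two
breast-cancer cell lines — satisfy this.

`simulate_site()` draws exact trajectories of this process with the direct
Gillespie method (compiled; no tau-leaping, because the simulator doubles
as the oracle for everything else). `ssa_ensemble()` averages replicates
and records Monte-Carlo standard errors and detectable-focus fractions.
Replicate `r` of an ensemble is seeded with
`(seed + 140737 r) mod (2^31 - 1)`, so ensembles are reproducible and
order-independent.

## Mean-field reductions

Experiments average over thousands of DSBs (about 40 per cell per Gy, so
roughly 160 after the 4 Gy dose modelled here), which motivates ordinary
differential equations for the means. The hierarchy does not close because
of the `<XY>` term in the repair rate; two closures are provided.

**Independence closure** (`closure = "naive"`): assume `<XY> = <X><Y>`,

$$\dot m_X = -k_1 m_X m_Y,\qquad
  \dot m_Y = k_2 m_X + k_3 m_Z - k_4 m_Y,\qquad
  \dot m_Z = k_5 m_Y - k_6 m_Z.$$

**Conditional-mean closure** (`closure = "conditional"`, the default):
track `p = P(X=1)` and the conditional means `u = E[Y|X=1]`,
`v = E[Z|X=1]`, `w = E[Y|X=0]`, `s = E[Z|X=0]`, and drop conditional
(co)variances. The damaged-branch means obey the mean equations at `X = 1`;
repair transfers sites carrying their current means `(u, v)` into the
repaired pool:

$$\dot p = -k_1 p u,\qquad \dot u = k_2 + k_3 v - k_4 u,\qquad
  \dot v = k_5 u - k_6 v,$$
$$\dot w = k_3 s - k_4 w + \phi\,(u - w),\qquad
  \dot s = k_5 w - k_6 s + \phi\,(v - s),\qquad
  \phi = \frac{k_1 u p}{1-p}.$$

Unconditional means follow from the mixture identities
`mY = p u + (1-p) w`, `mZ = p v + (1-p) s`.

Numerically the repaired-pool equations are integrated in the unnormalized
moments `W = (1-p) w`, `S = (1-p) s`, which removes the `1/(1-p)` factor:
the right-hand side is then smooth even while the pool is empty, and the
stiff-capable `lsoda` integrator (deSolve, compiled derivatives) handles
the system at tolerances down to `atol = 1e-12` without step-size collapse.
While the pool is empty its conditional means are reported as the donor
means (they multiply a zero weight, so the mixture identities stay exact).

Two properties of the closures are worth knowing:

* The conditional closure is the accurate one. The independence closure
  ignores the damage-repair correlation and its damage signal decays
  algebraically (`mX' ~ -c mX^2`, a `1/t` tail) rather than exponentially;
  only its post-repair subsystem reaches zero exponentially.
* Even the conditional closure repairs slightly *faster* than the exact
  process: repair preferentially removes sites with high `Y`, a selection
  effect carried by the conditional variance the closure drops. For the
  slow-repairing MDA-MB-468 rates this leaves a small systematic
  overestimate of repair (a few percent of the damage probability),
  near the Monte-Carlo resolution of 1000-replicate ensembles.

## Observation model and fitting

Two channels are measured per time point: `chi1`, mean DSBs per cell
(comet-assay proxy, emitted here directly in DSB units), and `chi2`, mean
gamma-H2AX foci per cell. The observation maps are

* `chi1_hat(t) = n_dsb0 * mX(t)` with `n_dsb0 = dose x 40` (160 at 4 Gy);
* `chi2_hat(t) = n_dsb0 * mZ(t) / Zmax` (`foci_from_model()`), one focus
  being worth `Zmax = 1000` gamma-H2AX molecules;
* a third, synthetic channel encodes that repair without H2AX is roughly
  ten times slower: `chi1_bar(t) = chi1(t/10)` (`no_h2ax_reference()`,
  time dilation with the ends held), fitted against the model solved with
  `k5 = 0`. The synthetic generator emits this channel directly from the
  `k5 = 0` model so that noiseless round trips are exact.

`dsb_objective()` sums squared residuals of the three channels, each
divided by the square of its first positive observation so channels of
different magnitude contribute comparably (the normalizer falls back to
the series maximum when the series starts at zero, as the focus count
does). Excursions of peak `mY` beyond `Ymax = 300` are discouraged by a
smooth quadratic penalty — `Ymax` and `Zmax` are observation-layer
constants, never hard caps on the stochastic dynamics. Unstable parameter
sets (`k3 k5 >= k4 k6`) and integrator failures return a large finite
barrier so direct-search optimizers can proceed.

**Identifiability.** The latent pATM count has no observable scale:
rescaling `Y` by `alpha` maps
`(k1, k2, k3, k5) -> (k1/alpha, alpha k2, alpha k3, k5/alpha)` and leaves
every observable trajectory exactly invariant. The data therefore
determine five parameter combinations (`k4`, `k6`, `k1 k2`, `k3/k2`,
`k5 k2`), not six rates. `dsb_fit()` handles this explicitly:

1. the search runs over the five identifiable degrees of freedom, with
   `k2` frozen at its starting value (a pure gauge choice);
2. the global stage is a Nelder-Mead simplex multi-start in log space
   (restarts drawn log-uniformly within `span = 2` decades of the start,
   50 by default), confined to a box of `span + 1` decades;
3. the best minimum is polished by Levenberg-Marquardt on the residual
   vector with staged finite-difference steps (1e-8 down to 1e-12) —
   necessary because the objective is extremely ill-conditioned ("sloppy")
   and the simplex cannot resolve its shallow directions;
4. the reported rates are the member of the fitted gauge orbit closest, in
   log space, to the starting guess.

On noiseless synthetic data this recovers the generating rates to
optimizer precision. With 10% multiplicative noise the sloppy directions
genuinely move: the global noisy optimum can sit an order of magnitude
from the truth in (for example) the joint `(k5, k6)` direction *and fit
better than the truth does* — that is a property of the model-design
combination, not of the optimizer, and users should read fitted individual
rates with the gauge and sloppiness caveats in mind. The identifiable
combinations are much better behaved.

The antibody extension adds reversible sequestration of free gamma-H2AX by
an anti-gamma-H2AX-TAT antibody into an inert bound pool `Q`
(`bind: k8 [TAT]0 Z`, `unbind: k7 Q`). Focus data identify only the
quasi-equilibrium grouping `g = k8 [TAT]0 / k7`;
`fit_antibody_grouping()` fixes `k7 = 1` h^-1 by convention and fits `g`
one-dimensionally per concentration, then summarizes the predicted linear
growth of `g` with `[TAT]0`. Whether bound gamma-H2AX is visible to the
detection stain is controlled by `count_bound` (default `TRUE`: the stain
recognizes the phosphoepitope whether or not the therapeutic antibody is
attached; both modes are exposed).

The Auger extension models de novo DSBs from In-111 decays on the bound
antibody: undamaged sites are re-damaged at mean rate `k9 mQ`, with
`k9 = kappa R` proportional to the specific activity `R`. The mean-field
term is `+ k9 mQ (1 - mX)` in `mX'`, built on the independence closure
(re-damage breaks the monotone structure the conditional closure's pool
bookkeeping relies on); a many-site stochastic simulation
(`simulate_population()`, total re-damage hazard `k9 sum(Q)` shared
uniformly among undamaged sites) guards its accuracy. De novo sites retain
their accumulated `(Y, Z)` history, consistent with the per-site
mean-field formulation. No numerical value of `kappa` is available; tests
and examples use an illustrative 1e-4 h^-1 per MBq/ug, and the persistence
area under the damage curve (`persistence_auc()`, trapezoidal over
`[0, 24]` h by default) is increasing in `R` for any positive `kappa`.

## The synthetic-data generator

`generate_observations()` stands in for the wet-lab time courses: 4 Gy
acute dose (160 initial DSBs/cell), sampling at
`{0, 0.5, 1, 2, 4, 6, 24}` h, and multiplicative Gaussian noise with a
coefficient of variation of 0.1 per channel (clamped at zero), with
optional per-cell Poisson count noise. Those defaults are the modelled
study conditions; `cv = 0` gives exact model curves. The generator does
not emulate comet-assay calibration (chi1 is emitted in DSB units, not
Olive-tail-moment units), microscope segmentation artifacts, cell-cycle
heterogeneity, or inter-experiment batch effects — passing recovery tests
on this generator demonstrates the estimation machinery, not robustness
to those real-data complications.

## Numerical choices

* Direct-method SSA with exhaustive propensity recomputation; event
  budget 5e8 per trajectory guards explosive parameter sets.
* `lsoda` with `atol = 1e-10`, `rtol = 1e-8` by default; the objective's
  polish stage tightens to `1e-12`/`1e-11`.
* Half-repair times are located by linear interpolation of `mX` across
  half its initial value on the solution grid.
* Trajectory recording is right-continuous step sampling (state after the
  last event at or before each grid time).
* Trapezoidal quadrature for the persistence AUC, with the upper limit
  interpolated when it falls inside a grid interval.

## Known limitations

* Spatial structure (focus position, correlated Auger damage along decay
  tracks) is out of scope; re-damage is mean-field.
* Persistent, unrepairable DSBs are not modelled; `X` switches off with
  probability one eventually.
* The printed MCF7 rate set bounds the achievable no-H2AX slowdown at
  `k4 k6 / (k4 k6 - k3 k5) = 3.55`, so the roughly tenfold slowdown used
  to construct the `chi1_bar` channel is not reproduced as a model output
  at those rates (the MDA-MB-468 set allows ~134-fold).
* Clonogenic survival is not modelled; the persistence AUC is a damage
  proxy only.

## Problem sizes used in the test suite

Ensemble comparisons use 1000 replicates on 25-point grids (the two
cell-line parameter sets) and 2000-3000 replicates for the reduced-rate
systems that the brute-force master-equation oracle can cover
(state space truncated at 12 molecules). Recovery benchmarks use 3-50
Nelder-Mead restarts and 5 replicate noisy data sets. These sizes resolve
the quantities asserted (Monte-Carlo standard errors reach ~1-3% of the
signal) while keeping the default suite quick to run.
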