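---
title: "Methods: a spatial krill-predator-fishery simulator for management strategy evaluation"
author: "krillmse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spatial krill-predator-fishery simulator for management strategy evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krillmse)
```

## The problem

The Antarctic krill fishery competes with penguins, seals, whales and fish
for a single forage resource across the small-scale management units (SSMUs)
of statistical subareas 48.1, 48.2 and 48.3. Two families of spatial
management are on the table: *feedback management* (FBM), in which a fixed
decision rule periodically redistributes the catch limit among SSMUs in
response to a monitored indicator, and a *marine protected area* (MPA), a
fixed set of no-take SSMUs with the displaced catch redistributed elsewhere.
`krillmse` implements a minimally realistic operating model of this system
and an evaluation layer that expresses every scenario outcome as a
counterfactual ratio against a matched base case, so 1.0 always means "the
management action changed nothing".

## The operating model

The model runs on a seasonal time step (summer `s = 0`, winter `s = 1`;
step `t = 2(year - 1) + s`). Krill biomass `K_i` (g) and mean individual
krill mass `w_i` (g) live on SSMUs; each predator population is resident in
one SSMU and forages across SSMUs through a season-specific distribution.
One season applies, in order:

1. **Mass trend.** `w_i(year) = w_i(0) * max(0.1, 1 + tau_i * year)`.
   The per-SSMU trend `tau_i` stands in for the effect of warming on krill
   gross growth potential; the floor keeps mass positive under any trend.
2. **Recruitment (summer only).** `R_i = r_i * K_i * eps`, with `eps`
   lognormal with median 1 and log-SD `sigma` drawn per SSMU per year.
   Median-1 deviates make the `sigma = 0` limit exactly deterministic.
3. **Movement.** `K' = t(M_s) %*% K` with `M_s` row-stochastic; the
   "no movement" reference-set members use identity matrices, the "drift"
   members a retention/downstream-flow matrix. Movement conserves biomass
   exactly.
4. **Threshold check.** An SSMU with allocated catch whose pre-harvest
   density `K_i / A_i` falls below the threshold (default 15 g m^-2)
   suspends fishing this season; the event is a *threshold violation* and
   the forgone catch is not redistributed (per-season redistribution is not
   part of any rule modeled here).
5. **Demand assembly.** Predator demand per SSMU is
   `sum_j adults_j * q_{j,s} * f_{j,i,s}`; fishery demand is the allocated
   limit in individuals times current mean mass, `Theta_{i,s} * w_i(t)`.
6. **Rationing.** `lambda_i = min(1, K_i / total demand)`; every consumer
   (predators and fishery alike) realizes `lambda * demand`. Competition is
   therefore proportional and symmetric.
7. **Krill survival.** `K(t+1) = surv_{i,s} * (K' - catch - predation)`.
8. **Predator demography.** Adults follow
   `A(t+1) = s_j * A(t) + maturing cohort`; each summer a cohort
   `A * e(x) * m_j` is bred, maturing `lag_j` years later. Foraging success
   `x_j = sum_i f_{j,i,s} lambda_i` couples food shortage to breeding only
   (adult survival is constant) - the simplest recursion consistent with an
   "effective breeders" response. `e(x)` is either linear (identity) or
   hyperstable, `x(1+c)/(x+c)`, which keeps breeding high until shortage is
   severe.

Catch limits follow the allocation identity
`Theta_i = B0 * gamma * p'_i / w_i`, with `B0` the initial arena krill
biomass, `gamma = 0.093` the fully developed harvest rate, and `p'` the
allocation fractions (summing to 1 over SSMU-by-season cells). Limits in
individuals are converted back to biomass with the *current* (trended) mean
mass, so a warming-driven decline in individual mass feeds through to the
tonnage actually taken.

## Management strategies

* **none** - the baseline 2009-2017-style spatial/seasonal catch
  distribution, fixed for the whole run. This is also the "No FBM"/"No MPA"
  base case.
* **fbm_krill** - every `interval` years (default 5), allocation fractions
  are set to normalized summer krill densities, `p'_i = d_i / sum(d)`.
* **fbm_pengs** - every `interval` years, penguin changes
  `dP_i = P_i(t) - P_i(t - 2*interval)` over penguin-resident SSMUs are
  remapped to `p_i = dP_i + alpha * |min(dP)|` and normalized. With
  `alpha = 1` the worst-declining SSMU gets `p = 0` and is closed until the
  next reassessment (ties: all closed). SSMUs without resident penguins
  receive fraction 0 - the indicator is undefined there; this is a
  consequential reading of the rule, flagged here deliberately.
* **mpa** - applied once at `t = 0`: masked SSMUs get fraction 0 and the
  displaced share is spread over open cells proportional to their baseline
  fractions (uniformly if all open baselines are 0).

Feedback rules emit per-SSMU *annual* fractions; within each SSMU the
baseline summer/winter split is retained, preserving the seasonal structure
of the fishery. Indicators are read from the true simulated state without
observation error. A degenerate indicator (all-zero densities, or penguin
changes summing to zero after the remap) keeps the previous allocation and
is logged in the trial's reassessment records. The total allocated fraction
is conserved at 1 under every rule and reassessment - the overall catch
limit is never reduced. `alpha < 1` is rejected whenever it would produce a
negative remapped allocation.

## Ensembles and counterfactuals

A trial is fully determined by (parameterization, scenario, seed); the only
randomness is the summer recruitment deviates. Ensembles run `n_trials`
trials against each member of the four-member reference set - the 2x2 of
krill movement {none, drift} and breeder response {linear, hyperstable} -
with per-trial seeds derived by a documented stable arithmetic hash, and
average across trials and parameterizations. Scenario and base case share
seed streams (*common random numbers*): expectations are unchanged, the
variance of the ratios drops, and no-op comparisons are exactly 1; an
unpaired mode is available via `run_comparison(..., paired = FALSE)`.

Outcomes are evaluated at years 30 and 100 (state at the end of the
evaluation year; catch accumulated through it) at two scales: per SSMU, and
arena-wide as ratios of summed totals (never means of per-SSMU ratios).
Threshold-violation probabilities are the flagged share of fishing
trial-seasons. The printed sources define no arena-scale aggregation for
violation probability, so two are emitted and labeled: `arena_any` (the
probability that at least one fished SSMU violates in a season) and
`arena_weighted` (the catch-weighted mean of SSMU probabilities); in a
heavily fished arena `arena_any` saturates near 1 and the weighted form is
the informative one. Deltas (`ratio - 1`) are classified on the comparison
scale: none (< 0.01), small (0.01-0.10), medium (> 0.10-0.50), large
(> 0.50), with the boundaries closed exactly as written.

## The synthetic world

The deposited inputs of the original operating model are not bundled, so
`generate_parameterization()` builds a synthetic stand-in with the stated
structure: 15 SSMUs labeled 48.1 (1-8), 48.2 (9-12), 48.3 (13-15); the
published residency pattern (penguins in 12 SSMUs, seals in 5, whales in
the two pelagic units 1 and 9, fish everywhere); coastal krill densities
(20-40 g m^-2) above pelagic ones (8-18 g m^-2), with some units near the
15 g m^-2 threshold so the suspension machinery is exercised; Dirichlet
baseline catch fractions concentrated on coastal shelves; and per-SSMU mass
trends drawn from [-0.003, -0.001] yr^-1, a material 10-30% century decline.
The MPA mask covers a chosen fraction of the coastal SSMUs of subareas
48.1/48.2 (Planning Domain 1) and never closes subarea 48.3.

**Initialization at the unfished fixed point.** The specified krill dynamics
are linear in biomass (proportional recruitment, constant survival,
demand-capped consumption), so the unfished interior equilibrium is a
knife-edge: it exists but does not attract, and a burn-in alone cannot find
it. The generator therefore solves for it analytically: predator fecundity
is set to `(1 - s^2)/s` so each population is stationary at full foraging
success, per-capita demands are rescaled so peak seasonal predation is 4% of
local krill biomass, and per-SSMU recruit rates are solved from the seasonal
cycle `K1 = s_s((1+r)K0 - C_s)`, `K0 = s_w(K1 - C_w)` (with winter demand
exerted by the post-breeding abundance `A/s`). `equilibrate()` keeps the
burn-in-and-verify contract - it runs the deterministic unfished model
forward, resets stocks to the end state, and errors if a further century
drifts any stock by 5% or more - and is an exact no-op on generated
parameterizations. Reference-set members with drift movement share the base
member's initial stocks (a controlled comparison) and are therefore slightly
off their own fixed point; the paired counterfactual design is what removes
such base-case drift from every reported ratio.

## Numerical choices and degenerate inputs

* Rationing with `lambda < 1` consumes all available krill in that SSMU;
  with proportional recruitment the SSMU then stays empty until movement
  reseeds it. Parameter choices keep routine dynamics away from this regime
  (peak seasonal predation 4% of local biomass).
* `0/0` counterfactual ratios are reported as 1.0 with a warning; positive
  over zero is NA with a warning. Never-fished SSMUs report violation
  probability 0 with a note.
* Ties in the "greatest penguin decline" close all tied SSMUs
  (deterministic and order-independent).
* Recruitment deviates are the only RNG draws, and none are consumed when
  `sigma = 0`, so the deterministic limit is bit-reproducible and paired
  arms stay synchronized.
* Problem sizes used by the bundled checks and the acceptance script - 2 to
  50 trials per reference-set member at a 100-year horizon - were chosen as
  scaled-down ensembles of the full 1001-trial design; means are unchanged
  in expectation and the pairing keeps ratio noise small at these sizes.

## What passing tests do and do not show

The synthetic world reproduces the *structure* of the study system - its
spatial layout, residency, seasonal fishery, reference-set uncertainty
bracketing, threshold behavior, and the qualitative trade-off patterns
(closures shift catch away from declining penguin SSMUs; SSMUs with reduced
relative catch show weakly higher relative penguin abundance; the MPA takes
zero catch inside the mask and spreads it proportionally outside). It does
not reproduce the original study's numerical endpoints: those depend on the
deposited operating-model parameter values (initial biomasses, demands,
movement and foraging matrices fit to tracking data), which are inputs this
package deliberately does not fabricate. With the fully developed fishery
the synthetic system is more collapse-prone than a tuned parameterization
would be - fished SSMUs slide toward the density threshold and, over
decades, below it - so century-scale deltas here are larger than a
calibrated system would print. Within-group species dynamics,
environment-driven movement, observation error on indicators, and
winter recruitment are out of scope.
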