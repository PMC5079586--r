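---
title: "Length-based assessment of a data-limited grouper fishery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-based assessment of a data-limited grouper fishery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenstock)
```

## The problem this package addresses

Many artisanal fisheries — the Galapagos sailfin grouper (*Mycteroperca
olfax*, "bacalao") fishery being the motivating case — have no continuous
record of catch and effort. What survives across decades of intermittent
monitoring is the *size of landed fish*. `lenstock` assembles the standard
chain of length-based, data-limited assessment methods so that an analyst
with per-fish length records and a handful of life-history parameters can
ask: is this stock being fished before it matures, before it reaches its
optimal harvest size, and how hard, relative to what its biology can
sustain?

The chain has five stages, each usable on its own:

1. **Catch-composition indicators** (Froese's framework): percentage of the
   catch above the length at maturity $L_m$, inside the optimum length
   interval around $L_{opt}$, and above the mega-spawner threshold.
2. **Length-based spawning potential ratio (LB-SPR)**: a per-recruit model
   fit to a length composition by maximum likelihood, estimating relative
   fishing mortality $F/M$ and logistic gear selectivity
   $(SL_{50}, SL_{95})$, from which SPR follows.
3. **Catch-curve mortality**: ages assigned from lengths by inverting the
   growth curve, Chapman–Robson survival on the descending limb, and a
   bias-corrected total mortality $Z$.
4. **Generational turnover**: $\bar{GT} = AM + (T_{max} - AM)/2$, a
   biological clock for how fast management effects could become visible.
5. **Trend models**: binomial GLMs of indicator proportions against year,
   and a random-intercept model of landed length,
   `TL ~ year + (1 | source)`, tested by parametric bootstrap.

An equilibrium age-structured simulator generates ground-truthed synthetic
datasets in the same per-fish format, so every estimator in the chain can be
exercised against known parameters.

## The per-recruit model

All model-based stages share one population skeleton. Ages run in annual
steps $a = 0, 1, \dots, T_{max}$ (a finer step is available; annual is the
default because the assessment's sums are annual). Mean length at age
follows von Bertalanffy growth
$L_a = L_\infty (1 - e^{-k (a - t_0)})$, and length at age is normal with
standard deviation $CV_{L_\infty} \times L_a$. Total mortality at age is

$$Z_a = M + F \, S(L_a), \qquad F = (F/M) \cdot M,$$

with the asymptotic logistic selectivity
$S(l) = \left[1 + e^{-\ln 19\,(l - SL_{50})/(SL_{95} - SL_{50})}\right]^{-1}$,
anchored so that $S(SL_{50}) = 0.5$ and $S(SL_{95}) = 0.95$ exactly. The
maturity ogive uses the same $\ln 19$ parameterisation with anchors
$(L_{m50}, L_{m95})$. Survivorship to age $a$ is the product of
$e^{-Z_{a'}}$ over younger ages, so the unfished case reduces to
$e^{-M a}$ exactly.

Individual growth variability is propagated with **growth-type groups**: 13
sub-cohorts whose $L_\infty$ values are equally spaced across
$\pm 2.5$ standard deviations of $\mathrm{Normal}(L_\infty,
CV_{L_\infty} L_\infty)$, weighted by the normal density. These are
conventional defaults for this family of methods and both are configurable;
with one group the model collapses to a single cohort, which is what the
package's brute-force test oracle checks against.

**Expected catch at length** — the observation model fitted to data — is the
selectivity-weighted number of fish per length bin: within each group,
numbers-at-age are spread over 2-cm half-open bins by the age's normal
length distribution, weighted by selectivity at the bin midpoint, combined
across groups, and normalised.

**Spawning potential ratio** is lifetime egg production per recruit under
fishing relative to the unfished value,
$SPR = P_{fished}/P_{unfished}$ with
$P_{unfished} = \sum_a E_a e^{-Ma}$ and the fished sum using the
$Z_a$-survivorship. Egg production at age integrates the maturity ogive and
the fecundity–length power law over the age's length distribution,
$E_a = \sum_l P(l \mid a)\, Mat(l)\, l^b$. We integrate rather than
evaluate at the mean length because propagating length variability is the
point of a length-based method: ages that straddle the maturity ogive
contribute eggs through their larger-than-average members, and evaluating
only the mean length suppresses exactly that contribution (for the default
grouper parameters the difference is SPR 0.050 vs 0.038 at $F/M = 1.98$).
By construction $SPR = 1$ exactly at $F = 0$ and SPR decreases
monotonically in $F/M$.

## Estimation and numerical choices

`fit_lbspr()` maximises the multinomial log-likelihood
$\sum_b n_b \log p_b(F/M, SL_{50}, SL_{95})$ by Nelder–Mead simplex search
over $(\log F/M, \log SL_{50}, \log(SL_{95} - SL_{50}))$ — the transforms
enforce positivity and ordering without constraints. Three deterministic
starts (anchored at the 15th/25th/40th percentiles of the observed
composition, with $F/M$ 0.5/1/2.5) guard against local optima, and the best
optimum is polished by a restart. Convergence uses a relative tolerance of
1e-8 on the log-likelihood. Bin probabilities below 1e-12 are floored
inside the likelihood only. An estimate of $F/M$ below 0.001 is flagged as
sitting on the zero-fishing boundary. Uncertainty comes from a
nonparametric bootstrap over individual fish (multinomial resampling of the
binned counts, 100 replicates by default, refit from the point estimate)
under a fixed seed.

Degenerate inputs are errors, not silent results: fewer than three occupied
bins, a dead simulated population, a single age class in the catch curve, a
descending limb with under three fish. Ties in the age-frequency peak go to
the youngest age of maximum catch, and the descending limb defaults to
"ages at and after the peak" (a peak-plus-one rule is available, since
conventions differ).

For the catch curve, ages are assigned by inverting the growth curve,
$a = t_0 - \ln(1 - TL/L_\infty)/k$, floored so that age classes are
right-open like the length bins, and capped at $T_{max}$ (lengths at or
above $L_\infty$ cannot be inverted and map to $T_{max}$, with a counter).
The Chapman–Robson estimator then gives $S = T/(n + T - 1)$ on the recoded
limb ages and the bias-corrected
$Z = -\log S - (n-1)(n-2)/[n(T+1)(n+T-1)]$. Two caveats are inherent and
documented rather than hidden: $t_0$ and $k$ are not observable from
lengths alone (the mortality report always echoes the values used), and
length-to-age conversion smears old ages where the growth curve flattens,
which attenuates $Z$ — the package's simulation tests quantify this rather
than pretend the estimator is unbiased.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| $L_\infty$ | 110 cm | published growth estimate for the grouper |
| $M$ | 0.29 yr$^{-1}$ | congener-based natural mortality |
| $M/k$ | 2.7 | life-history ratio for late-maturing, indeterminate growth |
| $CV_{L_\infty}$ | 0.10 | typical for teleosts; never published for this stock, so the runners sweep 0.05–0.15 |
| $L_{m50}$ | 65.3 cm | published maturity estimate |
| $L_{m95}$ | $1.1 \times L_{m50}$ | only the 50% point is published; a 10% spread is a moderately steep ogive |
| $b$ (fecundity exponent) | 3 | eggs roughly proportional to weight, weight roughly cubic in length |
| $t_0$ | 0 | unobservable from length data; echoed in every mortality report |
| bins | 2 cm, $[0, 1.3 L_\infty)$ | resolves the composition without empty-bin noise at the observed sample sizes |
| growth-type groups | 13 over $\pm 2.5$ sd | conventional defaults for this model family |
| bootstrap | 100 replicates | SD stabilises well below this for the compositions used |

Every one of these is a config key or function argument; `run_assessment()`
logs the resolved configuration in its manifest.

## What the simulator does and does not emulate

`simulate_timeseries()` draws landings from an equilibrium age-structured
population: constant recruitment (a per-recruit world, matching the SPR
definition, with no stock–recruit feedback), independent equilibria per
year, ages sampled proportional to survivorship times selectivity at the
age's mean length, lengths from the age's zero-truncated normal. This is
exactly the world the estimators assume, which is what makes
parameter-recovery tests meaningful: the LB-SPR fit recovers
$(F/M, SL_{50}, SL_{95}) = (2, 39, 47)$ with median errors under 3% at
$n = 5000$.

Passing those tests therefore shows internal consistency, not robustness to
real data. Real landings violate the generative model in ways the simulator
deliberately omits: recruitment pulses, seasonal growth, spatial and
vessel-level heterogeneity in selectivity, measurement rounding to favoured
lengths, sex change (the grouper is a protogynous hermaphrodite), and
spawning-aggregation targeting. Estimates on field data inherit whatever
bias those violations induce; the simulator is a correctness harness, not
evidence about nature.

## Choices made where the design was open

* **Selectivity applied at bin midpoints** in the observation model, but at
  the age's mean length inside $Z_a$: mortality acts on cohorts (ages),
  while the gear observes lengths. With a knife-edge gear the two coincide,
  which the oracle tests exploit.
* **Percentage indicators carry full precision**; rounding to one decimal
  happens only in display, so complements (e.g. % mature vs % below
  maturity) stay exact.
* **Boundary conventions**: mature means $TL \ge L_{m50}$; the optimum
  interval is closed; mega-spawner means strictly above the threshold.
  Chosen so boundary fish are counted exactly once per definition.
* **Indicator trend counts** are reconstructed as
  `round(pct * n / 100)` when only a published summary table is available —
  the reconstruction inherits the table's rounding, which is why the trend
  chi-squares from summaries are reported as approximate.
* **Mixed-model machinery** uses `lme4` (maximum likelihood, not REML,
  because the bootstrap compares models differing in fixed effects); the
  parametric bootstrap simulates from the fitted null and refits both
  models, with the plus-one p-value rule so p is never exactly zero.
* **Problem sizes in the test-suite**: recovery studies use 20 seeds at
  $n = 5000$ and simulation checks up to $n = 4 \times 10^4$ — sizes at
  which sampling error is small relative to the tolerances being asserted,
  while a full suite run stays in the low minutes.

## Known limitations

Equilibrium assumptions are strong: SPR and the catch curve both read a
snapshot length/age structure as a steady state, so recent changes in
effort show up with a lag and transient dynamics bias both. Asymptotic
selectivity is assumed (no dome); a dome would masquerade as extra
mortality. The maturity ogive's 95% point and the fecundity exponent are
defaults, not estimates, and SPR has some sensitivity to both (quantified
in the acceptance runner's sweep). Catch-curve mortality from
length-derived ages is attenuated near $L_\infty$ and should be read
alongside, not instead of, the LB-SPR exploitation estimate.
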