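# lenstock — length-based assessment of data-limited fish stocks

`lenstock` is an R package for assessing fisheries where the only signal
that spans the history of the fishery is the **length of landed fish**. It
was built around the artisanal fishery for the Galapagos sailfin grouper
(*Mycteroperca olfax*, "bacalao"), but every method is generic: supply
per-fish records (`year, source, tl_cm`) and a life history, and the
package runs the standard data-limited chain used by fisheries scientists:

* **Froese catch-composition indicators** — % of the catch at or above the
  length at maturity L\_m, % inside the optimum length interval around
  L\_opt = 10^(1.0421·log10(L∞) − 0.2742) (± 10%), and % of mega-spawners
  (fish above L\_opt + 10%);
* **Length-based spawning potential ratio (LB-SPR)** — a growth-type-group
  per-recruit model with total mortality at age Z\_a = M + F·S(L\_a) and
  logistic selectivity S(l) = 1/(1 + e^(−ln19·(l−SL50)/(SL95−SL50))),
  fitted to a binned length composition by multinomial maximum likelihood
  to estimate F/M, SL50 and SL95, with
  SPR = P\_fished/P\_unfished, P\_unfished = Σ\_a E\_a·e^(−Ma);
* **Chapman–Robson catch-curve mortality** — ages from inverse von
  Bertalanffy growth, survival S = T/(n + T − 1) on the descending limb,
  and bias-corrected Z = −log S − (n−1)(n−2)/[n(T+1)(n+T−1)];
* **Generational turnover** — GT = AM + (Tmax − AM)/2;
* **Year-trend inference** — binomial GLMs of indicator proportions and a
  random-intercept model `TL ~ year + (1 | source)` with parametric
  bootstrap testing;
* an **equilibrium age-structured simulator** producing ground-truthed
  synthetic datasets in the same format, so every estimator can be
  validated by parameter recovery.

The methods vignette (`vignettes/length-based-assessment.Rmd`) documents
the model, its assumptions, all defaults, and what the simulator does and
does not emulate.

## Worked example

Simulate a 489-fish landing sample from an equilibrium population fished at
F/M = 1.98 with gear selectivity (39, 46.7) cm — the exploitation regime
estimated for this fishery — and push it through the chain:

```r
library(lenstock)

lh  <- bacalao_life_history()       # Linf 110, Lm50 65.3, M 0.29, M/k 2.7
sel <- selectivity_params(39, 46.7)

compute_lopt(lh$l_inf)
#> Lopt = 71.3 cm; optimum interval 64.2-78.4 cm; mega-spawners > 78.4 cm

pop <- equilibrium_population(lh, 1.98, sel)
ds  <- sample_catch_lengths(pop, sel, 489, seed = 7)

compute_indicators(ds, lh)
#>  year   n pct_mature pct_opt pct_mega mean_tl sd_tl
#>  2012 489        3.5     3.3      0.6    46.1   9.4

fit_lbspr(length_composition(ds$tl_cm, make_length_bins(lh)), lh,
          n_boot = 100, seed = 7)
#> Length-based SPR fit
#>   n = 489 fish, 13 growth-type groups, logLik = -1426.47
#>   F/M  = 2 (+/- 0.26 SD)
#>   SL50 = 38.4 (+/- 0.81 SD) cm
#>   SL95 = 47.1 (+/- 1.5 SD) cm
#>   SPR  = 0.0466 (+/- 0.012 SD)

chapman_robson(build_age_frequency(ds, lh))
#> Chapman-Robson mortality estimate:
#>   annual survival S = 52.6% (se 1.7%)
#>   total mortality Z = 0.64 /yr (se 0.03)
#>   limb: n = 395 fish, recoded-age sum T = 438

generational_turnover(lh$am, lh$tmax)
#> Generational turnover: 13.8 yr (AM = 6.5, Tmax = 21.0)
```

Reading the numbers: only 3.5% of the simulated catch is mature and
essentially none are mega-spawners — the gear recruits fish at ~39 cm,
some 26 cm below the length at maturity. The LB-SPR fit recovers the
exploitation it was simulated under (F/M ≈ 2) and puts SPR below 5% of
unfished egg production, deep in recruitment-overfishing territory; the
catch curve independently indicates total mortality far above M = 0.29.
A stock with a ~14-year generational turnover recovers slowly from that
state.

The same chain runs end-to-end from a YAML config (real CSV data or a
simulation scenario) via `run_assessment("config.yaml", out_dir = "out")`,
which also writes a reproducibility manifest; `inst/scripts/lenstock.R`
exposes each stage as a shell subcommand.

Two small published datasets ship as plain-text fixtures in
`inst/extdata/`: the 25 historical photograph-derived lengths from
1925–1938 and the per-year indicator summary table for 1983–2012.

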