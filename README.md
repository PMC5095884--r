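# lumigrow

Quantitative analysis of tumor growth kinetics from longitudinal
bioluminescence imaging of mouse cohorts, with caliper cross-calibration.

## The problem

Bioluminescence imaging of luciferase-expressing tumor cells reports the
number of *living* tumor cells: the photon flux (photons/sec) is
proportional to viable cell count. A caliper, in contrast, measures the
whole palpable mass — living cells, necrotic tissue, and stroma. In
orthotopic breast-tumor xenografts the two readouts diverge sharply: the
bioluminescent signal plateaus around day 20 post-graft while the
caliper volume keeps growing almost linearly for weeks. `lumigrow`
implements a mechanistic model that reconciles the two, and the
population (nonlinear mixed-effects) machinery to fit it to a cohort of
animals.

## The model

The tumor burden is split into a proliferative compartment *P(t)* (alive,
light-emitting) and a necrotic compartment *N(t)* (dark, but contributing
to volume). *P* grows logistically with proliferation rate *a* (day⁻¹)
toward a micro-environment carrying capacity *K* (photons/sec), and cells
displaced by competition accumulate in *N*:

    dP/dt = a P (1 − P/K),       P(0) = P₀
    dN/dt = a P² / K,            N(0) = 0

with *P₀* the injected cell burden expressed in signal units. Both
compartments have closed-form solutions (evaluated overflow-safely in the
log domain); the total burden *V = P + N* is exponential early and
asymptotically linear with slope *aK* — a mechanistic explanation of the
classic biphasic (exponential-then-linear) tumor volume curve. Signal
converts to volume through the cells-to-light calibration (88.4
photons/sec per cell, fit by regression through the origin) and the
packing rule 10⁹ cells ≅ 1 cm³. The caliper volume exceeds the converted
cell-mass volume by a proportionality constant λ, whose excess over 1 is
read as the stromal fraction of the tumor, 100·(1 − 1/λ) %.

Inter-animal variability is handled by a nonlinear mixed-effects model:
individual parameters are lognormal around the population values,
observations carry proportional Gaussian error, and the population
likelihood is maximized with a SAEM (stochastic approximation EM)
engine written for this model family — Metropolis–Hastings sampling of
each animal's parameters, stochastic-approximation sufficient statistics,
closed-form M-steps, and Louis-type observed Fisher information for
relative standard errors (RSE). λ is estimated in a second stage on the
caliper records (a joint three-parameter fit is available as an option).

## Worked example

Simulate a 20-mouse cohort under the default study conditions (twice-weekly
imaging days 6–43, 1.5×10⁵ injected cells, 15% proportional noise) and
refit it:

```r
library(lumigrow)
cohort <- simulate_cohort(cohort_design(), seed = 1)
fit    <- saem_fit(cohort, seed = 1)
fit    <- fit_lambda(fit, seed = 1)
summary(fit)
```

```
Population parameter estimates (20 animals)
 parameter           unit estimate cv_percent rse_percent
         a         day^-1 4.28e-01       28.0        6.17
         K photons/second 4.29e+09       49.0       10.47
    lambda              - 2.23e+00       10.1        2.46
Proportional residual error sigma = 0.157
Implied stromal fraction: 55% of the total volume
```

The table reads like a standard population-model report: for each
parameter the population estimate, the inter-animal coefficient of
variation (CV, from the lognormal random-effect variance), and the
relative standard error (RSE, an identifiability diagnostic). Here the
generating truth was a = 0.399 day⁻¹ (CV 31.1%), K = 4.35×10⁹ photons/sec
(CV 55.3%), λ = 2.25 (CV 10%) — all recovered within a few percent, with
λ implying that roughly half the palpable volume is not tumor cells.

Tabulating the fitted typical animal shows the compartment kinetics and
the unit conversions:

```r
simulate_typical(growth_params(a = coef(fit)[["a"]], K = coef(fit)[["K"]],
                               P0 = 1.5e5 * 88.4, lam = coef(fit)[["lam"]]),
                 grid = c(6, 20, 43))
```

```
  time   P_signal    N_signal    V_signal  P_cm3  N_cm3  V_cm3 V_caliper_cm3
1    6  166227804     3287052   169514856 0.0019 0.0000 0.0019        0.0043
2   20 4036367547  8120200459 12156568006 0.0457 0.0919 0.1375        0.3071
3   43 4288174349 49773255070 54061429419 0.0485 0.5630 0.6116        1.3656
```

By day 20 the proliferative signal has essentially saturated while the
necrotic compartment keeps accumulating; the λ-scaled caliper volume
reaches ≈1.3 cm³ at day 43.

Other entry points: `fit_cells_to_light()` (calibration plates),
`two_stage_fit()` (naive per-animal baseline), `run_analysis()` (one-call
pipeline from a config list or YAML file, returning the parameter table,
trajectories and percentile bands), `recovery_experiment()`
(simulate-then-refit studies), `inject_dropout()` (humane-endpoint
censoring).

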