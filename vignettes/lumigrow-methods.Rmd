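---
title: "Methods: the proliferative/necrotic growth model and its population fit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the proliferative/necrotic growth model and its population fit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumigrow)
```

## The structural model

`lumigrow` models a growing xenograft as two compartments. The
proliferative compartment $P(t)$ is the population of living, dividing,
luciferase-expressing cells; it is what bioluminescence imaging sees, in
photons/sec. Its growth is logistic — competition for space and nutrients
caps it at a micro-environment carrying capacity $K$:

$$\frac{dP}{dt} = a P \left(1 - \frac{P}{K}\right), \qquad P(0) = P_0 .$$

Cells crowded out of proliferation do not disappear: they accumulate in a
necrotic compartment $N(t)$, which emits no light but still occupies
volume. Mass conservation assigns the competition loss term to $N$:

$$\frac{dN}{dt} = \frac{a P^2}{K}, \qquad N(0) = 0 .$$

Both have closed forms. With $S(t) = 1 + \tfrac{P_0}{K}(e^{at}-1)$,

$$P(t) = \frac{P_0 e^{at}}{S(t)}, \qquad
  N(t) = K \log S(t) - P(t) + P_0, \qquad
  V(t) = P + N = K \log S(t) + P_0 .$$

The total burden $V$ is exponential while $P \ll K$ and asymptotically
linear with slope $aK$ once $P$ saturates — a mechanistic account of the
familiar biphasic tumor volume curve. A note on curvature, since the
transition is sometimes described loosely: $V$ is convex throughout
($V'' = a^2P(1-P/K) > 0$) and $\log V$ is concave throughout, so neither
ever changes sign. What does change sign, exactly once, is $V'''$: the
growth acceleration rises to a single peak (at $P = K/2$) and then decays
to zero. The test suite asserts the transition in that form, together
with the late slope converging to $aK$.

Volume units enter through two constants: the cells-to-light ratio
(default 88.4 photons/sec per cell, estimated from calibration plates by
regression through the origin) and a packing density of $10^9$ cells per
cm³. The caliper measures more than the converted cell mass — stroma,
in particular — so predictions for caliper data carry a proportionality
constant $\lambda \ge 1$, and $100(1 - 1/\lambda)$ % of the palpable
volume is read as stromal.

The proliferation rate can be read as exponential doubling at low
density; `cell_cycle_length()` exposes $\tau = \log 2 / a$ as that
interpretation only. $a$ is the primitive parameter everywhere.

## Statistical model

For animal $i$ at time $t_{ij}$,

$$y_{ij} = f(t_{ij}; \theta_i)\,(1 + \varepsilon_{ij}), \qquad
  \varepsilon_{ij} \sim \mathcal{N}(0, \sigma^2), \qquad
  \theta_i = \theta_\mu \odot e^{\eta_i}, \quad
  \eta_i \sim \mathcal{N}(0, \theta_\omega).$$

The error is proportional on the natural scale (not log-additive): the
standard deviation of an observation is $\sigma f$. Individual parameters
are lognormal; the inter-animal CV reported for a diagonal element
$\omega^2$ is $100\sqrt{e^{\omega^2}-1}$ %. Assumptions worth making
explicit:

* $\theta_\omega$ is **diagonal** — no $a$–$K$ correlation is estimated.
  Per-parameter CVs are identifiable at cohort sizes of 20; a correlation
  is not, and none is reported in this literature's tables.
* $P_0$ is **fixed**, not estimated: the injected cell count times the
  cells-to-light ratio ($1.5\times10^5 \times 88.4 \approx 1.33\times10^7$
  photons/sec by default). Day 0 is the injection day; observation times
  are days post-graft.
* $\sigma$ defaults to 0.15 (15 % proportional). Optical-imaging
  repeatability studies put instrument-level variability in the several-
  percent range before biological sources; 15 % is a realistic total and
  is configurable everywhere it appears.

## SAEM estimation

`saem_fit()` maximizes the population likelihood by stochastic
approximation EM:

* **E-step** — for each animal, Metropolis–Hastings sampling of
  $\phi_i = \log\theta_i$ from its conditional distribution: one
  independence proposal from the current population distribution plus
  (by default) 3 componentwise random-walk sweeps per iteration. The
  random-walk scale adapts during exploration toward a 30 % acceptance
  rate and is then frozen, so the smoothing-phase kernel is fixed.
* **SA-step** — sufficient statistics
  ($\sum_i \phi_i$, $\sum_i \phi_i^2$, weighted residual sums of squares)
  are averaged with step size $\gamma_k = 1$ for the first $K_1 = 300$
  iterations (exploration) and $\gamma_k = 1/(k-K_1)$ for the next
  $K_2 = 200$ (smoothing).
* **M-step** — closed-form updates: $\mu = $ mean of $\phi$ statistics,
  $\omega^2$ their variance, $\sigma^2$ the mean squared proportional
  residual.

The schedule (300 + 200, 3 transitions) is a conventional setting for a
two-parameter structural model and converges in a few seconds at $n=20$;
all of it is adjustable through `saem_control()`. Given a seed the entire
trajectory is bit-reproducible. Initialization comes from
`two_stage_fit()` — per-animal nonlinear least squares on the log signal,
pooled by geometric mean and log-variance — with a fallback of
$a = 0.3$ day⁻¹ and the geometric-mean plateau for $K$ if individual
fits fail. The two-stage fit also serves as an independent baseline: on
rich, low-noise designs it must agree with SAEM, and the importance-
sampled marginal likelihood at the SAEM optimum must not fall below the
likelihood at the two-stage estimates; both are enforced in the tests.

**Standard errors.** `compute_rse()` estimates the observed Fisher
information by a Louis decomposition at the optimum:
$I_{\text{obs}} = \sum_i \{-E[H_i\,|\,y] - E[g_i g_i^\top|\,y]
+ E[g_i|y]E[g_i|y]^\top\}$, with analytic complete-data scores/Hessians
and the conditional expectations Monte-Carlo averaged over MH samples
(200 by default, after 50 burn-in sweeps). RSEs are $100\,se/\hat\theta$;
for lognormal fixed effects the delta method reduces this to
$100\,se(\log\hat\theta)$. On a constant-prediction toy model this
estimator is validated in the tests against the closed-form one-way
random-effects (GLS) standard error. When variance components collapse to
their floor (noise-free data) the information matrix is singular; RSEs
are then returned as `NaN` with a warning rather than fabricated.

**The caliper stage.** `fit_lambda()` defaults to *sequential*
estimation, mirroring the narrative order of the analysis: individual
kinetics $(a_i, K_i)$ are frozen at their empirical-Bayes estimates, each
animal's converted cell-mass volume $v_i(t)$ is computed, and
$V_{ij} = \lambda_i\,v_i(t_{ij})(1+\varepsilon)$ is fit as a
one-parameter lognormal population model with its own proportional error.
Whether the original analysis estimated $\lambda$ jointly or sequentially
is not documented; both are implemented (`method = "joint"` refits
$(a, K, \lambda)$ on both observation streams with separate residual
errors) and they agree on simulated cohorts. Sequential is the default
because it keeps the bioluminescence fit independent of caliper-data
quality. The percentile bands reported by `run_analysis()` expose both
scalings of the volume band — per-animal $\lambda_i$ and typical
$\lambda$ — since either renormalization is defensible for display.

## Numerical choices

* $e^{at}$ is never formed directly: $\log S(t)$ is a two-term
  log-sum-exp, so evaluation is exact-to-double-precision for $at$ far
  beyond 700. Estimation routinely proposes extreme parameters; the
  model surface must not overflow.
* Proposals with $K \le P_0$ get likelihood $-\infty$ and are rejected,
  enforcing the `P0 < K` invariant inside the samplers and optimizers
  (constructors enforce it for users).
* Variance floors: $\omega^2 \ge 10^{-8}$, $\sigma \ge 10^{-6}$, so
  degenerate (noise-free) data collapse gracefully instead of producing
  NaNs.
* `simulate_ode()` (adaptive lsoda) is not the fitting path — the closed
  forms are — but the numerical oracle the closed forms are verified
  against, to relative tolerance $10^{-6}$ over
  $a \in [0.05, 1]$, $K/P_0 \in [10, 10^5]$, $t \in [0, 60]$.
* `carlsson_volume()` ($V = \ell w^2/2$) swaps its arguments with a
  warning when width exceeds length, since operators record the axes
  inconsistently; erroring would discard usable measurements.

## The synthetic cohort generator

`cohort_design()` encodes the study conditions the package is meant to
analyze: 20 animals, $1.5\times10^5$ cells injected at day 0, imaging
twice weekly from day 6 to day 43, typical values
$a = 0.399$ day⁻¹ (CV 31.1 %), $K = 4.35\times10^9$ photons/sec
(CV 55.3 %), $\lambda = 2.25$ (CV 10 %), and 15 % proportional noise on
both channels (independent instruments). The exact visit days are not
fixed by a twice-weekly protocol, so the default concretizes it as 12
visits (days 6, 9, 12, 15, 18, 22, 25, 29, 32, 36, 39, 43); the schedule
is a design field, not a constant. Proportional Gaussian noise can go
non-positive at high $\sigma$; draws are resampled until positive rather
than clipped (keeping values log-safe), and the resample count is
recorded — at $\sigma \le 0.2$ the induced bias is negligible, and the
count is 0 in the default conditions.

`simulate_calibration_plate()` mirrors the in vitro dilution series: five
log-spaced densities from $10^2$ to $10^6$ cells/well. Because the
through-origin estimator weights wells by $x^2$, the top density carries
~99 % of the weight and the slope's relative SE is essentially
$\text{noise}/\sqrt{\text{replicates}}$. The default of 16 replicate
wells per density (two 96-well rows) makes a 3 % slope error a
2.4-SE event, which is the precision this calibration is expected to
deliver; triplicate plates would leave the slope ~3× noisier.

What the generator does **not** emulate: 2D/3D image formation and
tomographic reconstruction error (signals are taken as given),
multi-site metastatic signals, inter-occasion variability, correlated
$a$–$K$ random effects, informative dropout (censoring exists via
`inject_dropout()`, but the default cohorts are complete), and model
misspecification — the data really are logistic/necrotic. Passing
recovery tests therefore demonstrates that the estimation machinery is
correct and well-calibrated under the assumed data-generating process,
not that the model is right for any particular real tumor line.

## Problem sizes and limitations

The test suite and the acceptance script run cohorts of 20 animals × 12
visits with the default SAEM schedule (a fit takes a few seconds), 5-seed
replication for the stochastic recovery checks, and reduced schedules
(120 + 80) for unit tests of the machinery; these sizes were chosen to
match the study design while keeping a full run in well under a minute
per fit.

Known limitations: variance components at $n = 20$ are weakly identified
(the recovery band for CVs is a factor of two, by design, and that is
honest); the sequential $\lambda$ stage conditions on point estimates of
individual kinetics and therefore slightly understates $\lambda$'s
uncertainty; the RSE of $\lambda$ in joint mode is not currently
computed; and no covariate or treatment-effect modeling is provided —
the package deliberately stops at the two-compartment natural-growth
model and its calibration.
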