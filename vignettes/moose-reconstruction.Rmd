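---
title: "Methods: chi-square population reconstruction for Minnesota moose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chi-square population reconstruction for Minnesota moose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model behind `moosespr`, the choices made
where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real data.

## The data and what they can identify

Two data streams cover northeastern Minnesota's moose population over
the sixteen winters 2005–2020:

* **Aerial survey class counts** (`moose_survey()`): per winter, the
  estimated number of calves, adult females and adult males, derived
  from sightability-corrected totals and observed class ratios. These
  are treated as point counts; their design-based variances are not
  used (the objective is pure Pearson chi-square, whose denominators
  are the expected counts themselves).
* **Telemetry mortality counts** (`moose_telemetry()`): per year and
  study, the number of collared adults at risk at the start of the
  year (`n`) and how many died during it (`v`). Four studies
  contribute; they are pooled within year (`pool_telemetry()`) because
  the mortality objective consumes only annual totals. 2008 and 2009
  have no telemetry in any study and are kept as explicit no-data
  years — the reconstruction still estimates survival there, from the
  survey alone.

The survey fixes the scale of the population; the telemetry anchors
the survival rates. A year with neither observation (the imputation
use case, e.g. a pandemic-cancelled survey) simply contributes nothing
to the objective and is reconstructed from the recursion.

## Model

Cohorts enter as winter calves and thereafter lose members to annual
mortality. With `S_i` the annual adult survival out of winter `i`
(shared by sexes — the contributing studies found no sex difference —
but free across years), and a fixed 0.5 sex ratio at birth, adult
cells follow the invariance recursion implemented in
`project_adults()`/`build_expected()`. Free parameters are the `Y−1`
survivals, the three year-1 cohorts and the `Y−1` later calf cohorts:
`K = 33` for `Y = 16`. Calf survival to age one is not separately
identifiable from these data; it is absorbed into the recruitment
parameters, which is why "recruitment" here means *calves alive in
winter*, not births.

Harvest is not modelled: tribal subsistence harvest in the study area
averages a few tens of animals per year, well inside the noise of the
survey counts.

### Objective

`joint_objective()` sums Pearson cell contributions over *all*
observed survey cells, including year 1 and the calf column. Whether
to include those cells was an open choice — they carry their own free
parameters, so at a perfect fit they contribute zero — but including
them anchors each parameter directly to its observed cell and keeps
the goodness-of-fit statistic interpretable over the full matrix.
`telemetry_objective()` adds the mortality terms for years with
collar data. Missing cells contribute zero, exactly.

### Optimization

Any bounded minimizer reaching the minimum is acceptable; the package
uses L-BFGS-B on a transformed scale — a generalized logit mapping
survival onto [0.01, 0.999] and logs for abundances on [1, 50,000] —
so bounds are simple and gradients well scaled. The bounds keep both
chi-square denominators strictly positive; they are never active at
the study optimum. The deterministic start takes survival from pooled
telemetry (`1 − v/n`, 0.85 where unmonitored) and abundances from the
survey cells; ten further starts jitter that point log-normally
(σ = 0.2) under a fixed seed and the best objective wins. In practice
every start reaches the same minimum, which also beats an exhaustive
coarse grid on a small instance (see the tests). Convergence is
declared on the optimizer's own criterion or a projected-gradient norm
below 1e−3 on the transformed scale; the gradient is checked by
central differences so the norm is honest at a near-exact optimum.
The Pearson denominator is additionally floored at 1e−8 inside
`cell_chisq()` as a pure numeric guard.

## Uncertainty

Standard errors come from the inverse of the Hessian of **half** the
total objective, taken with respect to the *natural* parameters at the
optimum. Halving makes the chi-square behave like −2·log-likelihood,
so for a cell depending on a single parameter the SE has the
closed form `sqrt(a)` that the tests verify. Parameters pinned at a
bound are flagged and their SEs reported missing; a non-PD Hessian
falls back to a pseudo-inverse with a warning.

Reconstruction models understate uncertainty, so variances are scaled
by the goodness-of-fit factor `c = χ²_df/df`, computed over the survey
cells only, with `df = 3·16 − 33 = 15`. Two deliberate choices here:

* `c` multiplies **variances** (SEs scale by `√c`), the standard
  quasi-likelihood convention;
* `c` is **floored at 1** — deflating SEs when the model fits better
  than Poisson would contradict the factor's purpose as a guard. The
  floor engages only in near-perfect-fit scenarios; on the study data
  `c ≈ 54` (the survey's extra-Poisson noise is large), as stage 2 of
  the analysis computes.

Intervals for derived quantities — annual totals and per-capita
recruitment `R_i = N_{i+1,1}/N_{i,2}` — use the delta method through a
numerical Jacobian of the recursion, normal quantiles, and a floor at
zero. This recruitment definition (next winter's calves per current
adult female) is the one consistent with the series ending a year
before the abundance series, and with the survey's own calf:female
ratios.

## Sensitivity analysis

`sensitivity_search()` answers: how large a uniform relative change in
adult survival (or in recruitment) over 2009–2013 would have kept the
2013 total within 10% of 2009's? Increments are multiplicative,
accumulate linearly (`1 + k·0.001`; compounding `1.001^k` differs by
well under the reporting precision at these magnitudes), apply to all
window years at once with survival capped at 0.999, and the window is
**re-projected from the fitted 2009 state, never refit** — the question
concerns the estimates, not the data. The 10% criterion is one-sided
(`N_2013 ≥ 0.9·N_2009`); only the lower side can bind during a
decline.

## Forecasting and projection

The ten-year projection needs survival and recruitment beyond 2019.
`forecast_rates()` fits AR(1)-with-drift by least squares on the logit
(survival) or log (recruitment) scale — a deliberately simple,
transform-respecting model; the original analysis named only a
software package, not a model, so the 2030 abundance is a qualitative
rather than exact target. Degenerate fits (zero variance, |slope| ≥ 1)
fall back to a random walk with drift using the historical innovation
SD, which in particular reproduces a pure trend's drift exactly. For
an exactly constant history the innovation SD is zero and so are the
forecast SDs.

`stochastic_project()` draws each year's rates independently from the
h-step forecast distributions on the transformed scales (so survival
draws are always in (0,1) and recruitment positive), then applies the
same recursion as the reconstruction, with next-winter calves
`R_t × females_t`. Only this parameter (environmental) stochasticity
enters by default, matching the forecast framing; a `demographic`
flag adds binomial survival and Poisson births for synthetic studies.
The run is reproducible bit-for-bit under a fixed seed; envelopes are
empirical 5th/95th percentiles of 1,000 trajectories, and the annual
growth rate is each trajectory's geometric mean
`(N_end/N_start)^(1/horizon)`.

## Synthetic data: what it shows and what it cannot

`decline_scenario()` defines a 16-year truth shaped like the study
system — about 8,150 animals initially, survival sliding from 0.90 to
0.72 mid-series before partly recovering, recruitment falling in
parallel, a >50% drop across the middle four years. `generate_dataset()`
observes it through per-cell log-normal survey noise with a chosen CV
and binomial collar deaths on design at-risk counts. Defaults — CV
10%, 50 collared adults per year — reflect the rough precision of the
real survey and the pooled collar sample sizes.

Log-normal cell noise is a simplification: the real survey's error is
design-based (stratified sampling plus a sightability model) and
correlated across classes within a year through the shared total. The
generator therefore validates the *estimator* — parameter recovery
(median survival error < 0.05 at the default conditions, over 100
replicates in the tests), interval coverage (≥ 85% for yearly totals
with inflated 90% CIs), consistency as noise vanishes — not the survey
design. Coverage on real data additionally depends on the sightability
model being right, which this package takes on faith.

## Problem sizes and runtime choices

The tests run the full 16-year fit with the default ten restarts once
(seconds), a 100-replicate recovery study at the default synthetic
conditions with single-start fits (the deterministic start reaches the
optimum in this well-conditioned setting), and 1,000-simulation
projections, cross-checked against a 4,000-simulation run for
Monte-Carlo stability of the medians to 2%. Analysis stage 5 uses 50
replicates for its reported recovery table. These sizes were chosen so
the whole study re-runs comfortably on a laptop while keeping
Monte-Carlo error well inside the tolerances being asserted.

## Known limitations

* Sex-specific survival, age structure beyond calf/adult, and harvest
  are not modelled; survival is a single annual rate per year.
* The count-based survival series (`annual_survival()`) ignores
  within-year censoring, so it can differ by ~0.01 from Kaplan-Meier
  values computed from animal-level records (it agrees exactly where
  no censoring occurred mid-year). The reconstruction itself consumes
  only the (v, n) counts, so it is unaffected.
* Normal delta-method intervals can be noticeably symmetric where the
  sampling distribution of a total is skewed; profile or bootstrap
  intervals are out of scope.
* The AR(1) forecast is a modelling convenience; long-horizon
  projections inherit its mean-reversion assumption, and the 2030
  envelope should be read as scenario spread, not calibrated
  prediction.
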