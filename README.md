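# moosespr

Statistical population reconstruction of moose (*Alces alces*) in
northeastern Minnesota, 2005–2020, by integrated population modelling:
winter aerial-survey class counts and telemetry mortality counts from
four collaring studies are combined in a single minimum chi-square fit
that yields annual abundance, calf recruitment and adult survival —
with honest (inflated) uncertainty — plus a sensitivity analysis of the
2009–2013 decline and a stochastic ten-year projection.

The package is aimed at wildlife biologists and population modellers
who have (a) class-structured survey counts and (b) annual
death/at-risk counts from collared animals, and want a reconstruction
of the population's trajectory that is more precise than either data
stream alone.

## The model

The population is tracked in `A = 3` winter classes — calves, adult
females, adult males — over `Y = 16` consecutive years, with abundances
`N_ij` (year `i`, class `j`). Free parameters are:

- annual adult survival `S_i`, `i = 1…Y−1` (shared by sexes, varying by
  year),
- the year-1 cohorts `N_11, N_12, N_13`,
- the calf cohort entering each later winter, `N_21 … N_Y1`
  ("annual recruitment"),

for `K = 2(Y−1) + 3 = 33` parameters. Every other adult cell follows
deterministically from the invariance recursion (0.5 is the sex ratio
at birth):

```
N_i2 = (N_{i−1,1} · 0.5 + N_{i−1,2}) · S_{i−1}
N_i3 = (N_{i−1,1} · 0.5 + N_{i−1,3}) · S_{i−1}
```

The fit minimizes a joint chi-square objective,

```
Λ_Joint      = Σ_i Σ_j (a_ij − N_ij)² / N_ij          (survey cells)
Λ_Telemetry  = Σ_i (v_i − n_i(1−S_i))² / (n_i(1−S_i)) (collar deaths)
```

where `a_ij` are the observed survey counts and `v_i` of `n_i` collared
adults died in year `i`. Standard errors come from the inverse Hessian
of half the objective at the optimum, inflated by the goodness-of-fit
scale `c = χ²_df / df` with `df = A·Y − K = 15`; delta-method intervals
are derived for annual totals and for per-capita recruitment
`R_i = N_{i+1,1} / N_{i,2}` (calves next winter per adult female).

## Worked example

```r
library(moosespr)

fit <- fit_reconstruction(moose_survey(), pool_telemetry(moose_telemetry()))
fit$total[c("2005", "2009", "2013", "2020")]
#>     2005     2009     2013     2020
#> 8305.621 7840.602 3370.991 3162.790

round(fit$theta$survival[c("2005", "2019")], 3)
#>  2005  2019
#> 0.902 0.689

r <- per_capita_recruitment(fit)
round(r$recruitment[r$year %in% c(2005, 2019)], 3)
#> [1] 0.360 0.301
```

The reconstruction confirms the sharp decline — roughly 7,841 moose in
2009 to 3,371 in 2013 — followed by a plateau near 3,200, and attributes
it mainly to adult survival, which bottoms out at 0.689 in 2019 while
per-capita recruitment drifts from 0.360 to 0.301 calves per adult
female. Uncertainty and the two follow-up analyses:

```r
report <- inflate(hessian_se(fit), fit)        # df = 15, c = 54.4
ci <- derived_ci(fit, report, alpha = 0.10)    # 90% intervals

sensitivity_search(fit, c(2009, 2013), 0.9, "survival")$percent_change
#> [1] 27.2   # +27.2% survival would have held 2013 within 10% of 2009
sensitivity_search(fit, c(2009, 2013), 0.9, "recruitment")$percent_change
#> [1] 250.8  # recruitment would have had to rise 3.5-fold
```

The numbered drivers under `analysis/` run the full study —
`01_reconstruct.R`, `02_uncertainty.R`, `03_sensitivity.R`,
`04_project.R` (AR(1) rate forecasts + 1,000-simulation projection to
2030), `05_simulation_study.R` (synthetic-data recovery check) — each
writing its tables under `results/`.

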