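# cureplateau

Prognostic analysis of immunohistochemistry (IHC) biomarkers in Hodgkin
lymphoma, built around a cure-fraction survival model. The package is
for biostatisticians and translational researchers who have a cohort
table (follow-up times, event indicators, raw IHC readings per marker)
and want to ask: *does a biomarker — or a combination of biomarkers —
split the cohort into subpopulations with different long-term survival?*

The core model is an exponential decay to a plateau fitted to the
Kaplan–Meier estimate:

    S(t) = P + (S0 − P) · exp(−k·t)

where `S0` is survival at time zero (1 by default), `P` is the
**plateau** — the cure fraction, the asymptotic probability of never
experiencing the event — and `k` is the event rate among the non-cured,
reported as the half-life `t½ = ln 2 / k` in months. Stratification is
judged by comparing a **null** model (one curve describes everyone)
against a **stratified** model (one curve per marker-defined group)
using ΔAIC = AIC(null) − AIC(stratified), the evidence ratio
`ER = exp(|ΔAIC|/2)`, and the extra-sum-of-squares F test; a
censored-data maximum-likelihood route (`fit_config(loss = "mle")`) is
provided for calibrated inference. Around the core sit:

* semi-quantitative IHC scoring: the multiplicative immunoreactive
  score for SATB1 (intensity 0–3 × percent-positive 1–3, positive if
  the product exceeds 1) and the four-tier percent-positivity score for
  p16 (positive at ≥ 10% stained HRS cells);
* marker cross-classification with small-group merging
  (`assign_groups()`), pairwise shared-dynamics tests, and
  plateau-vs-no-plateau support tests;
* a seeded synthetic-cohort generator (`simulate_cohort()`) that is the
  exact inverse of the plateau model, used for all testing;
* single-sample gene-set enrichment with rank normalisation
  (`ssgsea_score()`) and reduced major axis regression
  (`rma_regression()`) for correlating signature scores with a
  transcript.

All user-facing functions take data frames and return tibbles; fitted
objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a cohort with the structure of an 86-patient retrospective
series (joint marker split 12/8/4/62, cure-fraction survival, uniform
1–197-month censoring), score its raw IHC fields, and run the full
pipeline:

```r
library(cureplateau)

sc     <- simulate_cohort(cohort_spec(), seed = 7)
report <- run_pipeline(sc$records, sc$measurements, seed = 7)
report
#> Prognostic analysis report (n = 86)
#>   follow-up: median 65.3 mo, range 0.8-196.8
#>   satb1_OS     dAIC =    60.74  ER > 100  p = 4.16e-12
#>   satb1_PFS    dAIC =    72.69  ER > 100  p = 4.4e-15
#>   p16_OS       dAIC =    72.34  ER > 100  p = 3.8e-14
#>   p16_PFS      dAIC =    79.14  ER > 100  p = 2.74e-16
#>   combined OS  dAIC =    61.61  ER > 100  p = 8.81e-11  (3 groups)
#>   combined PFS dAIC =    76.03  ER > 100  p = 3.11e-14  (3 groups)
```

Each line is one null-vs-stratified comparison: a positive ΔAIC with
"ER > 100" means the stratified model is over 100 times more likely
than a single shared curve for that endpoint. The combined analysis
merged the two small p16-positive joint groups into one p16+ group
(three groups total). Per-group estimates, here under the calibrated
likelihood route:

```r
g   <- assign_groups(sc$records, c("satb1", "p16"), min_group_size = 10)
cmp <- compare_stratification(sc$records, "OS", g, fit_config(loss = "mle"))
tidy(cmp)[, c("group", "n", "plateau", "half_life")]
#>         group  n plateau half_life
#> 1        p16+ 13   0.692     0.874
#> 2 SATB1-/p16- 60   0.277   153.236
#> 3 SATB1+/p16- 13   0.920     6.488
```

Read: the SATB1+/p16− group is estimated to have a 92% cure fraction
with events (among the non-cured) on a 6.5-month half-life, while the
double-negative group plateaus much lower — the same qualitative
structure the generator planted (true plateaus 0.75 / 0.60 / 0.907).
`autoplot(cmp)` overlays the per-group Kaplan–Meier steps with the
fitted plateau curves; `write_report(report, "out/")` serialises the
bundle as JSON/CSV/SVG.

The methods vignette (`vignettes/cure-plateau-modelling.Rmd`) documents
the model, the fitting surface, the calibration properties of the
least-squares versus likelihood routes, and the generator's scope.

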