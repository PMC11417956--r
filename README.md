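# ctxgrowth

Urinary C-telopeptide of type I collagen (CTX-I) is a degradation product
of bone resorption that can be measured non-invasively in urine, making it
a candidate marker for skeletal growth in populations where repeated
capture is impossible — zoo-housed and wild primates in particular.
`ctxgrowth` implements the full validation analysis for such a marker as a
tested R pipeline:

* **Synthetic cohort generation** — a configurable generator for
  bonobo-like longitudinal data: sex-specific forearm growth-velocity and
  CTX-I age curves, a diurnal (within-day) log-linear decline, ~25%
  day-to-day variability with skew-normal residuals, specific-gravity (SG)
  dilution, and site effects. Every downstream stage is testable against
  known generator truth.
* **Preprocessing** — SG correction
  (`ctx_raw * (sg_ref - 1) / (sg_sample - 1)`), the SG < 1.003 quality
  filter, forearm growth velocity (cm/day) anchored at midpoint "velocity
  dates", positivity enforcement before the log transform, and mean /
  two-SD standardization of predictors with the age gradient pooled across
  both datasets.
* **Descriptives** — per-individual summaries (n, mean, median, SD, SE,
  range, CV%) of SG-corrected concentrations and the cohort mean
  day-to-day coefficient of variation.
* **Hierarchical Bayesian regression** — for each outcome
  (log velocity, log CTX-I), a skew-normal likelihood
  (mean-parametrized `mu`, scale `sigma`, shape `alpha`), a nine-coefficient
  constrained cubic B-spline age smooth with per-spline sex deviations, a
  standardized sex effect, a standardized time-of-day covariate (CTX-I
  model), and random intercepts/age-slopes for individuals plus a site
  intercept — fitted by the package's own No-U-Turn sampler (Rcpp;
  analytic gradients, dual-averaging step size, diagonal mass adaptation),
  with Gelman-Rubin diagnostics, effective sample sizes and posterior
  predictive checks.
* **Comparison** — per-sex estimate tables for the nine age windows, the
  additive male derivation (male = female + difference, cell by cell, with
  a principled posterior-sum alternative), and sex-wise Spearman
  correlations between velocity and CTX-I spline estimates with exact
  permutation p-values for n ≤ 9.

The headline statistic is the per-sex rank correlation of the nine
age-window spline estimates between the two models: high in females
(r(7) = 0.83 on the packaged reference table), absent in males.

## Worked example

```r
library(ctxgrowth)

cfg  <- cohort_config(seed = 7, coupling = 1)   # female CTX-I tied to growth
sim  <- simulate_cohort(cfg)
prep <- prepare_model_data(sim$urine, sim$forearm, sim$individuals)
prep$log
#> urine retained: 192   SG-excluded: 6   velocities: 292   clamped: 9

spec <- sn_model_spec("log_ctx", chains = 2, iter = 1500, warmup = 500,
                      adapt_delta = 0.9, seed = 22)   # reduced desk settings
fit  <- fit_sn_spline(assemble_design(prep$urine, spec))
fit
#> Skew-normal spline model fit (log_ctx)
#>   2 chains x 1500 iterations (500 warmup), 133 parameters
#>   max R-hat 1.007, min ESS 340, divergences 0/0, runtime 11.5s

diurnal_effect(fit)
#> diurnal time effect: -0.37 (SE = 0.04, lCI = -0.45, uCI = -0.29)
```

The diurnal coefficient is the change in log CTX-I per two standard
deviations of collection time; its negative interval recovers the
generator's built-in within-day decline (expected 18:00 level 55% of the
07:00 level). The packaged reference estimate table reproduces the
headline correlations directly:

```r
compare_tables(ctx_fixture("table2_printed.csv"))
#> $female : Spearman rank correlation: r(7) = 0.83, p = 0.00827 (exact permutation)
#> $male   : Spearman rank correlation: r(7) = 0.20, p = 0.604 (t approximation, midranks for ties)
```

`run_ctx_pipeline()` chains all stages (descriptives, both model fits,
estimate tables, correlations, diurnal effect) and writes `table1.csv`,
`table2.csv`, `table3.csv`, `correlations.json` and a run report with
exclusion counts, clamp counts, seeds and convergence summaries. The
publication-scale sampler defaults (5 chains x 10,000 iterations,
`adapt_delta = 0.99`) are kept for real analyses; pass reduced specs as
above for desk runs.

## Layout

* `R/` — generator (`cohort.R`), preprocessing, descriptives, spline
  basis, model/sampler interface, inference tables and correlations,
  pipeline orchestration.
* `src/` — skew-normal hierarchical log posterior with analytic gradient,
  the NUTS implementation, and the exact Spearman permutation enumerator.
* `inst/extdata/` — reference tables used by the worked examples.
* `vignettes/ctxgrowth-methods.Rmd` — the model, priors, sampler,
  generator design and numerical choices in detail.
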