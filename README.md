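# uhrisk

Early risk modelling of **uncomplicated hypertension (UH) in pregnancy** —
gestational hypertension or worsening of essential hypertension beyond the
20th gestational week — from first-trimester measurements: 24-h ambulatory
blood-pressure (ABPM) indices, serum uric acid (UA), and the angiogenic
imbalance ratio sFlt-1/PlGF (the "AF ratio").

The package is aimed at biostatisticians and clinical researchers who want a
tested, reproducible implementation of this modelling pipeline, and a
synthetic-cohort simulator to study its behaviour when the original patient
data are not available.

## What it implements

1. **Synthetic cohort generator** (`cohort_config()`, `generate_cohort()`):
   132-pregnancy cohorts (configurable) with Table-1-style marginals
   (Gaussian copula over normal/lognormal marginals back-solved from
   median/IQR), logically consistent binary covariates, and a logistic
   outcome mechanism that rises with nighttime systolic pressure and depends
   on a genuine degree-2 surface in the standardized log biomarkers — so the
   whole pipeline has ground truth to recover.
2. **Descriptive machinery** (`describe_cohort()`, `mann_whitney()`,
   `chi_squared_or_fisher()`, `dipping()`): median (IQR) and count (%) group
   comparisons, Mann–Whitney U (exact enumeration at small n), Pearson
   chi-squared without continuity correction with a Fisher fallback when an
   expected cell drops below 5, and nocturnal dipping
   `100 × (day − night) / day`.
3. **The combined biomarker index** (`cv_degree_sweep()`, `select_degree()`,
   `build_index()`, `evaluate_index()`): a polynomial-logit combination of
   UA and the AF ratio. Candidate degrees 1–5 are compared by stratified
   fivefold cross-validation; the selected model's **out-of-fold logits**
   (each subject scored by the fold model that excluded them) become a new
   leakage-free predictor, while the full-data equation

   `index = b0 + b1·UA + b2·AF + b3·UA² + b4·UA·AF + b5·AF²`

   (inputs log-transformed and standardized by default) is kept for scoring
   new subjects.
4. **Multivariate logistic risk models** (`fit_logistic()`,
   `screen_confounders()`, `screen_interactions()`, `omnibus_lrt()`,
   `hosmer_lemeshow()`, `nagelkerke_r2()`, `roc_auc()`): Wald tables with
   `Exp(B) = e^B` and 95% CI `e^{B ± 1.96·SE}`, the 10% odds-ratio-change
   confounder rule, omnibus LRT, Hosmer–Lemeshow calibration (g − 2 df),
   Nagelkerke R², and ROC/AUC with the Hanley–McNeil standard error.
5. **Bayesian accuracy comparison** (`posterior_from_accuracy()`,
   `compare_accuracy()`, `credible_interval()`): Beta(1,1) prior, conjugate
   Beta-Binomial update `Beta(1 + k, 1 + n − k)`, 100,000 posterior draws to
   estimate `P(θ₁ > θ₀)` and the 95% credible interval of `θ₁ − θ₀`.
6. **Orchestration** (`uh_pipeline_config()`, `run_uh_pipeline()`): the full
   generate → describe → index → fit → compare run, writing a deterministic
   CSV/JSON report bundle with a seed manifest.

Fitted objects are tidyverse-friendly: `tidy()`, `glance()` and `autoplot()`
methods are provided throughout.

## Worked example

```r
library(uhrisk)

cohort <- generate_cohort(cohort_config(n_subjects = 132, seed = 42))

metrics <- cv_degree_sweep(cohort, k = 5, seed = 42)
select_degree(metrics)
#> [1] 2

index <- build_index(cohort, degree = 2, k = 5, seed = 42)
cohort$uaaf_index <- index$oof$oof_logit

fit <- fit_logistic(cohort, "uh", c("sbp_night", "uaaf_index"))
fit
#> Logistic risk model: uh ~ sbp_night + uaaf_index  (n = 132)
#> # A tibble: 3 × 8
#>   term        estimate std_error  wald    p_value odds_ratio   ci_lower ci_upper
#>   <chr>          <dbl>     <dbl> <dbl>      <dbl>      <dbl>      <dbl>    <dbl>
#> 1 (Intercept)  -11.1      2.86    15.2 0.0000970   0.0000144    5.30e-8  0.00392
#> 2 sbp_night      0.102    0.0259  15.5 0.0000820   1.11         1.05e+0  1.17
#> 3 uaaf_index     1.07     0.228   22.1 0.00000256  2.92         1.87e+0  4.57
#> Nagelkerke R2 0.506; accuracy 0.803 at threshold 0.5

roc_auc(fit$fitted, fit$y)
#> ROC: AUC 0.850, SE 0.033, 95%CI 0.785-0.915, p < 0.001 (n+ = 73, n- = 59)
```

Each mmHg of nighttime systolic pressure multiplies the odds of UH by ~1.11,
and each unit of the biomarker index multiplies them by ~2.9; the
cross-validated degree sweep picks the quadratic transformation, and the
combined model discriminates cases with AUC 0.85 on this simulated cohort.

Comparing two models' published accuracies (0.83 vs 0.69 on n = 132):

```r
compare_accuracy(posterior_from_accuracy(0.83, 132),
                 posterior_from_accuracy(0.69, 132), seed = 1)
#> P(theta1 > theta0) = 0.997  [k +/- 1 sensitivity: 0.995-0.998]
#> model 1: Beta(111, 23), 95% CI [0.760, 0.887]
#> model 0: Beta(92, 42), 95% CI [0.606, 0.762]
#> difference: 95% CI [0.040, 0.243]
```

The full pipeline, as one deterministic run writing a report bundle:

```r
run_uh_pipeline(uh_pipeline_config(seed = 5), "run1")
```

## Documentation

The methods vignette (`vignettes/uhrisk-methods.Rmd`) describes the
statistical model, the synthetic-data mechanism and its limitations, all
tunable parameters with defaults, and the numerical design choices.
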