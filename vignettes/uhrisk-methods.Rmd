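---
title: "Methods: risk modelling of uncomplicated hypertension in pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk modelling of uncomplicated hypertension in pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhrisk)
```

## The problem and the model

Uncomplicated hypertension (UH) in pregnancy — gestational hypertension or
worsening of essential hypertension beyond the 20th gestational week, defined
by office blood pressure ≥ 140 and/or ≥ 90 mmHg — is common and worsens
maternal and fetal prognosis, yet no single first-trimester biomarker
predicts it well. The modelling strategy implemented here combines three
information sources measured early in pregnancy:

* **ambulatory blood-pressure (ABPM) indices**, especially nighttime systolic
  and diastolic averages (nSBP, nDBP, mmHg);
* **serum uric acid** (UA, mg/dL), a marker of oxidative stress and impaired
  renal clearance;
* the **sFlt-1/PlGF ratio** (the "AF ratio"), indexing anti-angiogenic
  imbalance.

Neither UA nor the AF ratio shows a usable first-order association with UH,
so the two are combined nonlinearly. A logistic model is fitted to a
bivariate polynomial expansion of the (transformed) biomarkers, the degree
is chosen by cross-validation, and each subject's **out-of-fold logit** —
the linear predictor from the fold model that never saw that subject —
becomes a new scalar predictor, the combined biomarker index. Risk models
are then binary logistic regressions

$$\operatorname{logit} P(\text{UH}) = \beta_0 + \beta_1\,\text{BP index} +
\beta_2\,\text{index} + \boldsymbol\gamma^\top \mathbf{z},$$

with confounders $\mathbf{z}$ screened by the 10% odds-ratio-change rule and
interactions by Wald significance. Competing models are compared on their
classification accuracies with a Beta-Binomial Bayesian analysis rather than
p-values.

Assumptions worth stating: the risk models assume independent subjects, a
correctly specified linear logit in the chosen predictors, and complete
data; the index construction assumes the biomarker–outcome relation is
smooth enough for a low-degree polynomial; the Bayesian comparison treats
the two accuracies as independent binomials (predictions on the same
subjects are in fact correlated — the comparison is interpretable as a
marginal statement, not a paired one).

## The synthetic cohort generator

Real patient data for this problem are not publicly deposited, so the
package ships a first-class simulator. Its defaults define the study
conditions used throughout the tests.

**Continuous marginals.** Each variable is assigned a median and IQR on its
clinical units (see `default_marginals()`); age, BMI, heart rate and all BP
indices are truncated normals (`sd = IQR/1.349`), while uric acid, sFlt-1
and PlGF are lognormal (`sdlog = asinh(IQR/(2·median))/z_{0.75}`), because
their IQRs are of the order of their medians (heavy right skew). Office BP,
biochemistry and demographic defaults follow the published cohort summaries
(n = 132, 72 cases; e.g. office SBP 134.5 (12.8) mmHg, UA 4.1 (1.38) mg/dL,
sFlt-1 1908 (2683) U/L). The ambulatory indices have no published marginal
table, so their defaults are package choices plausible for a
moderate-cardiovascular-risk pregnant cohort: daytime SBP 126, nighttime SBP
111 mmHg (≈ 12% dipping), daytime DBP 79, nighttime DBP 66 mmHg.

**Dependence.** A Gaussian copula correlates the latent scores
(`default_correlation()`): ambulatory indices cohere strongly (24-h vs
daytime r = 0.9), office and ambulatory moderately (r = 0.6),
systolic–diastolic coupling 0.45–0.65, and weak metabolic links (e.g.
BMI–BP 0.15–0.2, sFlt-1–PlGF 0.3). No correlation structure is published;
these are configurable defaults. The stylized targets are projected to the
nearest positive-definite correlation matrix, which moves entries by a few
hundredths at most.

One structural consequence: with lognormal marginals and a Gaussian copula
the median of the ratio sFlt-1/PlGF equals the ratio of medians (≈ 8.9),
which is above the published ratio median of 7.0 — the three printed medians
are not jointly attainable in this family. The generator prioritizes the
sFlt-1 and PlGF marginals.

**Binary covariates** use the published prevalences; antihypertensive
treatment is drawn only among women with essential hypertension (22/55),
so treatment implies hypertension.

**Outcome mechanism.** With $z_u, z_a$ the standardized *log* uric acid and
log AF ratio (population moments implied by the config, see
`biomarker_scores()`),

$$\operatorname{logit} P(\text{UH}) = \beta_0 + 0.098\,(\text{nSBP} - 111)
 - 0.9713\,z_u^2 + 1.4606\,z_u z_a - 0.3904\,z_a^2.$$

The quadratic coefficients are the second-order terms of the package's
reference index equation and the nSBP slope is the headline per-mmHg
effect, so a correctly specified recovery model is degree 2 — making degree
selection and parameter recovery testable. The linear terms default to zero:
with them, the first-order marginal association of UA with the outcome
becomes clearly detectable at n = 132, contradicting the weak univariate
associations the cohort is meant to emulate (published p ≈ 0.46/0.54). The
surface acts on the log scale because the raw ratio is extremely skewed
(implied log-SD ≈ 1.07); raw-scale squares would be dominated by a handful
of outliers. $\beta_0$ is calibrated by root-finding so the mean event
probability over the realized covariates equals the configured prevalence
(72/132), which keeps the empirical prevalence unbiased at any sample size.
A post-hoc nighttime shift for cases exists (`night_shift_sbp`, default 0
mmHg); it is off by default so the outcome model stays exactly as written —
the nSBP pathway already produces the reduced dipping seen in cases.

**What the simulator does not emulate:** longitudinal BP trajectories,
gestational-age effects, measurement error and device differences,
informative referral (the real cohort is moderate-to-high risk by
inclusion), missing data, and progression to severe disease. Tests passing
on this generator therefore certify the *machinery* — not clinical validity
on real cohorts.

## The combined biomarker index

* **Transform** (`log_transform = TRUE`, `standardize = TRUE`): inputs are
  log-transformed and standardized to zero mean and unit variance, with the
  location/scale estimated on each training fold only (and on the full data
  for the final equation). The original report does not state its
  preprocessing; the printed equation's coefficient magnitudes (all O(1),
  mixed signs) are implausible on raw units, implying some scaling. Both
  knobs are exposed.
* **Expansion**: all monomials $z_u^i z_a^j$ with $0 < i + j \le d$, ordered
  by total degree then decreasing $i$ — for $d = 2$: `ua, af, ua2, ua_af,
  af2`, matching the reference equation's term order. Term count is
  $(d+1)(d+2)/2 - 1$.
* **Fit**: ridge-penalized logistic regression (glmnet, `alpha = 0`,
  unstandardized design) with `lambda = 1/n_train` by default — the mild L2
  strength equivalent to a common-default regularized logistic fit, the most
  plausible provenance of the published equation; `lambda = 0` requests the
  unpenalized ML fit.
* **Folds**: stratified k-fold (default k = 5) with assignment keyed by a
  32-bit FNV-1a hash of (subject id, seed) — fold membership is independent
  of row order, class proportions are preserved within one subject per fold,
  and the same seed always yields the same folds.
* **Metrics**: per-degree across-fold means of train/test accuracy
  (threshold 0.5 on probability), AUC and log loss. If every test fold is
  single-class (e.g. leave-one-out), the test AUC is computed on the pooled
  out-of-fold predictions instead.
* **Degree selection** (`select_degree()`): among degrees whose
  train-minus-test accuracy gap is at most `gap_threshold` (default 0.05),
  the lowest degree within `accuracy_tol` (default 0.04) of that subset's
  best test accuracy; ties break low; if nothing passes the gap rule the
  band is applied to all degrees. The 0.04 band is a one-SE-style parsimony
  rule: the standard error of a fivefold mean accuracy at n ≈ 130 is about
  0.04, so differences inside the band are noise. A narrower band makes
  selection oscillate between adjacent degrees on cohorts of this size.

## Risk-model conventions

* Maximum likelihood via iteratively reweighted least squares
  (`glm`, gradient tolerance 1e-8, up to 100 iterations); standard errors
  from the inverse observed information.
* Wald statistic $(B/SE)^2$ with a 1-df chi-squared p-value; odds-ratio CIs
  use $z = 1.96$ exactly (the convention that reconstructs the published
  tables); profile-likelihood intervals are out of scope.
* Reported accuracy is in-sample at threshold 0.5 — optimistically biased,
  and deliberately so, since it mirrors how the final models are reported in
  this literature; the bias is inherited by the Bayesian comparison.
* Rank-deficient designs error naming the collinear columns. Perfect or
  quasi-perfect separation is flagged as a distinct error when every fitted
  probability is numerically 0 or 1 (mean $\hat\mu(1-\hat\mu) < 10^{-8}$) —
  the IRLS iteration can "converge" silently in that state, so the flag does
  not rely on R's warnings.
* Hosmer–Lemeshow: subjects ranked by fitted probability into g = 10 groups
  (g is unstated in the original analysis; 10 is the universal default),
  remainder spread one-per-group from the start of the ranking, ties kept
  together, zero-expected groups merged with a warning, df = g − 2.
* ROC/AUC: trapezoidal integration over all thresholds on integer counts
  (exactly the tie-adjusted concordance probability); the AUC standard error
  uses Hanley–McNeil with $Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$, which
  reproduces the magnitude of the published SEs (0.032–0.044) at group
  sizes 60/72.
* Confounder rule: candidate retained iff
  $|OR_{adj} - OR_{crude}|/OR_{crude} \ge 0.10$; failed candidate fits are
  reported as `undetermined`.

## Bayesian accuracy comparison

Accuracies are given Beta(1,1) priors and updated with the observed number
of correct predictions: $k$ correct of $n$ gives Beta(1 + k, 1 + n − k).
When only a rounded accuracy is published, $k = \operatorname{round}(acc
\times n)$ (half away from zero); because that rounding could be off by one,
`compare_accuracy()` also reports the superiority probability recomputed by
quadrature with each count shifted ±1 (the band is < 0.01 wide for the
published cases). $P(\theta_1 > \theta_0)$ and the difference interval are
Monte-Carlo estimates from 100,000 seeded draws per posterior (MC standard
error ≤ 0.0016); the per-model accuracy intervals use exact Beta quantiles
since no sampling is needed there.

## Problem sizes used in the tests

The test suite certifies the statistical properties at sizes chosen to make
the checks sharp but quick: marginal fidelity and calibration at n = 5000;
logistic parameter recovery on 50 cohorts of n = 5000 (95% Wald coverage of
the generating nSBP effect); degree-2 recovery and the held-out AUC gain of
adding the index on 25 cohorts of n = 264 (two cohorts' worth — at n = 132
fivefold accuracy is noisy enough that the one-SE selection rule recovers
degree 2 only ~84% of the time, an honest property of the procedure at that
size, while the qualitative rise-then-overfit pattern of the metrics is
still verified on averaged n = 132 sweeps); Hosmer–Lemeshow type-I
calibration on 200 fitted models at n = 2000.

## Known limitations

* The generator cannot reproduce the published cohort's joint distribution —
  only stated marginals plus assumed dependence — so published AUC/accuracy
  values are recovered as qualitative patterns, not numbers.
* The published index equation cannot be exactly reproduced without knowing
  the original preprocessing and regularization; both are configurable, and
  the reference equation can be evaluated directly via `index_model()`.
* In-sample accuracy feeds the Bayesian comparison, so the comparison
  quantifies the difference of optimistic estimates.
* The Beta-Binomial comparison ignores the pairing of predictions across
  models on the same subjects.
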