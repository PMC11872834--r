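---
title: "Blood-marker biological age clocks: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-marker biological age clocks: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclock)
library(dplyr)
```

## The problem

Routine veterinary blood panels — complete blood counts and serum chemistry —
are collected at nearly every clinic visit, yet are usually interpreted one
analyte at a time against its reference interval. phenoclock implements a
composite alternative: a phenotypic ("biological") age trained on longitudinal
panels with survival outcomes. An animal whose panel profile looks like that
of a typically older animal receives a biological age above its chronological
age; the difference (AgeDev, in years) is a mortality risk score in its own
right.

## The model

All survival models in the package run on the age axis in *counting-process*
form. A blood draw at age $a_k$ opens a risk interval $(a_k, a_{k+1}]$ whose
covariates are the values measured at $a_k$; the event indicator sits at the
end of an animal's last interval. Animals enter the risk set at their first
draw (left truncation), and markers act as time-dependent covariates.

The clock itself is a pair of Gompertz proportional-hazards models sharing the
same training rows:

* the **full model** with hazard
  $h_1(t) = e^{xb}\, e^{\gamma t}$, where
  $xb = \beta_0 + \sum_m \mathrm{coef}_m \cdot \mathrm{value}_m
  + \beta_{breed}\,[\text{medium/large}] + \beta_{sex}\,[\text{male}]$;
* the **reference model** with demographics only:
  $h_2(t) = e^{\beta_0^{ref} + \beta_{breed}^{ref}[\cdot] +
  \beta_{sex}^{ref}[\cdot]}\, e^{\gamma_0 t}$.

Both are fitted by maximizing the counting-process likelihood
$\sum_i d_i \log h(t_{stop,i}) - [H(t_{stop,i}) - H(t_{start,i})]$
with $H(t) = e^{xb}(e^{\gamma t} - 1)/\gamma$
(quasi-Newton with analytic gradients, Newton-polished until the gradient
max-norm is below $10^{-6}$; $\gamma$ is kept positive through a log
parameterization, so its Wald interval is computed on the log scale and
exponentiated).

Biological age solves $S_{ref}(\mathrm{BioAge}) = S_{full}(\mathrm{age})$:

$$\mathrm{BioAge} \;=\; \frac{1}{\gamma_0}\,\log\!\left(1 +
\frac{\gamma_0\, e^{xb}\,(e^{\gamma\,\mathrm{age}} - 1)}
     {\gamma\, e^{ref\_lp}}\right),$$

where $ref\_lp$ is the reference model's linear predictor for the same breed
size and sex. Two properties anchor the implementation and are enforced by
tests: when the full model degenerates to the reference model, BioAge equals
chronological age identically; and the closed form agrees with numerically
inverting $S_{ref}$ to $10^{-8}$ years. The formula is evaluated in log space
(`log1p(exp(.))` with a linear branch for large arguments) so extreme linear
predictors cannot overflow.

A subtlety worth stating: the shape $\gamma_0$ that scales the outer
logarithm *must* be the reference model's shape, and the reference linear
predictor must include both breed size and sex. Any other pairing breaks the
identity BioAge = age in the degenerate case, which is how we fixed the
convention.

## The workflow around the clock

1. **Curation** (`preprocess_panel()`): natural-log transform of nine
   right-skewed analytes (ALP, ALT, AST, creatine kinase, bilirubin,
   creatinine, GGT, triglycerides, urea nitrogen); removal of rows outside
   the per-marker 1st–99th percentile (type-7 quantiles, ties kept, whole
   rows dropped so panels stay complete); completeness filtering. Order is
   fixed: log → trim → complete. Trimming happens after the log transform;
   because the log is monotone this changes nothing for the log-marker tails
   themselves, only the documentation of the cut values.
2. **Screening** (`screen_markers()`): per-marker Cox models on SD-1
   standardized values (unbiased n−1 variance, fitted on a reference set via
   `fit_scaling()` and *applied*, never re-fitted, elsewhere), adjusted for
   sex and breed size in dogs, with Efron tie handling and
   Benjamini–Hochberg step-up across the panel. Hazard-ratio profiles across
   species are compared by complete-linkage clustering of Euclidean
   distances on *log* hazard ratios (symmetric around zero), dropping
   markers missing in any species.
3. **Selection** (`lasso_cox_cv()`): L1-penalized Cox on the start-stop
   rows, folds assigned per animal so repeated measures never straddle a
   fold, demographics unpenalized, penalty chosen at the cross-validated
   deviance minimum (no 1-SE rule). Inputs are the transformed, unscaled
   markers with internal standardization for the penalty only, so selected
   coefficients are per native (or ln) unit.
4. **Training** (`train_clock()`) on the training split only; splits are by
   animal (`split_train_test()`, default 75/25).
5. **Evaluation**: hazard ratio per AgeDev year (`cox_agedev()`), quintile
   contrasts (`quintile_hr()`, observation-level cuts), a maximally selected
   log-rank cutpoint scan (`cutpoint_scan()`), incident/dynamic ROC
   (`incident_dynamic_roc()`), reference-range counts
   (`count_out_of_range()`), and diet-group comparison
   (`compare_diet_groups()`).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| trim percentiles `p_lo`, `p_hi` | 1, 99 | % | guard against acute illness / entry errors |
| train fraction `split` | 0.75 | — | standard hold-out at cohort sizes of ~10^3 |
| CV folds `k_folds` | 20 | — | low-variance deviance estimates on ~10^2 events |
| `nlambda`, `lambda.min.ratio` | 30, 0.05 | — | the near-unpenalized tail of the start-stop Cox path converges slowly and is always past the CV minimum; tighten `epsnr`/`mxitnr` when near-zero penalties must match an unpenalized fit |
| ROC window | (5, 10] | years | scores measured after age 5 predicting survival to age 10 |
| cutpoint grid | observed AgeDev between the 10th and 90th percentiles | years | the standard restriction for maximally selected statistics |
| loess span (diet curves) | 0.75 | — | smooth trajectory display; a generalized additive model would differ in detail |
| out-of-range bounds | closed | — | a value exactly on a reference bound counts as in range |

## The synthetic-data generator

No public cohort with longitudinal panels *and* survival exists for dogs, so
every quantitative claim in this package is made on synthetic cohorts with
known ground truth (`sim_truth()`, `simulate_cohort()`,
`simulate_cr_trial()`). The generator emulates:

* repeated draws on a fixed visit schedule (default yearly), with markers
  following an AR(1) process (stationary SD, lag-1 correlation ρ, default
  0.5) around a linear age trend — ln-flagged markers are simulated on the
  log scale and written out as `exp(value)`, so curation recovers exactly
  the scale the hazard acts on;
* a Gompertz event law whose log-hazard is linear in the markers, breed size
  and sex, with covariates held constant between visits — precisely the
  model the likelihood assumes, which is what makes unbiased parameter
  recovery a meaningful test;
* exponential "adoption" censoring plus administrative censoring at the
  follow-up limit.

The default truth (`default_sim_truth()`) uses the published ten per-unit
clock coefficients as the true hazard weights of ten canine-typical markers,
plus five null markers; γ = 0.25/yr, breed effect 0.4, sex effect 0.2; the
intercept is solved so a reference animal's median lifespan is ~11 years; the
adoption rate (0.15/yr) is calibrated so a 1000-animal cohort yields roughly
300 deaths, the event yield the recovery studies assume.

What the generator does **not** emulate: per-animal random frailty or marker
set-points, breed-specific marker distributions, nonlinear age trajectories,
measurement batch effects, informative censoring (adoption independent of
health), or visit schedules that react to illness. Passing tests therefore
demonstrate the *machinery* is correct and adequately powered under the
stated conditions — not that real cohorts satisfy those conditions.

## Numerical choices

* Likelihood and closed form evaluated in log space; `expm1`/`log1p` used
  throughout, so γ → 0 degrades gracefully to the exponential model.
* Gompertz MLE: BFGS with analytic gradients from several γ starts, then
  Newton polishing with step halving; convergence requires gradient
  max-norm < 10⁻⁶; linear dependence among covariates is detected up front
  and reported as a singular-information error.
* Cutpoint statistic: signed square root of the Cox score test with Breslow
  ties, which equals the two-group log-rank statistic on tie-free data.
* Incident/dynamic AUC: at each event age, cases are the failures and
  controls the remaining risk set; AUC(t) is score concordance with ties at
  0.5; the summary is the pair-count-weighted mean, so a constant score is
  exactly 0.5 and a perfectly separating score exactly 1.
* Degenerate inputs fail loudly and early: zero-variance markers in
  scaling, constant AgeDev in the hazard model, empty quintiles, candidate
  cutpoints outside the observed range, grids below the conditioning age.

## Worked example

```{r pipeline, eval = FALSE}
out <- run_pipeline(tempfile("clockrun"), n_animals = 1000, seed = 1,
                    k_folds = 20)
out$evaluation$hr_per_agedev_year
out$evaluation$pearson_r_bioage_age
autoplot(out$screen)
autoplot(out$selection)
```

Typical study sizes used by the package's own checks (chosen to keep each
study at desk scale while leaving Monte-Carlo error well below the margins
being tested): 1000 animals for parameter recovery (100 replicates), 800 for
selection-support recovery (25 replicates), 400 for cutpoint recovery
(50 replicates), and 48 (24 matched pairs) for the calorie-restriction power
study (50 replicates), mirroring the size of the landmark paired-feeding
dog trial.

## The published coefficient table

`dog_clock_coefficients()` ships the ten published per-unit coefficients
(e.g. −0.744 per g/dL serum albumin, +0.263 per ln U/L alkaline
phosphatase). The published intercepts and shapes for the two models live in
supplementary material we do not reproduce, so the bundle is deliberately
incomplete for scoring: either transcribe those constants or retrain with
`train_clock()` on your own cohort. The package's synthetic defaults embed
the same ten coefficients as ground truth, which keeps every simulated
magnitude (AgeDev spreads, hazard ratios near 1.7–1.8 per year) in a
realistic range.

## Design choices that were genuinely open

* **Fold unit**: folds and train/test splits are by animal, never by row —
  repeated measures leak otherwise.
* **Reference category**: small female; breed = 1 for medium/large, sex = 1
  for male. Coefficient signs are reported under this encoding.
* **Duplicate draws** at the same age keep the first; **draws at or after
  the end of follow-up** are discarded; both warn. An animal measured only
  on its death date contributes no risk interval and is excluded.
* **Screening vs training scale**: per-SD standardization is used only for
  the univariate screen (comparability across analytes); the clock is
  trained on native/ln units so its coefficients are per unit.
* **Stratification**: breed size enters the per-marker models as a
  covariate; stratified baselines are a plausible alternative we expose via
  the model formula rather than a default.
* **ROC input**: the fitted Cox linear predictor of the score (falling back
  to the raw score when the fit is degenerate); using the raw score instead
  changes nothing when the fitted coefficient is positive.
* **Small-cohort selection**: when cross-validation prefers the null model
  (plausible below ~100 events at these effect sizes), `run_pipeline()`
  warns and trains on the full candidate set rather than failing.

## Limitations

The clock assumes proportional hazards on the age axis and a log-linear
marker–hazard relationship; both are conventions inherited from the
phenotypic-age literature, not biological laws. Coefficients are
cohort-specific: a clock trained on one population (or species) should not
be scored on another without retraining — the package's species arguments
change covariate sets, not biology. Reference intervals bundled with the
package are editable defaults, not a clinical standard.
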