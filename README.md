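# phenoclock

Blood-panel biological age ("phenoage") clocks for companion animals, built
on longitudinal complete-blood-count and serum-chemistry panels with
survival outcomes. The package is aimed at veterinary clinical researchers
and biostatisticians who have repeated routine lab panels per animal and
want a single mortality-calibrated health score instead of 28 separate
reference-interval flags.

## The method

Longitudinal draws become counting-process records: a draw at age `a_k`
opens the risk interval `(a_k, a_{k+1}]` with covariates fixed at `a_k`,
animals enter the risk set at their first draw (left truncation), and the
death/censor flag sits on the last interval. On these rows the package:

1. screens each marker against all-cause mortality per +1 SD
   (Cox, sex + breed size adjusted, Benjamini–Hochberg across the panel);
2. selects a parsimonious marker set by LASSO-penalized Cox regression with
   animal-level cross-validation folds;
3. fits the clock: a **full** Gompertz proportional-hazards model
   `h1(t) = exp(xb) * exp(gamma * t)`,
   `xb = beta0 + sum(coef_m * value_m) + beta_breed*[medium/large] +
   beta_sex*[male]`, and a demographics-only **reference** model with shape
   `gamma0`, both by maximum likelihood on the counting-process data.

Biological age solves `S_ref(BioAge) = S_full(age)` in closed form:

```
BioAge = log(1 + gamma0 * exp(xb) * (exp(gamma*age) - 1) / (gamma * exp(ref_lp))) / gamma0
```

and `AgeDev = BioAge - age` (years above or below the cohort norm for the
animal's breed size and sex). AgeDev is then evaluated as a mortality
predictor: hazard ratio per year, quintile contrasts, a maximally selected
log-rank cutpoint scan, incident/dynamic time-dependent ROC, out-of-range
counts, and calorie-restriction group comparisons.

Because no public dog cohort couples longitudinal panels with survival, the
package ships a first-class synthetic-cohort generator (`simulate_cohort()`,
`simulate_cr_trial()`) whose event law is exactly the model above, with
known ground truth for parameter-recovery and power studies. The ten
published per-unit clock coefficients (`dog_clock_coefficients()`) serve as
the generator's default truth.

## Worked example

```r
library(phenoclock)
out <- run_pipeline(tempfile("clockrun"), n_animals = 1000, seed = 1,
                    k_folds = 20)
out$evaluation[c("hr_per_agedev_year", "pearson_r_bioage_age", "auc_agedev")]
#> $hr_per_agedev_year
#> [1] 1.236199
#> $pearson_r_bioage_age
#> [1] 0.9440745
#> $auc_agedev
#> [1] 0.638936
length(out$selection$nonzero_selected)   # 9 markers at log(lambda) = -5.39
```

Reading these numbers: on the held-out quarter of a 1000-animal synthetic
cohort, each additional year of AgeDev multiplies the mortality hazard by
about 1.24 independent of breed size and sex; biological age tracks
chronological age closely (r = 0.94) while the residual carries the risk
signal; and AgeDev measured after age 5 discriminates survival to age 10
with a moderate incident/dynamic AUC of 0.64 — risk stratification, not a
diagnostic. Cross-validation keeps 9 of the 15 candidate markers, all from
the set with nonzero true coefficients.

Scoring and display chain with the pipe:

```r
scores <- score_cohort(panel, animals, out$clock)   # animal_id, age, bioage, agedev
autoplot(out$screen)                                # per-SD forest plot
autoplot(out$selection)                             # CV deviance curve
tidy(out$clock)                                     # both models, Wald CIs
```

A thin command-line wrapper lives at `inst/scripts/phenoclock`
(`simulate`, `pipeline`, `score` subcommands).

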