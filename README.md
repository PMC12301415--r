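# delirisk

Swarm-optimized AutoML for predicting delirium risk in emergency polytrauma
patients, with a synthetic cohort generator, optimizer benchmarks, Shapley
interpretation, decision-curve analysis, and a command-line decision-support
workflow.

## What it is for

Post-traumatic delirium is common in ICU polytrauma patients and routinely
under-detected. `delirisk` is aimed at clinical-ML researchers who want a
fully reproducible, interpretable risk-modelling pipeline for this setting:

* **Optimizer.** The Flood Algorithm (FLA), a swarm-intelligence continuous
  minimizer, plus an improved variant (IFLA) with chaotic sine-map
  initialization (`c_{k+1} = 0.99 |sin(π c_k)|`) and heavy-tailed Cauchy
  mutation of the incumbent best. Validated on a 12-function benchmark suite
  (sphere … Schwefel, Lunacek bi-Rastrigin, rotated hybrids).
* **AutoML.** A genome in `[0,1]^(19+6)` jointly encodes a feature mask over
  the 19 candidate predictors and the hyperparameters of a gradient-boosted
  classifier; IFLA minimizes `1 − CV-AUC + λ·|S|/19` over it (five
  stratified folds, λ = 0.01), then the best configuration is refit on the
  full training partition. Baselines: logistic regression, RBF-SVM, and
  depth-wise and leaf-wise gradient boosting.
* **Synthetic cohort.** No patient-level data are publicly available, so a
  seeded generator reproduces the published two-group summary statistics of
  a 956-patient multicenter cohort exactly in composition (764/192 split,
  326 delirium cases) and within sampling error in its marginals, including
  the 97.43% cell-completeness missingness profile.
* **Evaluation & interpretation.** PRE/SEN/SPE/ACC/ER/F1, tie-aware ROC-AUC
  and step-interpolated PR-AUC, decision-curve net benefit
  `TP/n − (FP/n)·p_t/(1−p_t)`, and exact (≤ 12 features) or
  permutation-sampled Shapley attributions with efficiency guaranteed.

## Worked example

```r
library(delirisk)

spec   <- build_default_spec()
cohort <- inject_missingness(generate_cohort(spec, seed = 7), spec, seed = 8)
table(cohort$partition, cohort$delirium)
#>          0   1
#>   test  116  76
#>   train 514 250

model <- fit_automl(cohort, opt = optimizer_config(20, 60, seed = 1, variant = "ifla"))
model
#> <automl_model> 3/19 features [age, fdp, rts], CV AUC 0.9990

imputed <- impute_cohort(cohort, spec)
metric_table(c(list(automl = model), fit_baselines(cohort, seed = 1)), imputed, "test")
#>      model   PRE   SEN   SPE   ACC    F1 ROC_AUC PR_AUC
#> 1   automl 0.986 0.947 0.991 0.974 0.966   0.998  0.997
#> 2       lr 0.962 0.987 0.974 0.979 0.974   0.999  0.999
#> 3      svm 1.000 1.000 1.000 1.000 1.000   1.000  1.000
#> 4  xgboost 0.974 1.000 0.983 0.990 0.987   0.999  0.999
#> 5 lightgbm 0.974 1.000 0.983 0.990 0.987   1.000  1.000

predict_patient(model, list(age = 81, gcs = 11, lactate = 4.6, fdp = 72, cfs = 6),
                imputed[imputed$partition == "train", ])
#> Delirium risk: 98.4% (high risk)
#> Alerts:
#>   - lactate > 2: Tissue hypoperfusion: optimize fluid resuscitation; ...
#>   - lactate > 4: Threshold-effect alert: marked delirium risk escalation ...
#>   - cfs >= 5: Frailty bundle: nutritional support (protein >= 1.2 g/kg/day), ...
#>   - fdp > 20: Coagulopathy monitoring: repeat FDP six-hourly; ...
#>   - gcs <= 12: Impaired consciousness: dynamic GCS monitoring, ...
#> Top contributions: fdp, age, rts
```

The IFLA-driven search selects a compact feature set (here age, FDP, and
RTS) and discriminates near-perfectly — expectedly so: the synthetic cohort
samples variables independently given the outcome, so its group separations
(e.g. FDP 60.6 ± 18.8 vs 16.7 ± 8.2 mg/L) are easier than real, correlated
patient data. The patient report combines the probability, a risk tier
(cut points 0.3/0.7), literature-derived alert rules whose conditions the
input actually satisfies, and a local Shapley attribution.

All of this is also scriptable from a shell via `inst/cli/delirisk`
(subcommands `generate-cohort`, `benchmark`, `train`, `evaluate`, `explain`,
`predict`).

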