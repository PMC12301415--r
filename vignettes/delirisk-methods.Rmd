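---
title: "Methods: flood-algorithm AutoML for post-traumatic delirium risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flood-algorithm AutoML for post-traumatic delirium risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Delirium affects roughly a quarter to a third of polytrauma patients admitted
to intensive care, prolongs ventilation, and worsens long-term cognition, yet
bedside screening is applied inconsistently. `delirisk` builds an automated
machine-learning (AutoML) risk model for this population: a swarm-intelligence
optimizer jointly selects predictors and tunes hyperparameters of a
gradient-boosted classifier against cross-validated discrimination, and the
resulting model is interrogated with Shapley attributions and decision-curve
analysis and wrapped in a small decision-support command-line workflow.

Because no patient-level polytrauma dataset is publicly deposited, the package
ships a seeded synthetic cohort generator parameterized from published
two-group summary statistics of a 956-patient multicenter cohort. The
generator is first-class, tested code: every downstream component is
validated end-to-end on cohorts it produces.

# The synthetic cohort generator

## What it emulates

The generator reproduces, by construction or within sampling error:

* the exact composition — 956 patients, 326 (34.1%) with delirium, an 80/20
  split of 764 training (250 delirium) and 192 test (76 delirium) patients;
* group-conditional marginal distributions for the 19 candidate predictors
  (age, sex, BMI, Clinical Frailty Scale, Charlson index, smoking, alcohol,
  systolic blood pressure, GCS, heart rate, temperature, hemoglobin,
  fibrinogen, FDP, lactate, CRP, RTS, ISS, TBI);
* a missing-completely-at-random profile with FDP the most affected variable
  (2.6%) and overall predictor-cell completeness of 97.43%.

Published mean ± SD rows become normal draws; median (IQR) rows become
lognormal draws whose parameters are matched on the log scale, so the
analytic median equals the published median exactly (body temperature uses a
location shift of 30 °C before taking logs, since its support is far from
zero and nearly symmetric); n (%) rows become Bernoulli draws; the Charlson
index is Poisson with rate `median + 1/3`, the standard median-matching
approximation. All draws are clipped to physical ranges and rounded to the
printed precision.

## Deliberate idealizations

* **Independence within group.** Published tables give marginals only, so
  variables are sampled independently given the outcome. Real trauma data
  have strong dependencies (GCS–TBI, lactate–RTS); synthetic cohorts
  therefore overstate the effective information content, and classifiers
  reach higher AUCs here than they would on real patients. Passing tests
  demonstrate the machinery is correct, not that clinical performance
  transfers.
* **Bounded-score conflicts.** The published table contains values that are
  impossible on their scales (a mean GCS of 15.85 against a ceiling of 15;
  RTS quartiles above the 7.84 maximum). The generator samples from the
  median (IQR) forms and clips to the legal ranges ([3, 15] for GCS,
  [0, 7.84] for RTS, [1, 9] for CFS): physical validity takes precedence
  over replicating typographic artifacts. One quantile (GCS no-delirium
  upper quartile, printed equal to its median) is widened to 15.5 before
  clipping so the fitted distribution is well defined.
* **Missingness calibration.** The published per-variable statements
  (FDP highest at 2.6%, others "at most 1%") are arithmetically
  incompatible with the published overall completeness of 97.43% over 19
  predictors. The generator keeps FDP at 2.6% — still the single highest
  rate — and calibrates the shared rate of the other 18 variables
  (≈ 2.568%) so expected cell completeness equals 97.43%, treating the
  overall figure as the binding quantity.
* **Imputation without leakage.** Medians (continuous/ordinal/count) and
  modes (binary) are estimated on the training partition only and reused
  for test rows, the standard leakage-safe protocol; the source description
  is silent on this point.

# The Flood Algorithm and its improvement

The baseline Flood Algorithm (FLA) is a population minimizer over a box. Each
agent proposes

$$y_i = x_i + r_1 \odot (x_{best} - x_i) + r_2 \odot (x_a - x_b),$$

a downhill flow toward the incumbent best plus differential diffusion between
two random agents ($r_1, r_2$ per-dimension uniform), clipped and accepted
greedily. With probability $0.1\,(1 - t/T)$ an *overflow* event replaces the
worst tenth of agents with uniform reinitializations (implemented as those
agents' proposal for the iteration, so the evaluation budget is exactly
$N(T{+}1) + T$ and best-so-far monotonicity is preserved).

The improved variant (IFLA) adds two ingredients:

* **Chaotic sine-map initialization.** Each dimension's initial coordinates
  come from an orbit of $c_{k+1} = 0.99\,|\sin(\pi c_k)|$ mapped onto the
  box. The map's invariant density covers (0, 1) without gaps (variance
  ≈ 0.107 versus 1/12 for uniform, measured by direct iteration); orbits
  that collapse below $10^{-6}$ restart from a fresh uniform draw.
* **One-dimensional Cauchy mutation of the global best.** Once per
  iteration a single uniformly chosen coordinate of the best position is
  perturbed by a standard Cauchy deviate (inverse-CDF construction
  $\tan(\pi(u - \tfrac12))$) scaled by $0.1\,(1 - t/T)$ of that
  dimension's range. The mutant replaces the best only on improvement;
  otherwise it reseeds the current worst agent when it beats it.

The single-coordinate design is the package's own choice where the
description of the method leaves the mutation operator open: a heavy-tailed
jump applied to *all* coordinates simultaneously almost surely destroys every
already-converged coordinate and is essentially never accepted late in a run,
whereas a one-dimensional jump can hop between basins of (near-)separable
multimodal landscapes. On 10-dimensional Rastrigin at the default budget
(population 30, 500 iterations, 30 repeats) this design reduces the median
final fitness severalfold relative to FLA, which is the qualitative behavior
the improved algorithm is meant to deliver; full-vector mutation showed no
robust gain. Ties keep the incumbent, so histories are non-increasing and
runs are bit-reproducible from the seed.

## Benchmark suite

Twelve functions at dimension 10 validate the optimizer: sphere, Rosenbrock,
Rastrigin, Ackley, Griewank, Zakharov, Levy, Schwefel, Lunacek bi-Rastrigin,
and three hybrids that rotate (seeded random orthogonal matrix) and shift a
pair of base forms. Official CEC-style rotation data files require external
downloads; the suite instead uses analytic classical forms with seeded
internal shifts/rotations, preserving the unimodal/multimodal/hybrid mix
while remaining self-contained. Every function documents its global optimum,
verified to 10⁻⁹ in the tests; the Schwefel per-dimension minimizer is
refined numerically at suite-construction time so its documented optimum is
exact rather than the usual 418.9829 approximation. Algorithms are compared
with per-run best fitnesses, Wilcoxon rank-sum tests (two-sided, the
metaheuristics convention), and mean convergence curves.

# AutoML: joint feature selection and tuning

A genome in $[0,1]^{19+6}$ encodes a feature mask (gene ≥ 0.5 selects; an
all-below-threshold genome selects its argmax gene, so the set is never
empty) and six hyperparameters of a histogram gradient-boosted tree learner:
learning rate (0.01–0.3, log scale), boosting rounds (50–500), depth (2–8),
minimum child size (5–50, applied as a hessian floor of count/4), and row and
column subsampling (0.5–1). Fitness is

$$1 - \overline{\mathrm{AUC}}_{5\text{-fold}} + \lambda\,\frac{|S|}{19},
\qquad \lambda = 0.01,$$

with label-stratified folds fixed by the seed. Each fold's held-out data
doubles as an early-stopping validation set (patience 25, capped at the
decoded round count) — the standard wrapper-AutoML device that also keeps a
full IFLA run affordable; the final model is refit on the whole training
partition at the mean early-stopped round count. The default search budget
for model fitting is population 20 × 60 iterations; benchmark-function
experiments use the larger 30 × 500 budget. The classification threshold for
tabled metrics is 0.5.

The four baselines — logistic regression, RBF-kernel SVM (scores: sigmoid of
the decision value, a batch-independent monotone transform), depth-wise
boosted trees at xgboost defaults, and a leaf-wise (31-leaf, loss-guided)
histogram GBM — are fitted on all 19 features at fixed settings.

# Evaluation conventions

* ROC curves sweep the distinct scores with ties grouped; the trapezoidal
  area then equals the Mann–Whitney statistic
  $P(s^+ > s^-) + \tfrac12 P(\text{tie})$, which the tests verify against an
  $O(n^2)$ pairwise oracle to 10⁻¹².
* PR-AUC integrates the precision step function in recall (average
  precision). Trapezoidal PR interpolation is rejected deliberately: it is
  optimistically biased for skewed classes.
* Precision and F1 are reported as absent (`NA`) when a classifier makes no
  positive prediction, as happens for the degenerate all-negative SVM rows
  whose accuracies (0.6728 train, 0.6042 test) are pure class-balance
  arithmetic.
* Decision curves use net benefit
  $\mathrm{TP}/n - (\mathrm{FP}/n)\,p_t/(1-p_t)$ on a default grid of 99
  thresholds (0.01–0.99), against treat-all and treat-none references.

# Shapley attribution

The value function $v(S)$ is the interventional expectation: features in $S$
take the explained row's values, the remainder come from each background row
in turn, and predictions are averaged (default background: 100 seeded
training rows, bounding the cost of $v$). Exact enumeration covers up to 12
features ($2^{12}$ subsets) and satisfies efficiency to machine precision;
beyond that a permutation-sampling estimator with per-feature Monte Carlo
standard errors takes over. Axiom checks (efficiency, null player, symmetry)
and exact-vs-sampled agreement are part of the test suite. Global importance
ranks features by mean absolute contribution and exports raw feature values
alongside contributions so any plotting layer can color by value.

# Decision support

`predict_patient()` combines the model probability (risk tiers at 0.3/0.7 —
configurable; the tiers are an interface convention, not an estimated
quantity), a local attribution, and an editable alert-rule table with
thresholds taken from the clinical literature on post-traumatic delirium:
lactate > 2 mmol/L (hypoperfusion) and > 4 mmol/L (threshold-effect alert),
CFS ≥ 5 (frailty bundle), FDP > 20 mg/L (coagulopathy monitoring), GCS ≤ 12
(impaired consciousness). Every fired rule's condition is literally true of
the input, and reports are pure functions of (model, input, configuration).

# Numerical and degenerate-input choices

* Integer rounding is half-up (`floor(x + 0.5)`), not banker's rounding.
* Optimizer ties keep the incumbent: determinism over exploration.
* Objectives returning non-finite values abort with the offending position.
* A cohort column that is entirely missing in the training partition raises
  an error naming the column rather than silently imputing.
* All randomness flows through explicit seeds; library calls restore the
  caller's RNG state.

# Problem sizes used in the shipped tests

Cohort checks run at the full 956-patient scale. Optimizer validation uses
2-D sphere (10 seeds × both variants) and 10-D Rastrigin (30 paired runs) at
the default 30 × 500 budget; the end-to-end pipeline check trains at the
default desk-scale AutoML budget (20 × 60) on one synthetic cohort and
requires test ROC-AUC above 0.9 — comfortably met because of the strong
group separations in the published table (FDP alone separates groups by
more than two pooled standard deviations). Attribution checks use 5-feature
models with 2000 sampled permutations.

# Known limitations

* Synthetic cohorts carry no inter-variable correlation, no longitudinal
  structure, and no site effects; absolute performance numbers on them do
  not transfer to real cohorts.
* The baseline FLA is a faithful reconstruction from the water-mass
  metaphor, not a line-by-line reimplementation of the original publication.
* Exact Shapley cost grows as $2^d$; the sampler is the only route past 12
  features.
* No confidence intervals on AUCs and no calibration analysis are provided.
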