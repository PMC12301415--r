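# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

default_spec <- function() memo("spec", build_default_spec)

# complete default cohort at seed 7
cohort7 <- function() memo("cohort7", function() generate_cohort(default_spec(), 7))

# cohort with default missingness (seed 8) and training-statistic imputation
imputed7 <- function() memo("imputed7", function() {
  impute_cohort(inject_missingness(cohort7(), default_spec(), 8), default_spec())
})

# small-budget AutoML model on the default cohort, reused by several suites
quick_automl <- function() memo("quick_automl", function() {
  fit_automl(imputed7(), opt = optimizer_config(10L, 8L, 1L, "ifla"))
})

train_rows <- function() memo("train_rows", function() {
  co <- imputed7()
  co[co$partition == "train", , drop = FALSE]
})

test_rows <- function() memo("test_rows", function() {
  co <- imputed7()
  co[co$partition == "test", , drop = FALSE]
})

sphere2 <- function() objective_fn(function(x) sum(x^2), 2, -5, 5, "sphere2")

rastrigin10 <- function() {
  objective_fn(function(z) sum(z^2 - 10 * cos(2 * pi * z) + 10),
               10, -5.12, 5.12, "rastrigin10")
}

# wrap a glm fitted on a subset of columns as a model the package's
# predict_proba understands; columns absent from the formula are exact
# null players
lr_model <- function(fit, feature_names) {
  structure(list(fit = fit, kind = "lr", feature_names = feature_names,
                 imputation_stats = list()),
            class = c("baseline_lr", "baseline_model"))
}

# two-class toy table with a single perfectly separating feature; keep n
# large enough that boosted trees can split under their child-size floors
separable_toy <- function(n = 40) {
  data.frame(x1 = c(seq(1, 2, length.out = n / 2), seq(5, 6, length.out = n / 2)),
             x2 = rep(c(0.3, 0.4), n / 2),
             delirium = rep(c(0L, 1L), each = n / 2),
             partition = "train")
}
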