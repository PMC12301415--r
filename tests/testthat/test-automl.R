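test_that("genome decoding follows the mask threshold, guard, and scale maps", {
  space <- automl_search_space(feature_names = paste0("f", 1:5),
                               hyperparameters = list(
                                 list(name = "lr", lo = 1e-3, hi = 1e-1,
                                      scale = "log", type = "real"),
                                 list(name = "n", lo = 10, hi = 20,
                                      scale = "linear", type = "integer")))
  cfg <- decode_genome(c(0.7, 0.2, 0.5, 0.1, 0.1, 0.5, 0.25), space)
  expect_identical(cfg$selected_features, c("f1", "f3"))
  expect_equal(cfg$hyperparameters$lr, 1e-2, tolerance = 1e-12)  # geometric midpoint
  expect_identical(cfg$hyperparameters$n, 13L)                   # 12.5 rounds half-up
  # all-below-threshold guard selects the argmax gene
  cfg2 <- decode_genome(c(0.4, 0.4, 0.4, 0.49, 0.4, 0, 0), space)
  expect_identical(cfg2$selected_features, "f4")
  expect_error(decode_genome(rep(0.5, 3), space), "genome length")
  # decode is total on the hypercube and never empty
  set.seed(2)
  for (k in 1:50) {
    g <- runif(7)
    cf <- decode_genome(g, space)
    expect_gte(length(cf$selected_features), 1L)
    expect_true(cf$hyperparameters$lr >= 1e-3 && cf$hyperparameters$lr <= 1e-1)
    expect_true(cf$hyperparameters$n >= 10L && cf$hyperparameters$n <= 20L)
  }
})

test_that("search space validation enforces descriptor invariants", {
  expect_error(automl_search_space(hyperparameters = list(
    list(name = "a", lo = 2, hi = 1, scale = "linear", type = "real"))), "lo must be")
  expect_error(automl_search_space(hyperparameters = list(
    list(name = "a", lo = 0, hi = 1, scale = "log", type = "real"))), "log scale")
})

test_that("cv fitness is deterministic, bounded, and near zero on separable data", {
  toy <- separable_toy(200)
  space <- automl_search_space(feature_names = c("x1", "x2"), lambda = 0)
  genome <- c(1, 0, rep(0.5, length(space$hyperparameters)))
  f1 <- cv_fitness(genome, toy, space, folds = 5, seed = 3)
  f2 <- cv_fitness(genome, toy, space, folds = 5, seed = 3)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_lt(as.numeric(f1), 0.02)   # AUC ~ 1 when one feature separates
  # sparsity penalty ordering: same data, larger mask, higher penalty term
  space_l <- automl_search_space(feature_names = c("x1", "x2"), lambda = 0.5)
  f_one <- cv_fitness(c(1, 0, rep(0.5, 6)), toy, space_l, folds = 5, seed = 3)
  f_two <- cv_fitness(c(1, 1, rep(0.5, 6)), toy, space_l, folds = 5, seed = 3)
  expect_gt(as.numeric(f_two), as.numeric(f_one) - 1e-9)
  expect_error(cv_fitness(genome, transform(toy, delirium = 0), space, 5, 1),
               "both classes")
})

test_that("cv fitness is uninformative under label permutation", {
  train <- train_rows()
  space <- automl_search_space(lambda = 0)
  genome <- c(rep(0.9, 19), rep(0.5, 6))
  set.seed(11)
  null_fit <- vapply(1:3, function(i) {
    shuffled <- train
    shuffled$delirium <- sample(shuffled$delirium)
    as.numeric(cv_fitness(genome, shuffled, space, folds = 5, seed = i))
  }, 0)
  expect_gt(mean(null_fit), 0.35)   # 1 - AUC with AUC ~ 0.5
  expect_lt(mean(null_fit), 0.65)
})

test_that("the fitted AutoML model beats random genomes and selects true signal", {
  model <- quick_automl()
  expect_s3_class(model, "automl_model")
  expect_gte(length(model$config$selected_features), 1L)
  # optimized fitness no worse than a random genome under the same seed
  space <- automl_search_space()
  set.seed(21)
  g_rand <- runif(25)
  f_rand <- as.numeric(cv_fitness(g_rand, train_rows(), space, 5, 1))
  expect_lte(model$cv_score, f_rand)
  # the strongest published separations are found
  expect_true(any(c("fdp", "age") %in% model$config$selected_features))
  # probabilities live in [0, 1] and are deterministic
  p <- predict_proba(model, test_rows())
  expect_length(p, 192L)
  expect_true(all(p >= 0 & p <= 1))
  dup <- test_rows()[c(1, 1), ]
  expect_equal(predict_proba(model, dup)[1], predict_proba(model, dup)[2])
})

test_that("forcing a single candidate feature yields a single-feature model", {
  toy <- separable_toy(60)
  space <- automl_search_space(feature_names = "x1", lambda = 0)
  model <- fit_automl(toy, space,
                      opt = optimizer_config(6, 3, 2, "ifla"),
                      spec = cohort_spec(list(
                        x1 = variable_spec("x1", "continuous", "normal",
                                           list(mean = 0, sd = 1), list(mean = 0, sd = 1)),
                        x2 = variable_spec("x2", "continuous", "normal",
                                           list(mean = 0, sd = 1), list(mean = 0, sd = 1)))))
  expect_identical(model$config$selected_features, "x1")
})

test_that("missing cells at prediction time fall back to stored training medians", {
  model <- quick_automl()
  rows <- test_rows()[1:4, ]
  feat <- model$config$selected_features[1]
  rows_na <- rows
  rows_na[[feat]] <- NA_real_
  rows_med <- rows
  rows_med[[feat]] <- model$imputation_stats[[feat]]
  expect_equal(predict_proba(model, rows_na), predict_proba(model, rows_med))
  rows_gone <- rows[setdiff(names(rows), feat)]
  expect_error(predict_proba(model, rows_gone), "lacks required feature")
})

test_that("the four baselines fit and discriminate on the synthetic cohort", {
  models <- fit_baselines(imputed7(), seed = 1)
  expect_named(models, c("lr", "svm", "xgboost", "lightgbm"))
  test <- test_rows()
  for (nm in names(models)) {
    p <- predict_proba(models[[nm]], test)
    expect_true(all(p >= 0 & p <= 1), label = nm)
    auc <- roc_pr_curves(test$delirium, p)$roc_auc
    expect_gt(auc, 0.5)
  }
})

test_that("logistic regression separates a separable toy perfectly", {
  toy <- separable_toy(40)
  fit <- suppressWarnings(glm(delirium ~ x1, data = toy, family = binomial()))
  model <- lr_model(fit, c("x1", "x2"))
  p <- predict_proba(model, toy)
  expect_equal(roc_pr_curves(toy$delirium, p)$roc_auc, 1.0)
})

test_that("a fitted model round-trips through its directory layout", {
  model <- quick_automl()
  dir <- tempfile()
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "learner.json")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- load_model(dir)
  expect_identical(back$config$selected_features, model$config$selected_features)
  expect_equal(predict_proba(back, test_rows()), predict_proba(model, test_rows()),
               tolerance = 1e-6)
})
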