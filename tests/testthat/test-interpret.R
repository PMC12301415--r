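# toy model with known structure: probability = plogis(x1 + x2), x3 ignored.
# Registered as a baseline-like object so predict_proba dispatch applies the
# glm fitted with an offset-free formula on x1 + x2 only.
additive_toy_model <- function() {
  set.seed(31)
  n <- 400
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  df$delirium <- rbinom(n, 1, plogis(df$x1 + df$x2))
  fit <- glm(delirium ~ x1 + x2, data = df, family = binomial())
  list(model = lr_model(fit, c("x1", "x2", "x3")), data = df)
}

test_that("exact Shapley values satisfy efficiency, null player, and symmetry", {
  toy <- additive_toy_model()
  bg <- toy$data[1:60, ]
  row <- toy$data[101, ]
  at <- shapley_exact(toy$model, row, bg)
  expect_equal(at$base_value + sum(at$per_feature), at$prediction, tolerance = 1e-9)
  # x3 never enters the model: exact null player
  expect_equal(unname(at$per_feature["x3"]), 0, tolerance = 1e-12)
  # symmetric model, identical row values -> identical contributions
  fit_sym <- glm(delirium ~ I(x1 + x2), data = toy$data, family = binomial())
  model_sym <- lr_model(fit_sym, c("x1", "x2"))
  row_sym <- row
  row_sym$x1 <- 1.3
  row_sym$x2 <- 1.3
  bg_sym <- bg
  bg_sym$x2 <- bg_sym$x1  # make the two features exchangeable in background too
  at_sym <- shapley_exact(model_sym, row_sym, bg_sym)
  expect_equal(unname(at_sym$per_feature["x1"]), unname(at_sym$per_feature["x2"]),
               tolerance = 1e-9)
})

test_that("exact Shapley on the fitted cohort model is exactly efficient", {
  model <- quick_automl()
  bg <- train_rows()[seq_len(50), ]
  for (i in c(1, 7)) {
    at <- shapley_exact(model, test_rows()[i, ], bg)
    expect_equal(at$base_value + sum(at$per_feature), at$prediction,
                 tolerance = 1e-9)
  }
})

test_that("exact enumeration refuses more than 12 features", {
  model <- quick_automl()
  fake_feats <- paste0("f", 1:13)
  expect_error(shapley_exact(model, test_rows()[1, ], train_rows()[1:5, ],
                             features = fake_feats),
               "shapley_mc")
})

test_that("the Monte Carlo estimator agrees with exact enumeration", {
  set.seed(5)
  n <- 300
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                   x4 = rnorm(n), x5 = rnorm(n))
  df$delirium <- rbinom(n, 1, plogis(1.5 * df$x1 - df$x2 + 0.5 * df$x3))
  fit <- glm(delirium ~ x1 + x2 + x3 + x4 + x5, data = df, family = binomial())
  model <- lr_model(fit, paste0("x", 1:5))
  bg <- df[1:40, ]
  row <- df[201, ]
  exact <- shapley_exact(model, row, bg)
  mc <- shapley_mc(model, row, bg, n_permutations = 2000, seed = 17)
  for (f in paste0("x", 1:5)) {
    se <- max(mc$mc_se[f], 1e-9)
    expect_lt(abs(mc$per_feature[f] - exact$per_feature[f]), 3 * se,
              label = sprintf("MC vs exact for %s", f))
  }
  # same seed reproduces; constant model attributes nothing
  mc2 <- shapley_mc(model, row, bg, n_permutations = 50, seed = 17)
  mc3 <- shapley_mc(model, row, bg, n_permutations = 50, seed = 17)
  expect_identical(mc2$per_feature, mc3$per_feature)
  const_fit <- glm(delirium ~ 1, data = df, family = binomial())
  const <- lr_model(const_fit, paste0("x", 1:5))
  atc <- shapley_mc(const, row, bg, n_permutations = 50, seed = 1)
  expect_true(all(abs(atc$per_feature) < 1e-12))
})

test_that("global importance ranks by mean absolute contribution, order-invariantly", {
  toy <- additive_toy_model()
  bg <- toy$data[1:40, ]
  rows <- toy$data[101:115, ]
  atts <- lapply(seq_len(nrow(rows)), function(i) shapley_exact(toy$model, rows[i, ], bg))
  gi <- global_importance(atts)
  expect_identical(nrow(gi$ranking), 3L)
  expect_identical(gi$ranking$feature[3], "x3")        # null player ranks last
  expect_identical(nrow(gi$summary), 15L * 3L)
  gi_rev <- global_importance(rev(atts))
  expect_equal(gi$ranking, gi_rev$ranking)
  # single-feature model puts its only feature first
  one <- global_importance(list(structure(list(
    per_feature = c(a = 0.4), base_value = 0.2, prediction = 0.6,
    feature_values = 1), class = "attribution")))
  expect_identical(one$ranking$feature, "a")
  expect_error(global_importance(list()), "at least one")
})

test_that("top-ranked cohort features are stable across attribution seeds", {
  model <- quick_automl()
  train <- train_rows()
  test <- test_rows()
  tops <- lapply(1:3, function(s) {
    bg <- train[delirisk:::with_seed(s, sample.int(nrow(train), 40)), ]
    idx <- delirisk:::with_seed(s + 100, sample.int(nrow(test), 8))
    atts <- lapply(idx, function(i) shapley_exact(model, test[i, ], bg))
    head(global_importance(atts)$ranking$feature, 3)
  })
  # the single most important feature never changes with the seed
  expect_length(unique(vapply(tops, `[`, "", 1)), 1L)
})
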