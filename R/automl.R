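#' Joint feature-selection / hyperparameter search space
#'
#' Describes the genome the optimizer searches over: one mask gene per
#' candidate feature plus one gene per hyperparameter of the boosted-tree
#' base learner. The default hyperparameter box covers learning rate
#' (log-scale), boosting rounds, tree depth, minimum child size, and row /
#' column subsampling.
#'
#' @param feature_names candidate predictor names (default: the 19 cohort
#'   predictors of [build_default_spec()]).
#' @param hyperparameters list of descriptors `list(name, lo, hi, scale,
#'   type)` with `scale` in `{"linear", "log"}` and `type` in `{"real",
#'   "integer"}`.
#' @param lambda sparsity penalty weight: the fitness adds
#'   `lambda * n_selected / n_candidates`, nudging the search toward compact
#'   feature sets without forcing them.
#' @return an object of class `search_space`.
#' @export
automl_search_space <- function(feature_names = names(build_default_spec()$variables),
                                hyperparameters = default_hyperparameters(),
                                lambda = 0.01) {
  for (h in hyperparameters) {
    if (h$lo >= h$hi) stopf("hyperparameter '%s': lo must be < hi", h$name)
    if (h$scale == "log" && h$lo <= 0) stopf("hyperparameter '%s': log scale requires lo > 0", h$name)
  }
  structure(list(feature_names = feature_names,
                 hyperparameters = hyperparameters, lambda = lambda),
            class = "search_space")
}

#' @rdname automl_search_space
#' @export
default_hyperparameters <- function() {
  list(
    list(name = "learning_rate", lo = 0.01, hi = 0.3, scale = "log", type = "real"),
    list(name = "n_estimators", lo = 50, hi = 500, scale = "linear", type = "integer"),
    list(name = "max_depth", lo = 2, hi = 8, scale = "linear", type = "integer"),
    list(name = "min_child_samples", lo = 5, hi = 50, scale = "linear", type = "integer"),
    list(name = "subsample", lo = 0.5, hi = 1.0, scale = "linear", type = "real"),
    list(name = "colsample", lo = 0.5, hi = 1.0, scale = "linear", type = "real")
  )
}

#' Decode a genome into a model configuration
#'
#' The first `length(feature_names)` genes are the feature mask: feature `i`
#' is selected iff its gene is at least 0.5; if no gene reaches 0.5 the single
#' largest gene is selected (the feature set is never empty). The remaining
#' genes map onto the hyperparameter boxes, linearly or log-linearly, with
#' integers rounded half-up.
#'
#' @param genome numeric vector in `[0, 1]` of length
#'   `n_features + n_hyperparameters`.
#' @param space a [automl_search_space()].
#' @return a list of class `model_config` with `selected_features` (character)
#'   and `hyperparameters` (named list).
#' @export
decode_genome <- function(genome, space) {
  n_feat <- length(space$feature_names)
  n_hp <- length(space$hyperparameters)
  if (length(genome) != n_feat + n_hp) {
    stopf("genome length %d does not match the search space (%d features + %d hyperparameters)",
          length(genome), n_feat, n_hp)
  }
  mask <- genome[seq_len(n_feat)] >= 0.5
  if (!any(mask)) mask[which.max(genome[seq_len(n_feat)])] <- TRUE
  hp <- list()
  for (j in seq_len(n_hp)) {
    h <- space$hyperparameters[[j]]
    g <- genome[n_feat + j]
    val <- if (h$scale == "log") {
      exp(log(h$lo) + g * (log(h$hi) - log(h$lo)))
    } else {
      h$lo + g * (h$hi - h$lo)
    }
    if (h$type == "integer") val <- as.integer(round_half_up(val))
    hp[[h$name]] <- val
  }
  structure(list(selected_features = space$feature_names[mask],
                 hyperparameters = hp),
            class = "model_config")
}

xgb_params_from_config <- function(hp, seed) {
  list(objective = "binary:logistic", eval_metric = "auc",
       tree_method = "hist", nthread = 1, seed = seed,
       eta = hp$learning_rate, max_depth = hp$max_depth,
       # xgboost gates splits on the child hessian sum, which for logistic
       # loss is at most n/4 — scale the sample count accordingly
       min_child_weight = hp$min_child_samples / 4,
       subsample = hp$subsample, colsample_bytree = hp$colsample)
}

stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

cohort_matrix <- function(rows, feature_names) {
  missing_cols <- setdiff(feature_names, names(rows))
  if (length(missing_cols)) {
    stopf("cohort lacks required feature column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  as.matrix(as.data.frame(rows)[feature_names])
}

#' Cross-validated fitness of a genome
#'
#' Decodes the genome, trains the boosted-tree learner on the selected
#' features in each of `folds` label-stratified folds (with the held-out fold
#' as early-stopping validation, capped at the decoded number of rounds), and
#' returns `1 - mean out-of-fold ROC-AUC + lambda * n_selected / n_candidates`.
#' Lower is better; deterministic given `(genome, seed)`.
#'
#' @param genome numeric genome in `[0, 1]`.
#' @param train imputed training rows with a `delirium` column.
#' @param space a [automl_search_space()].
#' @param folds number of stratified CV folds.
#' @param seed fold-assignment and learner seed.
#' @return scalar fitness; attribute `"mean_best_iteration"` records the mean
#'   early-stopped round count across folds.
#' @export
cv_fitness <- function(genome, train, space, folds = 5L, seed = 1L) {
  config <- decode_genome(genome, space)
  y <- train$delirium
  if (length(unique(y)) < 2L) stopf("training data must contain both classes")
  X <- cohort_matrix(train, config$selected_features)
  fold <- stratified_folds(y, folds, seed)
  params <- xgb_params_from_config(config$hyperparameters, seed)
  aucs <- numeric(folds)
  best_iters <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (length(unique(y[!tr])) < 2L) stopf("fold %d contains a single class", k)
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    dva <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], label = y[!tr])
    bst <- xgboost::xgb.train(params = params, data = dtr,
                              nrounds = config$hyperparameters$n_estimators,
                              evals = list(val = dva),
                              early_stopping_rounds = 25L, verbose = 0)
    log_auc <- attributes(bst)$evaluation_log[[2L]]
    aucs[k] <- max(log_auc)
    best_iters[k] <- which.max(log_auc)
  }
  fit <- (1 - mean(aucs)) +
    space$lambda * length(config$selected_features) / length(space$feature_names)
  attr(fit, "mean_best_iteration") <- mean(best_iters)
  fit
}

#' Fit the AutoML model
#'
#' Runs the (improved) Flood Algorithm over the unit hypercube
#' `[0,1]^(n_features + n_hyperparameters)` with [cv_fitness()] as the
#' objective — joint wrapper feature selection and hyperparameter tuning —
#' then refits the base learner on the full training partition at the best
#' decoded configuration. Imputation statistics (training medians/modes) are
#' fitted here and stored with the model.
#'
#' @param cohort a cohort containing a training partition (missing cells
#'   allowed; they are imputed with training statistics).
#' @param space a [automl_search_space()].
#' @param opt an [optimizer_config()]; the default is the desk-scale AutoML
#'   budget (population 20, 60 iterations, IFLA).
#' @param spec the [cohort_spec()] governing imputation roles.
#' @param folds CV folds for the fitness.
#' @return an object of class `automl_model`: the trained booster, decoded
#'   `config`, `imputation_stats`, `cv_score` (1 - penalized fitness is not
#'   reported; `cv_score` is the best fitness reached), `cv_auc`, and the
#'   optimization `result`.
#' @export
fit_automl <- function(cohort, space = automl_search_space(),
                       opt = optimizer_config(population_size = 20L,
                                              max_iterations = 60L,
                                              seed = 1L, variant = "ifla"),
                       spec = build_default_spec(), folds = 5L) {
  imputed <- impute_cohort(cohort, spec)
  stats_ <- attr(imputed, "imputation_stats")
  train <- imputed[imputed$partition == "train", , drop = FALSE]
  dim_ <- length(space$feature_names) + length(space$hyperparameters)
  objective <- objective_fn(function(g) as.numeric(cv_fitness(g, train, space, folds, opt$seed)),
                            dim = dim_, lower = 0, upper = 1,
                            name = "cv_fitness")
  result <- fla_optimize(objective, opt)
  config <- decode_genome(result$best_position, space)
  fit_final <- cv_fitness(result$best_position, train, space, folds, opt$seed)
  nrounds <- max(10L, as.integer(round(attr(fit_final, "mean_best_iteration"))))
  X <- cohort_matrix(train, config$selected_features)
  params <- xgb_params_from_config(config$hyperparameters, opt$seed)
  booster <- xgboost::xgb.train(params = params,
                                data = xgboost::xgb.DMatrix(X, label = train$delirium),
                                nrounds = nrounds, verbose = 0)
  cv_auc <- 1 - (as.numeric(fit_final) -
                   space$lambda * length(config$selected_features) /
                   length(space$feature_names))
  structure(list(learner = booster, config = config, space = space,
                 imputation_stats = stats_, cv_score = result$best_fitness,
                 cv_auc = cv_auc, nrounds = nrounds, result = result),
            class = "automl_model")
}

#' @export
print.automl_model <- function(x, ...) {
  cat(sprintf("<automl_model> %d/%d features [%s], CV AUC %.4f\n",
              length(x$config$selected_features), length(x$space$feature_names),
              paste(x$config$selected_features, collapse = ", "), x$cv_auc))
  invisible(x)
}

#' Predicted delirium probabilities
#'
#' Applies the model's stored imputation statistics to any missing cells,
#' restricts to the model's features, and returns per-row probabilities.
#'
#' @param model a fitted model (`automl_model` or a baseline).
#' @param rows cohort rows (missing cells allowed).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, rows) UseMethod("predict_proba")

apply_imputation <- function(rows, stats_, needed) {
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols)) {
    stopf("input lacks required feature column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  for (nm in needed) {
    nas <- is.na(rows[[nm]])
    if (any(nas)) {
      if (is.null(stats_[[nm]])) stopf("no imputation statistic stored for '%s'", nm)
      rows[[nm]][nas] <- stats_[[nm]]
    }
  }
  rows
}

#' @export
predict_proba.automl_model <- function(model, rows) {
  rows <- apply_imputation(rows, model$imputation_stats, model$config$selected_features)
  X <- cohort_matrix(rows, model$config$selected_features)
  as.numeric(stats::predict(model$learner, xgboost::xgb.DMatrix(X)))
}

#' Fit the four baseline classifiers
#'
#' Fits logistic regression, an RBF support-vector machine, depth-wise
#' gradient boosting (xgboost defaults), and a leaf-wise histogram
#' gradient-boosted machine (LightGBM-style growth: 31 leaves, loss-guided)
#' on all candidate features of the training partition, at fixed documented
#' settings. The SVM's probability scores are the sigmoid of its decision
#' values, a monotone map of the decision function used only for ranking
#' metrics.
#'
#' @param cohort a cohort with a training partition.
#' @param seed learner seed.
#' @param spec the [cohort_spec()] governing imputation.
#' @param feature_names candidate features (default all 19).
#' @return named list of models (`lr`, `svm`, `xgboost`, `lightgbm`), each
#'   supporting [predict_proba()].
#' @export
fit_baselines <- function(cohort, seed = 1L, spec = build_default_spec(),
                          feature_names = names(spec$variables)) {
  imputed <- impute_cohort(cohort, spec)
  stats_ <- attr(imputed, "imputation_stats")
  train <- imputed[imputed$partition == "train", , drop = FALSE]
  X <- cohort_matrix(train, feature_names)
  y <- train$delirium
  df <- as.data.frame(X)
  df$delirium <- y

  lr <- stats::glm(delirium ~ ., data = df, family = stats::binomial())
  svm_fit <- with_seed(seed, e1071::svm(X, factor(y), kernel = "radial", scale = TRUE))
  xgb_default <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1, seed = seed,
                  eta = 0.3, max_depth = 6),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 100L, verbose = 0)
  lgbm_style <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1, seed = seed,
                  tree_method = "hist", grow_policy = "lossguide",
                  max_leaves = 31L, max_depth = 0L, eta = 0.1),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 100L, verbose = 0)

  mk <- function(fit, kind) {
    structure(list(fit = fit, kind = kind, feature_names = feature_names,
                   imputation_stats = stats_),
              class = c(paste0("baseline_", kind), "baseline_model"))
  }
  list(lr = mk(lr, "lr"), svm = mk(svm_fit, "svm"),
       xgboost = mk(xgb_default, "xgboost"), lightgbm = mk(lgbm_style, "lightgbm"))
}

#' @export
predict_proba.baseline_model <- function(model, rows) {
  rows <- apply_imputation(rows, model$imputation_stats, model$feature_names)
  X <- cohort_matrix(rows, model$feature_names)
  switch(model$kind,
    lr = as.numeric(stats::predict(model$fit, as.data.frame(X), type = "response")),
    svm = {
      dv_att <- attr(stats::predict(model$fit, X, decision.values = TRUE),
                     "decision.values")
      dv <- as.numeric(dv_att)
      # decision values are signed toward the first factor level; orient so
      # larger scores mean higher delirium probability
      if (identical(colnames(dv_att)[1], "0/1")) dv <- -dv
      stats::plogis(dv)
    },
    as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X)))
  )
}
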