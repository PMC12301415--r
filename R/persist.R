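#' Persist and reload a fitted AutoML model
#'
#' A model directory holds the booster (`learner.json`, xgboost's JSON
#' serialization) plus `config.json` with the decoded configuration,
#' imputation statistics, search space, and CV score. `train` / `predict`
#' CLI commands round-trip this layout.
#'
#' @param model an `automl_model`.
#' @param dir target directory (created if absent).
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "automl_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$learner, file.path(dir, "learner.json"))
  meta <- list(selected_features = model$config$selected_features,
               hyperparameters = model$config$hyperparameters,
               imputation_stats = model$imputation_stats,
               feature_names = model$space$feature_names,
               lambda = model$space$lambda,
               cv_score = model$cv_score, cv_auc = model$cv_auc,
               nrounds = model$nrounds)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  learner <- xgboost::xgb.load(file.path(dir, "learner.json"))
  space <- automl_search_space(feature_names = meta$feature_names,
                               lambda = meta$lambda)
  structure(list(learner = learner,
                 config = structure(list(selected_features = meta$selected_features,
                                         hyperparameters = as.list(meta$hyperparameters)),
                                    class = "model_config"),
                 space = space,
                 imputation_stats = as.list(meta$imputation_stats),
                 cv_score = meta$cv_score, cv_auc = meta$cv_auc,
                 nrounds = meta$nrounds),
            class = "automl_model")
}
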