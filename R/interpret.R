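# Value function v(S): mean model prediction over background rows with the
# features in S taken from `row` and the rest from each background row
# (marginal/interventional expectation). `masks` is a logical matrix, one
# subset per row; returns one value per subset, batching all predictions.
subset_values <- function(model, row, background, feats, masks) {
  nb <- nrow(background)
  ns <- nrow(masks)
  bg <- as.matrix(as.data.frame(background)[feats])
  rv <- as.numeric(as.data.frame(row)[1, feats])
  big <- bg[rep(seq_len(nb), ns), , drop = FALSE]
  for (s in seq_len(ns)) {
    on <- which(masks[s, ])
    if (length(on)) {
      rows_s <- (s - 1L) * nb + seq_len(nb)
      big[rows_s, on] <- matrix(rv[on], nb, length(on), byrow = TRUE)
    }
  }
  preds <- predict_frame(model, big, feats)
  colMeans(matrix(preds, nb, ns))  # column s = subset s
}

# predict on a plain feature matrix, bypassing imputation (rows are complete)
predict_frame <- function(model, X, feats) {
  df <- as.data.frame(X)
  names(df) <- feats
  predict_proba(model, df)
}

#' Exact Shapley attribution of one prediction
#'
#' Enumerates all feature subsets and computes each feature's Shapley value
#' `sum_S |S|! (d-|S|-1)! / d! * (v(S u {j}) - v(S))` where `v(S)` is the
#' mean prediction with the features in `S` taken from the explained row and
#' the remainder from background rows. Satisfies the efficiency axiom
#' exactly: `base_value + sum(contributions) = prediction`.
#'
#' @param model a fitted model supporting [predict_proba()]; attribution is
#'   over the model's feature set.
#' @param row single cohort row (data.frame) to explain.
#' @param background cohort rows supplying the off-coalition feature values
#'   (a seeded sample of ~100 training rows is typical).
#' @param features features to attribute; defaults to the model's features.
#' @return an object of class `attribution`: `per_feature` (named
#'   contributions), `base_value` (mean background prediction), `prediction`,
#'   and `feature_values` of the explained row.
#' @export
shapley_exact <- function(model, row, background, features = model_features(model)) {
  d <- length(features)
  if (d > 12L) {
    stopf("exact enumeration is limited to 12 features (got %d); use shapley_mc()", d)
  }
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
  colnames(masks) <- features
  v <- subset_values(model, row, background, features, masks)
  sizes <- rowSums(masks)
  # weight of S as a predecessor set; the full set never acts as one
  w <- ifelse(sizes < d, factorial(sizes) * factorial(pmax(d - sizes - 1, 0)) / factorial(d), 0)
  phi <- numeric(d)
  # subset index arithmetic: bit j flips between S and S u {j}
  bit <- 2L^(seq_len(d) - 1L)
  idx <- seq_len(nrow(masks)) - 1L
  for (j in seq_len(d)) {
    without <- which(bitwAnd(idx, bit[j]) == 0L)
    with_j <- without + bit[j]
    phi[j] <- sum(w[without] * (v[with_j] - v[without]))
  }
  names(phi) <- features
  new_attribution(phi, base_value = v[1L], prediction = v[length(v)],
                  row = row, features = features)
}

new_attribution <- function(phi, base_value, prediction, row, features) {
  structure(list(per_feature = phi, base_value = base_value,
                 prediction = prediction,
                 feature_values = as.numeric(as.data.frame(row)[1, features])),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("prediction %.4f = base %.4f + contributions:\n", x$prediction, x$base_value))
  print(round(sort(x$per_feature, decreasing = TRUE), 4))
  invisible(x)
}

#' Monte Carlo Shapley attribution
#'
#' Permutation-sampling estimator: each draw samples a feature ordering and a
#' background row, walks the ordering replacing background values by the
#' explained row's values, and records successive prediction differences as
#' marginal contributions. The average over draws is an unbiased estimate of
#' the exact Shapley values.
#'
#' @inheritParams shapley_exact
#' @param n_permutations number of sampled orderings.
#' @param seed RNG seed.
#' @return an `attribution` with an extra `mc_se` field (per-feature Monte
#'   Carlo standard errors).
#' @export
shapley_mc <- function(model, row, background, n_permutations = 200L, seed = 1L,
                       features = model_features(model)) {
  stopifnot(n_permutations >= 1L)
  d <- length(features)
  nb <- nrow(background)
  bg <- as.matrix(as.data.frame(background)[features])
  rv <- as.numeric(as.data.frame(row)[1, features])
  with_seed(seed, {
    perms <- replicate(n_permutations, sample.int(d), simplify = FALSE)
    bg_pick <- sample.int(nb, n_permutations, replace = TRUE)
  })
  # build all chain rows ((d+1) per permutation), one batched predict call
  chain <- matrix(0, n_permutations * (d + 1L), d)
  for (p in seq_len(n_permutations)) {
    x <- bg[bg_pick[p], ]
    base_row <- (p - 1L) * (d + 1L)
    chain[base_row + 1L, ] <- x
    for (step in seq_len(d)) {
      x[perms[[p]][step]] <- rv[perms[[p]][step]]
      chain[base_row + 1L + step, ] <- x
    }
  }
  preds <- predict_frame(model, chain, features)
  contrib <- matrix(0, n_permutations, d, dimnames = list(NULL, features))
  for (p in seq_len(n_permutations)) {
    base_row <- (p - 1L) * (d + 1L)
    deltas <- diff(preds[base_row + seq_len(d + 1L)])
    contrib[p, perms[[p]]] <- deltas
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  out <- new_attribution(phi, base_value = mean(predict_frame(model, bg, features)),
                         prediction = predict_frame(model, matrix(rv, 1L), features),
                         row = row, features = features)
  out$mc_se <- se
  out
}

model_features <- function(model) {
  if (inherits(model, "automl_model")) model$config$selected_features
  else if (inherits(model, "baseline_model")) model$feature_names
  else stopf("cannot infer feature set; pass `features` explicitly")
}

#' Global feature importance from local attributions
#'
#' Ranks features by the mean absolute Shapley contribution across a set of
#' explained rows, and emits the long-format (row, feature, contribution,
#' feature value) triples that a beeswarm-style summary plot consumes.
#'
#' @param attributions non-empty list of `attribution` objects over a common
#'   feature set.
#' @return list of class `global_importance`: `ranking` (data.frame
#'   `feature`, `mean_abs_contribution`, sorted descending) and `summary`
#'   (long data.frame).
#' @export
global_importance <- function(attributions) {
  if (!length(attributions)) stopf("need at least one attribution")
  feats <- names(attributions[[1L]]$per_feature)
  contrib <- t(vapply(attributions, function(a) a$per_feature[feats], numeric(length(feats))))
  vals <- t(vapply(attributions, function(a) {
    v <- a$feature_values
    names(v) <- names(a$per_feature)
    v[feats]
  }, numeric(length(feats))))
  mean_abs <- colMeans(abs(contrib))
  ranking <- data.frame(feature = feats, mean_abs_contribution = mean_abs)
  ranking <- ranking[order(-ranking$mean_abs_contribution), ]
  rownames(ranking) <- NULL
  summary_df <- data.frame(
    row = rep(seq_len(nrow(contrib)), times = length(feats)),
    feature = rep(feats, each = nrow(contrib)),
    contribution = as.vector(contrib),
    value = as.vector(vals))
  structure(list(ranking = ranking, summary = summary_df),
            class = "global_importance")
}

#' @export
print.global_importance <- function(x, ...) {
  cat("Global feature importance (mean |Shapley contribution|):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
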