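check_labels_probs <- function(labels, probabilities) {
  if (!length(labels)) stopf("empty input: no labels supplied")
  if (length(labels) != length(probabilities)) {
    stopf("labels and probabilities differ in length (%d vs %d)",
          length(labels), length(probabilities))
  }
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary 0/1")
  if (any(!is.finite(probabilities)) || any(probabilities < 0 | probabilities > 1)) {
    stopf("probabilities must lie in [0, 1]")
  }
}

#' Threshold classification metrics
#'
#' Computes the six standard confusion-matrix metrics at a probability
#' threshold: precision (PRE), sensitivity (SEN), specificity (SPE), accuracy
#' (ACC), error rate (ER = 1 - ACC), and F1. Predictions are positive iff
#' `probability >= threshold`. When the classifier makes no positive
#' prediction, precision and F1 are undefined and reported as `NA` (printed
#' tables show them as absent).
#'
#' @param labels binary 0/1 outcome vector.
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param threshold classification threshold (default 0.5).
#' @return a list of class `metric_set` with fields `PRE`, `SEN`, `SPE`,
#'   `ACC`, `ER`, `F1` and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' # an all-negative classifier on a 250/514 split
#' m <- confusion_metrics(rep(c(1, 0), c(250, 514)), rep(0, 764))
#' round(m$ACC, 4)  # 0.6728
#' @export
confusion_metrics <- function(labels, probabilities, threshold = 0.5) {
  check_labels_probs(labels, probabilities)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & labels == 1)
  fp <- sum(pred == 1L & labels == 0)
  tn <- sum(pred == 0L & labels == 0)
  fn <- sum(pred == 0L & labels == 1)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(labels)
  pre <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(pre) && !is.na(sen) && pre + sen > 0) {
    2 * pre * sen / (pre + sen)
  } else NA_real_
  structure(list(PRE = pre, SEN = sen, SPE = spe, ACC = acc, ER = 1 - acc,
                 F1 = f1, tp = tp, fp = fp, tn = tn, fn = fn,
                 threshold = threshold),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  fmt <- function(v) if (is.na(v)) "—" else formatC(v, digits = digits, format = "f")
  cat(sprintf("PRE %s  SEN %s  SPE %s  ACC %s  ER %s  F1 %s (threshold %.2f)\n",
              fmt(x$PRE), fmt(x$SEN), fmt(x$SPE), fmt(x$ACC), fmt(x$ER),
              fmt(x$F1), x$threshold))
  invisible(x)
}

#' ROC and precision-recall curves with areas
#'
#' Sweeps the unique scores as thresholds (ties grouped, so the ROC area
#' equals the Mann-Whitney statistic `P(score+ > score-) + 0.5 P(tie)`),
#' computes the ROC area by the trapezoidal rule, and the PR area under the
#' precision step function in recall (average-precision convention;
#' trapezoidal PR interpolation is deliberately not used because it is
#' optimistically biased).
#'
#' @param labels binary 0/1 outcomes; both classes must be present.
#' @param probabilities predicted scores (any monotone scale).
#' @return a list of class `roc_pr` with `roc` (data.frame `threshold`,
#'   `fpr`, `tpr`), `pr` (data.frame `threshold`, `recall`, `precision`),
#'   `roc_auc`, `pr_auc`.
#' @export
roc_pr_curves <- function(labels, probabilities) {
  if (!length(labels)) stopf("empty input: no labels supplied")
  if (length(unique(labels)) < 2L) stopf("both classes must be present to build curves")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  ord <- order(probabilities, decreasing = TRUE)
  lab <- labels[ord]
  sc <- probabilities[ord]
  # cumulative counts at each distinct score (ties grouped)
  last_of_group <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab == 1)[last_of_group]
  fp <- cumsum(lab == 0)[last_of_group]
  thr <- sc[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  roc_auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  pr_auc <- sum(diff(c(0, recall)) * precision)
  structure(list(roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
                 pr = data.frame(threshold = thr, recall = recall, precision = precision),
                 roc_auc = roc_auc, pr_auc = pr_auc),
            class = "roc_pr")
}

#' @export
print.roc_pr <- function(x, ...) {
  cat(sprintf("ROC-AUC %.4f  PR-AUC %.4f (%d thresholds)\n",
              x$roc_auc, x$pr_auc, nrow(x$pr)))
  invisible(x)
}

#' Decision curve analysis
#'
#' Net benefit of acting on the model at each threshold probability `p_t`:
#' `NB = TP/n - (FP/n) * p_t / (1 - p_t)` with predictions positive iff
#' `probability >= p_t`, compared against treating everyone (TP = all
#' positives, FP = all negatives) and treating no one (NB = 0).
#'
#' @param labels binary 0/1 outcomes.
#' @param probabilities predicted probabilities.
#' @param thresholds threshold grid in (0, 1); values outside are dropped.
#' @return a data.frame of class `net_benefit_curve` with columns
#'   `threshold`, `nb_model`, `nb_treat_all`, `nb_treat_none`.
#' @export
decision_curve <- function(labels, probabilities,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  check_labels_probs(labels, probabilities)
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(labels)
  n_pos <- sum(labels == 1)
  n_neg <- n - n_pos
  odds <- thresholds / (1 - thresholds)
  nb <- vapply(thresholds, function(p_t) {
    pred <- probabilities >= p_t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tp / n - (fp / n) * p_t / (1 - p_t)
  }, 0)
  out <- data.frame(threshold = thresholds, nb_model = nb,
                    nb_treat_all = n_pos / n - (n_neg / n) * odds,
                    nb_treat_none = 0)
  class(out) <- c("net_benefit_curve", class(out))
  out
}

#' Model comparison metric table
#'
#' Evaluates a named list of fitted models on one cohort partition and lays
#' the results out as a standard comparison table (rows = models; columns =
#' PRE, SEN, SPE, ACC, F1, ROC_AUC, PR_AUC). The error rate is computed but
#' not shown, mirroring the conventional published layout.
#'
#' @param models named list of models supporting [predict_proba()].
#' @param cohort an imputed cohort.
#' @param partition `"train"` or `"test"`.
#' @param threshold classification threshold.
#' @return a data.frame with one row per model.
#' @export
metric_table <- function(models, cohort, partition = "test", threshold = 0.5) {
  rows <- cohort[cohort$partition == partition, , drop = FALSE]
  out <- lapply(names(models), function(nm) {
    p <- predict_proba(models[[nm]], rows)
    m <- confusion_metrics(rows$delirium, p, threshold)
    a <- roc_pr_curves(rows$delirium, p)
    data.frame(model = nm, PRE = m$PRE, SEN = m$SEN, SPE = m$SPE, ACC = m$ACC,
               F1 = m$F1, ROC_AUC = a$roc_auc, PR_AUC = a$pr_auc)
  })
  do.call(rbind, out)
}
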