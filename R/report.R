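#' Default clinical alert rules
#'
#' Marker thresholds with evidence-based recommendations for post-traumatic
#' delirium prevention: lactate above 2 mmol/L flags tissue hypoperfusion and
#' above 4 mmol/L a threshold-effect alert; Clinical Frailty Scale of 5 or
#' more triggers the frailty care bundle; FDP above 20 mg/L flags
#' trauma-induced coagulopathy; GCS of 12 or less marks high-risk impaired
#' consciousness.
#'
#' @return data.frame with columns `marker`, `threshold`, `direction`
#'   (`">"` or `"<="` / `">="`), `recommendation`.
#' @export
default_rules <- function() {
  data.frame(
    marker = c("lactate", "lactate", "cfs", "fdp", "gcs"),
    threshold = c(2, 4, 5, 20, 12),
    direction = c(">", ">", ">=", ">", "<="),
    recommendation = c(
      "Tissue hypoperfusion: optimize fluid resuscitation; consider central venous oxygen saturation monitoring.",
      "Threshold-effect alert: marked delirium risk escalation above 4 mmol/L; intensive hemodynamic support and reassessment.",
      "Frailty bundle: nutritional support (protein >= 1.2 g/kg/day), early mobilization within 24 h, restrict benzodiazepines.",
      "Coagulopathy monitoring: repeat FDP six-hourly; consider tranexamic acid to mitigate microcirculatory dysfunction.",
      "Impaired consciousness: dynamic GCS monitoring, especially with traumatic brain injury; high delirium risk."),
    stringsAsFactors = FALSE)
}

#' Risk report configuration
#'
#' @param cut_low,cut_high probability cut points separating the low /
#'   moderate / high risk tiers.
#' @param rules alert rule table, see [default_rules()].
#' @param n_background background rows used for the Shapley attribution.
#' @return list of class `risk_config`.
#' @export
risk_config <- function(cut_low = 0.3, cut_high = 0.7, rules = default_rules(),
                        n_background = 100L) {
  stopifnot(cut_low < cut_high)
  structure(list(cut_low = cut_low, cut_high = cut_high, rules = rules,
                 n_background = n_background),
            class = "risk_config")
}

rule_fires <- function(rule, value) {
  switch(rule$direction,
         ">" = value > rule$threshold,
         ">=" = value >= rule$threshold,
         "<" = value < rule$threshold,
         "<=" = value <= rule$threshold,
         stopf("unknown rule direction '%s'", rule$direction))
}

#' Patient-level decision-support report
#'
#' Produces the structured report of the clinical decision-support workflow:
#' the predicted delirium probability, a risk tier from the configured cut
#' points, every alert rule whose condition the input satisfies, and a local
#' Shapley attribution of the prediction against a background of training
#' rows.
#'
#' @param model a fitted model supporting [predict_proba()].
#' @param features named list or vector of patient feature values; names must
#'   be valid cohort variables. Features the model selected but the caller
#'   omitted are imputed from the model's stored training statistics.
#' @param background cohort rows for the attribution background (training
#'   rows; a seeded subsample of `config$n_background` rows is used).
#' @param config a [risk_config()].
#' @param seed seed for background subsampling (and the Monte Carlo
#'   attribution fallback when the model uses more than 12 features).
#' @return list of class `risk_report`: `probability`, `tier`,
#'   `triggered_rules` (data.frame), `attribution`.
#' @export
predict_patient <- function(model, features, background,
                            config = risk_config(), seed = 1L) {
  features <- as.list(features)
  valid <- unique(c(model_features(model), names(build_default_spec()$variables)))
  unknown <- setdiff(names(features), valid)
  if (length(unknown)) {
    stopf("unknown feature name(s): %s. Valid names: %s",
          paste(unknown, collapse = ", "), paste(valid, collapse = ", "))
  }
  row <- as.data.frame(lapply(features, as.numeric))
  needed <- model_features(model)
  for (nm in setdiff(needed, names(row))) row[[nm]] <- NA_real_
  row <- apply_imputation(row, imputation_stats_of(model), needed)

  probability <- predict_proba(model, row)
  tier <- if (probability < config$cut_low) "low"
          else if (probability < config$cut_high) "moderate" else "high"

  fired <- lapply(seq_len(nrow(config$rules)), function(i) {
    rule <- config$rules[i, ]
    if (!is.null(features[[rule$marker]]) &&
        rule_fires(rule, as.numeric(features[[rule$marker]]))) rule else NULL
  })
  triggered <- do.call(rbind, fired[!vapply(fired, is.null, TRUE)])
  if (is.null(triggered)) triggered <- config$rules[0, ]

  bg <- background
  if (nrow(bg) > config$n_background) {
    keep <- with_seed(seed, sample.int(nrow(bg), config$n_background))
    bg <- bg[keep, , drop = FALSE]
  }
  attribution <- if (length(needed) <= 12L) {
    shapley_exact(model, row, bg)
  } else {
    shapley_mc(model, row, bg, n_permutations = 200L, seed = seed)
  }

  structure(list(probability = probability, tier = tier,
                 triggered_rules = triggered, attribution = attribution,
                 input = features),
            class = "risk_report")
}

imputation_stats_of <- function(model) {
  if (!is.null(model$imputation_stats)) model$imputation_stats else list()
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("Delirium risk: %.1f%% (%s risk)\n", 100 * x$probability, x$tier))
  if (nrow(x$triggered_rules)) {
    cat("Alerts:\n")
    for (i in seq_len(nrow(x$triggered_rules))) {
      r <- x$triggered_rules[i, ]
      cat(sprintf("  - %s %s %s: %s\n", r$marker, r$direction, r$threshold,
                  r$recommendation))
    }
  } else cat("No alert rules triggered.\n")
  top <- sort(abs(x$attribution$per_feature), decreasing = TRUE)
  cat("Top contributions:", paste(names(top)[seq_len(min(3, length(top)))],
                                  collapse = ", "), "\n")
  invisible(x)
}
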