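#' Describe one synthetic cohort variable
#'
#' A `variable_spec` holds the sampling family and group-conditional parameters
#' for a single predictor of the synthetic polytrauma cohort. Each variable is
#' drawn independently within outcome group from one of four families:
#' `normal` (mean/sd), `lognormal_from_quantiles` (median and quartiles matched
#' on the log scale, with an optional location shift), `bernoulli`
#' (proportion), or `poisson` (rate derived from a target median).
#'
#' For `lognormal_from_quantiles`, `mu = log(median - shift)` and
#' `sigma = (log(q3 - shift) - log(q1 - shift)) / (2 * qnorm(0.75))`, so the
#' analytic median of the fitted distribution equals the specified median
#' exactly (before clipping to the physical bounds).
#'
#' @param name column name.
#' @param role one of `"continuous"`, `"binary"`, `"count"`, `"ordinal"`;
#'   drives imputation (binary variables take the training mode, all others
#'   the training median).
#' @param family sampling family, see Description.
#' @param params_delirium,params_nodelirium named lists of family parameters
#'   for the delirium and no-delirium group respectively:
#'   `normal` needs `mean`, `sd`; `lognormal_from_quantiles` needs `median`,
#'   `q1`, `q3` and optional `shift`; `bernoulli` needs `prob`; `poisson`
#'   needs `median`.
#' @param clip length-2 numeric, physical bounds applied after sampling.
#' @param decimals rounding precision applied after clipping.
#' @param missing_rate per-variable missing-completely-at-random rate used by
#'   [inject_missingness()]; must lie in `[0, 0.05]`.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, role, family, params_delirium, params_nodelirium,
                          clip = c(-Inf, Inf), decimals = 2,
                          missing_rate = 0) {
  role <- match.arg(role, c("continuous", "binary", "count", "ordinal"))
  family <- match.arg(family,
                      c("normal", "lognormal_from_quantiles", "bernoulli", "poisson"))
  if (length(clip) != 2L || !(clip[1] < clip[2])) {
    stopf("variable '%s': clip must satisfy lo < hi", name)
  }
  if (missing_rate < 0 || missing_rate > 0.05) {
    stopf("variable '%s': missing_rate must be in [0, 0.05]", name)
  }
  check <- function(p, grp) {
    switch(family,
      normal = {
        if (!is.numeric(p$mean) || !is.numeric(p$sd) || p$sd <= 0)
          stopf("variable '%s' (%s): normal family needs mean and sd > 0", name, grp)
      },
      lognormal_from_quantiles = {
        shift <- p$shift %||% 0
        if (!(p$q1 < p$median && p$median < p$q3))
          stopf("variable '%s' (%s): need q1 < median < q3", name, grp)
        if (p$q1 - shift <= 0)
          stopf("variable '%s' (%s): quantiles must exceed the shift", name, grp)
      },
      bernoulli = {
        if (p$prob < 0 || p$prob > 1)
          stopf("variable '%s' (%s): bernoulli proportion must be in [0,1]", name, grp)
      },
      poisson = {
        if (!is.numeric(p$median) || p$median < 0)
          stopf("variable '%s' (%s): poisson family needs a non-negative median", name, grp)
      }
    )
  }
  check(params_delirium, "delirium")
  check(params_nodelirium, "no delirium")
  structure(list(name = name, role = role, family = family,
                 params_delirium = params_delirium,
                 params_nodelirium = params_nodelirium,
                 clip = as.numeric(clip), decimals = decimals,
                 missing_rate = missing_rate),
            class = "variable_spec")
}

# Default per-variable MCAR rates. FDP carries the highest rate (0.026); the
# shared rate for the remaining 18 predictors is calibrated so that expected
# overall cell completeness over the 19 predictor columns equals 97.43%:
#   (0.026 + 18 * r) / 19 = 0.0257  =>  r = (19 * 0.0257 - 0.026) / 18
.fdp_missing_rate <- 0.026
.other_missing_rate <- (19 * 0.0257 - .fdp_missing_rate) / 18

#' Default synthetic polytrauma cohort specification
#'
#' Builds the parametric description of the two-group (delirium / no-delirium)
#' synthetic cohort. The 19 candidate predictors are parameterized from
#' published training-set summary statistics of a multicenter polytrauma
#' cohort: mean +/- SD rows become normal draws, median (IQR) rows become
#' lognormal draws matched on median and quartiles, and n (%) rows become
#' Bernoulli draws. Group sizes are fixed at 250/514 (train) and 76/116
#' (test), 956 patients in total with 326 (34.1%) delirium cases.
#'
#' Scale-bounded scores are clipped to their legal ranges (GCS to \[3, 15\],
#' RTS to \[0, 7.84\], CFS to \[1, 9\]), so summary statistics of bounded
#' variables can deviate slightly from the printed values near the bounds.
#' Variables are sampled independently within group; no inter-variable
#' correlation is modelled.
#'
#' @param seed default generation seed stored in the spec (can be overridden
#'   per call in [generate_cohort()]).
#' @return an object of class `cohort_spec` with fields `variables` (named
#'   list of [variable_spec()]s), the four group/partition counts, and `seed`.
#' @examples
#' spec <- build_default_spec()
#' spec$variables$fdp$params_delirium
#' @export
build_default_spec <- function(seed = 1L) {
  v <- list(
    variable_spec("age", "continuous", "normal",
                  list(mean = 77.37, sd = 8.42), list(mean = 58.28, sd = 9.44),
                  clip = c(18, 105), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("sex", "binary", "bernoulli",
                  list(prob = 0.596), list(prob = 0.591),
                  clip = c(0, 1), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("bmi", "continuous", "normal",
                  list(mean = 21.14, sd = 4.32), list(mean = 22.60, sd = 3.88),
                  clip = c(12, 50), decimals = 1,
                  missing_rate = .other_missing_rate),
    variable_spec("cfs", "ordinal", "normal",
                  list(mean = 4.58, sd = 1.15), list(mean = 3.23, sd = 0.68),
                  clip = c(1, 9), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("charlson", "count", "poisson",
                  list(median = 0), list(median = 0),
                  clip = c(0, 20), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("smoking", "binary", "bernoulli",
                  list(prob = 0.172), list(prob = 0.196),
                  clip = c(0, 1), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("alcohol", "binary", "bernoulli",
                  list(prob = 0.348), list(prob = 0.356),
                  clip = c(0, 1), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("sbp", "continuous", "normal",
                  list(mean = 137.75, sd = 23.16), list(mean = 140.85, sd = 24.16),
                  clip = c(50, 260), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("gcs", "ordinal", "lognormal_from_quantiles",
                  list(median = 14, q1 = 13, q3 = 15),
                  list(median = 15, q1 = 14, q3 = 15.5),
                  clip = c(3, 15), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("heart_rate", "continuous", "lognormal_from_quantiles",
                  list(median = 84, q1 = 71, q3 = 101),
                  list(median = 82, q1 = 71, q3 = 93),
                  clip = c(30, 220), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("temperature", "continuous", "lognormal_from_quantiles",
                  list(median = 36.3, q1 = 36.0, q3 = 36.8, shift = 30),
                  list(median = 36.5, q1 = 36.1, q3 = 36.9, shift = 30),
                  clip = c(34, 42), decimals = 1,
                  missing_rate = .other_missing_rate),
    variable_spec("hemoglobin", "continuous", "normal",
                  list(mean = 121.83, sd = 20.67), list(mean = 137.56, sd = 17.89),
                  clip = c(30, 220), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("fibrinogen", "continuous", "normal",
                  list(mean = 259.78, sd = 42.17), list(mean = 257.88, sd = 44.35),
                  clip = c(50, 700), decimals = 1,
                  missing_rate = .other_missing_rate),
    variable_spec("fdp", "continuous", "normal",
                  list(mean = 60.56, sd = 18.79), list(mean = 16.74, sd = 8.22),
                  clip = c(0, 300), decimals = 2,
                  missing_rate = .fdp_missing_rate),
    variable_spec("lactate", "continuous", "lognormal_from_quantiles",
                  list(median = 2.3, q1 = 1.5, q3 = 4.0),
                  list(median = 2.1, q1 = 1.6, q3 = 2.9),
                  clip = c(0.2, 25), decimals = 1,
                  missing_rate = .other_missing_rate),
    variable_spec("crp", "continuous", "lognormal_from_quantiles",
                  list(median = 9, q1 = 3, q3 = 40),
                  list(median = 5, q1 = 2, q3 = 14),
                  clip = c(0.1, 400), decimals = 1,
                  missing_rate = .other_missing_rate),
    variable_spec("rts", "continuous", "lognormal_from_quantiles",
                  list(median = 7.83, q1 = 7.24, q3 = 7.88),
                  list(median = 7.86, q1 = 7.84, q3 = 7.94),
                  clip = c(0, 7.84), decimals = 2,
                  missing_rate = .other_missing_rate),
    variable_spec("iss", "count", "lognormal_from_quantiles",
                  list(median = 18, q1 = 10, q3 = 27),
                  list(median = 12, q1 = 9, q3 = 19),
                  clip = c(1, 75), decimals = 0,
                  missing_rate = .other_missing_rate),
    variable_spec("tbi", "binary", "bernoulli",
                  list(prob = 0.468), list(prob = 0.418),
                  clip = c(0, 1), decimals = 0,
                  missing_rate = .other_missing_rate)
  )
  names(v) <- vapply(v, `[[`, "", "name")
  cohort_spec(variables = v, seed = seed)
}

#' Assemble a cohort specification
#'
#' @param variables named list of [variable_spec()] objects.
#' @param n_train_delirium,n_train_control,n_test_delirium,n_test_control
#'   group-by-partition patient counts; the default four counts sum to 956.
#' @param seed default generation seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(variables,
                        n_train_delirium = 250L, n_train_control = 514L,
                        n_test_delirium = 76L, n_test_control = 116L,
                        seed = 1L) {
  if (!length(variables)) stopf("cohort_spec needs at least one variable")
  if (is.null(names(variables)) || anyDuplicated(names(variables))) {
    stopf("cohort_spec variables must be uniquely named")
  }
  structure(list(variables = variables,
                 n_train_delirium = as.integer(n_train_delirium),
                 n_train_control = as.integer(n_train_control),
                 n_test_delirium = as.integer(n_test_delirium),
                 n_test_control = as.integer(n_test_control),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  n <- x$n_train_delirium + x$n_train_control + x$n_test_delirium + x$n_test_control
  cat(sprintf("Synthetic cohort spec: %d variables, %d patients (train %d/%d, test %d/%d)\n",
              length(x$variables), n,
              x$n_train_delirium, x$n_train_control,
              x$n_test_delirium, x$n_test_control))
  invisible(x)
}

# Fitted log-scale parameters for a lognormal_from_quantiles variable.
lognormal_pars <- function(p) {
  shift <- p$shift %||% 0
  z75 <- stats::qnorm(0.75)
  mu <- log(p$median - shift)
  sigma <- (log(p$q3 - shift) - log(p$q1 - shift)) / (2 * z75)
  list(mu = mu, sigma = sigma, shift = shift)
}

# One group's sample for a single variable, using the ambient RNG stream.
sample_variable <- function(vs, params, n) {
  x <- switch(vs$family,
    normal = stats::rnorm(n, params$mean, params$sd),
    lognormal_from_quantiles = {
      lp <- lognormal_pars(params)
      lp$shift + stats::rlnorm(n, lp$mu, lp$sigma)
    },
    bernoulli = stats::rbinom(n, 1L, params$prob),
    poisson = stats::rpois(n, params$median + 1 / 3),
    stopf("unknown sampling family '%s' for variable '%s'", vs$family, vs$name)
  )
  round_half_up(clip(x, vs$clip[1], vs$clip[2]), vs$decimals)
}
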