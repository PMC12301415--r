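#' Generate a synthetic polytrauma cohort
#'
#' Realizes a [cohort_spec()] as a patient table: one row per patient at the
#' spec's exact group-by-partition counts, each variable drawn independently
#' from its group's family, clipped to the physical bounds and rounded.
#' Identical `(spec, seed)` pairs yield bit-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer generation seed; defaults to `spec$seed`.
#' @return a `data.frame` of class `cohort` with one column per variable plus
#'   `delirium` (0/1 outcome) and `partition` (`"train"`/`"test"`).
#' @examples
#' cohort <- generate_cohort(build_default_spec(), seed = 7)
#' table(cohort$partition, cohort$delirium)
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_del <- spec$n_train_delirium + spec$n_test_delirium
  n_ctl <- spec$n_train_control + spec$n_test_control
  with_seed(seed, {
    cols <- lapply(spec$variables, function(vs) {
      c(sample_variable(vs, vs$params_delirium, n_del),
        sample_variable(vs, vs$params_nodelirium, n_ctl))
    })
    cohort <- as.data.frame(cols, check.names = FALSE)
    cohort$delirium <- rep(c(1L, 0L), c(n_del, n_ctl))
    split_cohort(cohort, spec)
  })
}

#' Assign the train/test partition
#'
#' Tags each row `"train"` or `"test"`, stratified by outcome so the exact
#' published counts are reproduced: 764 training patients (250 delirium) and
#' 192 test patients (76 delirium) under the default spec. Assignment is
#' deterministic by row order within each outcome group (rows are exchangeable
#' draws, so order carries no information).
#'
#' @param cohort a cohort `data.frame` with a `delirium` column.
#' @param spec the [cohort_spec()] providing the partition counts.
#' @return the cohort with a `partition` column, class `cohort`.
#' @export
split_cohort <- function(cohort, spec = build_default_spec()) {
  if (is.null(cohort$delirium)) stopf("cohort carries no `delirium` label column")
  n_del <- sum(cohort$delirium == 1L)
  n_ctl <- sum(cohort$delirium == 0L)
  if (n_del != spec$n_train_delirium + spec$n_test_delirium ||
      n_ctl != spec$n_train_control + spec$n_test_control) {
    stopf("cohort group sizes (%d delirium / %d control) do not match the spec (%d / %d)",
          n_del, n_ctl,
          spec$n_train_delirium + spec$n_test_delirium,
          spec$n_train_control + spec$n_test_control)
  }
  partition <- character(nrow(cohort))
  idx_del <- which(cohort$delirium == 1L)
  idx_ctl <- which(cohort$delirium == 0L)
  partition[idx_del] <- rep(c("train", "test"),
                            c(spec$n_train_delirium, spec$n_test_delirium))
  partition[idx_ctl] <- rep(c("train", "test"),
                            c(spec$n_train_control, spec$n_test_control))
  cohort$partition <- partition
  class(cohort) <- unique(c("cohort", class(cohort)))
  cohort
}

#' Mask cells missing-completely-at-random
#'
#' Applies each variable's `missing_rate` independently per cell. Under the
#' default spec the expected overall cell completeness across the 19 predictor
#' columns is 97.43%, with fibrin degradation products (FDP) carrying the
#' single highest per-variable rate (2.6%).
#'
#' @param cohort a complete cohort.
#' @param spec the governing [cohort_spec()].
#' @param seed masking seed.
#' @return the cohort with `NA`s injected into predictor columns.
#' @export
inject_missingness <- function(cohort, spec = build_default_spec(), seed = spec$seed) {
  rates <- vapply(spec$variables, `[[`, 0, "missing_rate")
  if (any(rates > 0.05)) stopf("missing rates above 0.05 are not supported")
  with_seed(seed, {
    for (nm in names(spec$variables)) {
      r <- spec$variables[[nm]]$missing_rate
      if (r > 0) {
        mask <- stats::runif(nrow(cohort)) < r
        cohort[[nm]][mask] <- NA
      }
    }
  })
  cohort
}

#' Fraction of observed predictor cells
#'
#' @param cohort a cohort.
#' @param variables predictor columns to count; defaults to every column
#'   except `delirium` and `partition`.
#' @return proportion of non-missing cells in `[0, 1]`.
#' @export
completeness <- function(cohort, variables = setdiff(names(cohort), c("delirium", "partition"))) {
  cells <- as.matrix(cohort[variables])
  1 - mean(is.na(cells))
}

#' Impute missing cells with training-partition statistics
#'
#' Continuous, count and ordinal columns are filled with the median of the
#' observed training-partition values; binary columns with the training-
#' partition mode. Statistics are estimated on the training rows only and
#' reused verbatim for the test rows, so no information leaks across the
#' split. The fitted statistics are attached as attribute
#' `"imputation_stats"` for reuse at prediction time.
#'
#' @param cohort a cohort, possibly containing `NA` cells.
#' @param spec the governing [cohort_spec()] (supplies variable roles).
#' @return the cohort with no missing predictor cells.
#' @export
impute_cohort <- function(cohort, spec = build_default_spec()) {
  vars <- intersect(names(spec$variables), names(cohort))
  train <- cohort[cohort$partition == "train", , drop = FALSE]
  stats_out <- list()
  for (nm in vars) {
    obs <- train[[nm]][!is.na(train[[nm]])]
    if (!length(obs)) stopf("column '%s' is entirely missing in the training partition", nm)
    fill <- if (spec$variables[[nm]]$role == "binary") {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])
    } else {
      stats::median(obs)
    }
    stats_out[[nm]] <- fill
    cohort[[nm]][is.na(cohort[[nm]])] <- fill
  }
  attr(cohort, "imputation_stats") <- stats_out
  cohort
}

#' Write / read a cohort as CSV
#'
#' One patient per row, predictor columns in spec order plus `delirium` and
#' `partition`; missing cells are empty strings. A write/read round-trip of a
#' seeded cohort is bit-identical.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `cohort` data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if (!is.null(cohort$partition)) class(cohort) <- unique(c("cohort", class(cohort)))
  cohort
}
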