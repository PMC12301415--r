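test_that("default spec encodes the published group parameters", {
  spec <- default_spec()
  expect_length(spec$variables, 19L)
  expect_equal(spec$variables$fdp$params_delirium, list(mean = 60.56, sd = 18.79))
  expect_equal(spec$variables$tbi$params_delirium$prob, 0.468)
  expect_equal(spec$variables$age$params_nodelirium, list(mean = 58.28, sd = 9.44))
  total <- spec$n_train_delirium + spec$n_train_control +
    spec$n_test_delirium + spec$n_test_control
  expect_identical(total, 956L)
  expect_equal(spec$variables$fdp$missing_rate, 0.026)
  rates <- vapply(spec$variables, `[[`, 0, "missing_rate")
  expect_true(all(rates >= 0 & rates <= 0.05))
  expect_identical(names(rates)[which.max(rates)], "fdp")
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(variable_spec("x", "continuous", "normal",
                             list(mean = 1, sd = 0), list(mean = 1, sd = 1)),
               "sd > 0")
  expect_error(variable_spec("x", "binary", "bernoulli",
                             list(prob = 1.2), list(prob = 0.5)),
               "proportion")
  expect_error(variable_spec("x", "continuous", "lognormal_from_quantiles",
                             list(median = 5, q1 = 6, q3 = 7),
                             list(median = 5, q1 = 4, q3 = 7)),
               "q1 < median < q3")
  expect_error(variable_spec("x", "continuous", "normal",
                             list(mean = 0, sd = 1), list(mean = 0, sd = 1),
                             clip = c(2, 1)),
               "lo < hi")
  expect_error(variable_spec("x", "continuous", "normal",
                             list(mean = 0, sd = 1), list(mean = 0, sd = 1),
                             missing_rate = 0.2),
               "missing_rate")
})

test_that("generated cohorts reproduce the exact published composition", {
  co <- cohort7()
  expect_identical(nrow(co), 956L)
  expect_identical(sum(co$delirium), 326L)
  tab <- table(co$partition, co$delirium)
  expect_identical(as.integer(tab["train", "1"]), 250L)
  expect_identical(as.integer(tab["train", "0"]), 514L)
  expect_identical(as.integer(tab["test", "1"]), 76L)
  expect_identical(as.integer(tab["test", "0"]), 116L)
  expect_setequal(unique(co$partition), c("train", "test"))
})

test_that("generation is seed-deterministic through a CSV round-trip", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(default_spec(), 11), f1)
  write_cohort(generate_cohort(default_spec(), 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_cohort(f1)
  expect_equal(nrow(back), 956L)
  expect_false(identical(readLines(f1),
                         {write_cohort(generate_cohort(default_spec(), 12), f2); readLines(f2)}))
})

test_that("group marginals stay within sampling error of their targets", {
  co <- cohort7()
  spec <- default_spec()
  for (nm in c("age", "bmi", "fdp", "hemoglobin", "sbp")) {
    for (grp in c(1, 0)) {
      p <- if (grp == 1) spec$variables[[nm]]$params_delirium else spec$variables[[nm]]$params_nodelirium
      x <- co[[nm]][co$delirium == grp]
      se <- p$sd / sqrt(length(x))
      expect_lt(abs(mean(x) - p$mean), 3 * se,
                label = sprintf("|mean(%s) - target| in group %d", nm, grp))
    }
  }
})

test_that("degenerate and bounded families behave as specified", {
  spec <- cohort_spec(list(always = variable_spec(
    "always", "binary", "bernoulli", list(prob = 1), list(prob = 1),
    clip = c(0, 1), decimals = 0)),
    n_train_delirium = 10L, n_train_control = 10L,
    n_test_delirium = 5L, n_test_control = 5L)
  co <- generate_cohort(spec, 3)
  expect_true(all(co$always == 1))
  # clip bounds respected everywhere
  co7 <- cohort7()
  for (nm in names(default_spec()$variables)) {
    cl <- default_spec()$variables[[nm]]$clip
    expect_true(all(co7[[nm]] >= cl[1] & co7[[nm]] <= cl[2]), label = nm)
  }
  expect_true(all(co7$gcs >= 3 & co7$gcs <= 15))
  expect_true(all(co7$rts <= 7.84))
})

test_that("lognormal quantile matching reproduces the published median analytically", {
  spec <- default_spec()
  for (nm in c("gcs", "heart_rate", "temperature", "lactate", "crp", "rts", "iss")) {
    p <- spec$variables[[nm]]$params_delirium
    lp <- delirisk:::lognormal_pars(p)
    expect_equal(lp$shift + exp(lp$mu), p$median, tolerance = 1e-9, label = nm)
  }
})

test_that("split is a disjoint exhaustive partition and errors on bad counts", {
  co <- cohort7()
  expect_identical(sum(co$partition == "train"), 764L)
  expect_identical(sum(co$partition == "test"), 192L)
  expect_identical(sum(co$partition %in% c("train", "test")), nrow(co))
  bad <- co[-1, ]
  expect_error(split_cohort(bad, default_spec()), "do not match")
  expect_error(split_cohort(data.frame(x = 1)), "delirium")
})

test_that("missingness injection hits the configured completeness", {
  spec <- default_spec()
  co <- inject_missingness(cohort7(), spec, 8)
  comp <- completeness(co)
  expect_lt(abs(comp - 0.9743), 0.003)
  # FDP carries the highest missing rate
  miss_by_var <- vapply(names(spec$variables), function(nm) mean(is.na(co[[nm]])), 0)
  expect_lt(abs(miss_by_var[["fdp"]] - 0.026), 0.015)
  # rates all zero leaves the cohort untouched
  spec0 <- spec
  for (nm in names(spec0$variables)) spec0$variables[[nm]]$missing_rate <- 0
  expect_identical(inject_missingness(cohort7(), spec0, 8), cohort7())
  # expected FDP missing count ~ binomial(956, 0.026) ~= 25
  n_fdp_missing <- mean(replicate(20, sum(is.na(inject_missingness(cohort7(), spec, sample.int(1e6, 1))$fdp))))
  expect_lt(abs(n_fdp_missing - 956 * 0.026), 3 * sqrt(956 * 0.026 * 0.974 / 20))
})

test_that("imputation uses training statistics, removes all NAs, and is idempotent", {
  spec <- default_spec()
  co <- inject_missingness(cohort7(), spec, 8)
  imp <- impute_cohort(co, spec)
  expect_identical(sum(is.na(imp[names(spec$variables)])), 0L)
  # continuous fills equal the observed training median
  tr <- co[co$partition == "train", ]
  med_fdp <- median(tr$fdp[!is.na(tr$fdp)])
  filled <- imp$fdp[is.na(co$fdp)]
  expect_true(all(filled == med_fdp))
  # binary fills equal the training mode
  tr_sex <- tr$sex[!is.na(tr$sex)]
  mode_sex <- as.numeric(names(which.max(table(tr_sex))))
  expect_true(all(imp$sex[is.na(co$sex)] == mode_sex))
  # idempotence and identity on complete data
  expect_identical(as.data.frame(impute_cohort(imp, spec))[names(spec$variables)],
                   as.data.frame(imp)[names(spec$variables)])
  clean <- impute_cohort(cohort7(), spec)
  expect_identical(as.data.frame(clean)[names(spec$variables)],
                   as.data.frame(cohort7())[names(spec$variables)])
  # fully-missing column errors by name
  broken <- co
  broken$lactate <- NA_real_
  expect_error(impute_cohort(broken, spec), "lactate")
})

test_that("toy median and mode fills match hand arithmetic", {
  spec <- cohort_spec(list(
    x = variable_spec("x", "continuous", "normal", list(mean = 0, sd = 1),
                      list(mean = 0, sd = 1)),
    b = variable_spec("b", "binary", "bernoulli", list(prob = 0.5), list(prob = 0.5))),
    n_train_delirium = 2L, n_train_control = 2L,
    n_test_delirium = 1L, n_test_control = 1L)
  co <- data.frame(x = c(1, 2, NA, 4, 1, 1), b = c(1, 1, 0, NA, 1, 0),
                   delirium = c(1, 1, 0, 0, 1, 0),
                   partition = c("train", "train", "train", "train", "test", "test"))
  imp <- impute_cohort(co, spec)
  expect_equal(imp$x[3], 2)  # median of {1, 2, 4}
  expect_equal(imp$b[4], 1)  # mode of {1, 1, 0}
})
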