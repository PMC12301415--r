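# Classical test functions, all written with their global minimum at the
# origin (value 0) unless noted, so shifted/rotated variants can document
# their optimum analytically.

f_sphere <- function(z) sum(z^2)
f_rastrigin <- function(z) sum(z^2 - 10 * cos(2 * pi * z) + 10)
f_ackley <- function(z) {
  d <- length(z)
  -20 * exp(-0.2 * sqrt(sum(z^2) / d)) - exp(sum(cos(2 * pi * z)) / d) + 20 + exp(1)
}
f_griewank <- function(z) sum(z^2) / 4000 - prod(cos(z / sqrt(seq_along(z)))) + 1
f_zakharov <- function(z) {
  s <- sum(0.5 * seq_along(z) * z)
  sum(z^2) + s^2 + s^4
}
f_rosenbrock <- function(z) {        # minimum 0 at z = 1
  d <- length(z)
  sum(100 * (z[-1] - z[-d]^2)^2 + (1 - z[-d])^2)
}
f_levy <- function(z) {              # minimum 0 at z = 1
  w <- 1 + (z - 1) / 4
  d <- length(w)
  sin(pi * w[1])^2 +
    sum((w[-d] - 1)^2 * (1 + 10 * sin(pi * w[-d] + 1)^2)) +
    (w[d] - 1)^2 * (1 + sin(2 * pi * w[d])^2)
}

# Lunacek bi-Rastrigin: two unequal sphere basins plus a Rastrigin ripple;
# global minimum 0 at z = mu0.
f_lunacek <- function(z, mu0 = 2.5) {
  d <- length(z)
  s <- 1 - 1 / (2 * sqrt(d + 20) - 8.2)
  mu1 <- -sqrt((mu0^2 - 1) / s)
  min(sum((z - mu0)^2), d + s * sum((z - mu1)^2)) +
    10 * (d - sum(cos(2 * pi * (z - mu0))))
}

# Seeded random orthogonal matrix (QR of a Gaussian matrix, signs fixed).
random_rotation <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), d)
}

#' Benchmark suite for optimizer validation
#'
#' Builds 12 box-bounded test functions at the requested dimension for
#' validating swarm optimizers: unimodal (sphere, Zakharov, Rosenbrock),
#' multimodal (Rastrigin, Ackley, Griewank, Levy, Schwefel, Lunacek
#' bi-Rastrigin), and three hybrid functions that apply a seeded random
#' orthogonal rotation and shift to a pair of the base forms. The simple
#' functions carry seeded random shift vectors (drawn from the central 20% of
#' the box) so the optimum never sits at the origin; Schwefel and the Lunacek
#' bi-Rastrigin keep their canonical optima. Every function documents its
#' global minimizer and minimum value, accurate to well below 1e-9.
#'
#' @param dim dimension (at least 2).
#' @param seed seed for the shift vectors and rotations.
#' @return a list of class `benchmark_suite` holding 12 [objective_fn()]s.
#' @export
make_suite <- function(dim = 10L, seed = 1L) {
  stopifnot(dim >= 2L)
  with_seed(seed, {
    shifted <- function(base, name, half_range, opt_offset = 0) {
      # shift drawn from the central fifth of the box; optimum at s + offset
      s <- stats::runif(dim, -0.2 * half_range, 0.2 * half_range)
      objective_fn(function(x) base(x - s), dim,
                   lower = -half_range, upper = half_range, name = name,
                   known_optimum = 0, optimum_position = s + opt_offset)
    }
    hybrid <- function(base1, base2, name, half_range) {
      s <- stats::runif(dim, -0.2 * half_range, 0.2 * half_range)
      R <- random_rotation(dim)
      d1 <- floor(dim / 2)
      objective_fn(function(x) {
        z <- as.numeric(R %*% (x - s))
        base1(z[seq_len(d1)]) + base2(z[(d1 + 1):dim])
      }, dim, lower = -half_range, upper = half_range, name = name,
      known_optimum = 0, optimum_position = s)
    }
    # per-dimension Schwefel minimizer refined numerically once per suite
    sw <- stats::optimize(function(x) -x * sin(sqrt(x)), c(400, 440), tol = 1e-12)
    schwefel <- objective_fn(function(x) sum(-x * sin(sqrt(abs(x))) + (-sw$objective)),
                             dim, lower = -500, upper = 500, name = "schwefel",
                             known_optimum = 0,
                             optimum_position = rep(sw$minimum, dim))
    lunacek <- objective_fn(f_lunacek, dim, lower = -5.12, upper = 5.12,
                            name = "lunacek_bi_rastrigin", known_optimum = 0,
                            optimum_position = rep(2.5, dim))
    fns <- list(
      shifted(f_sphere, "sphere", 100),
      shifted(f_rosenbrock, "rosenbrock", 30, opt_offset = 1),
      shifted(f_rastrigin, "rastrigin", 5.12),
      shifted(f_ackley, "ackley", 32.768),
      shifted(f_griewank, "griewank", 600),
      shifted(f_zakharov, "zakharov", 10),
      shifted(f_levy, "levy", 10, opt_offset = 1),
      schwefel,
      lunacek,
      hybrid(f_rastrigin, f_sphere, "hybrid_rastrigin_sphere", 10),
      hybrid(f_ackley, f_griewank, "hybrid_ackley_griewank", 30),
      hybrid(f_zakharov, f_rastrigin, "hybrid_zakharov_rastrigin", 10)
    )
  })
  names(fns) <- vapply(fns, `[[`, "", "name")
  structure(list(functions = fns, dim = as.integer(dim), seed = as.integer(seed)),
            class = "benchmark_suite")
}

#' Compare optimizer configurations on a benchmark suite
#'
#' Runs [run_trials()] for every function x configuration, computes stability
#' statistics, pairwise two-sided Wilcoxon rank-sum tests between algorithms
#' on the per-run best fitnesses, and mean convergence curves. Run seeds are
#' derived identically for every configuration (base seed + function offset +
#' run index) so comparisons are paired.
#'
#' @param suite a [make_suite()] result.
#' @param configs named list of [optimizer_config()]s (names label the
#'   algorithms; unnamed lists are labelled by variant).
#' @param n_runs independent runs per function x algorithm.
#' @return list of class `benchmark_comparison`: `table` (one row per
#'   function x algorithm with mean/sd/median/min/max), `per_run` (long
#'   data.frame for boxplots), `pvalues` (function x pair rank-sum p-values),
#'   `curves` (long data.frame of mean best-so-far per iteration).
#' @export
compare_algorithms <- function(suite, configs, n_runs = 10L) {
  stopifnot(inherits(suite, "benchmark_suite"), length(configs) >= 2L)
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, `[[`, "", "variant")
  }
  rows <- list(); per_run <- list(); curves <- list(); pvals <- list()
  for (fi in seq_along(suite$functions)) {
    fn <- suite$functions[[fi]]
    trials <- lapply(names(configs), function(alg) {
      cfg <- configs[[alg]]
      cfg$seed <- cfg$seed + 1000L * fi
      run_trials(fn, cfg, n_runs, keep_history = TRUE)
    })
    names(trials) <- names(configs)
    for (alg in names(configs)) {
      tr <- trials[[alg]]
      rows[[length(rows) + 1L]] <- data.frame(
        func = fn$name, algorithm = alg, mean = tr$mean, sd = tr$sd,
        median = tr$median, min = tr$min, max = tr$max)
      per_run[[length(per_run) + 1L]] <- data.frame(
        func = fn$name, algorithm = alg, run = seq_len(n_runs), best = tr$per_run)
      curves[[length(curves) + 1L]] <- data.frame(
        func = fn$name, algorithm = alg,
        iteration = seq_len(nrow(tr$history)),
        mean_best = rowMeans(tr$history))
    }
    pairs <- utils::combn(names(configs), 2L)
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      x <- trials[[a]]$per_run; y <- trials[[b]]$per_run
      pv <- if (isTRUE(all.equal(x, y))) 1 else
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
      pvals[[length(pvals) + 1L]] <- data.frame(
        func = fn$name, algorithm_a = a, algorithm_b = b, p_value = pv)
    }
  }
  structure(list(table = do.call(rbind, rows),
                 per_run = do.call(rbind, per_run),
                 pvalues = do.call(rbind, pvals),
                 curves = do.call(rbind, curves)),
            class = "benchmark_comparison")
}

#' Write a benchmark comparison to CSV files
#'
#' @param comparison a [compare_algorithms()] result.
#' @param dir output directory (created if absent); writes `summary.csv`,
#'   `per_run.csv`, `pvalues.csv`, `curves.csv`.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(comparison$table, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(comparison$per_run, file.path(dir, "per_run.csv"), row.names = FALSE)
  utils::write.csv(comparison$pvalues, file.path(dir, "pvalues.csv"), row.names = FALSE)
  utils::write.csv(comparison$curves, file.path(dir, "curves.csv"), row.names = FALSE)
  invisible(dir)
}
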