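#' Define a box-bounded continuous minimization problem
#'
#' @param fn objective, a function of a numeric vector returning a finite
#'   scalar; lower is better.
#' @param dim problem dimension.
#' @param lower,upper bounds, scalars or length-`dim` vectors.
#' @param name label used in reports.
#' @param known_optimum optional documented global minimum value.
#' @param optimum_position optional documented minimizer.
#' @return an object of class `objective_fn`.
#' @export
objective_fn <- function(fn, dim, lower, upper, name = "objective",
                         known_optimum = NULL, optimum_position = NULL) {
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower >= upper)) stopf("objective '%s': lower must be < upper elementwise", name)
  structure(list(fn = fn, dim = as.integer(dim), lower = lower, upper = upper,
                 name = name, known_optimum = known_optimum,
                 optimum_position = optimum_position),
            class = "objective_fn")
}

#' Optimizer run settings
#'
#' @param population_size number of agents (water parcels), at least 4.
#' @param max_iterations iteration budget.
#' @param seed RNG seed fixing the whole run.
#' @param variant `"ifla"` (sine-map initialization + Cauchy mutation),
#'   `"fla"` (baseline Flood Algorithm), or `"random"` (uniform random search
#'   at the same evaluation budget, for calibration).
#' @param overflow_fraction fraction of the population reinitialized during an
#'   overflow event; also scales the (decaying) event probability.
#' @param mutation_scale0 initial Cauchy mutation scale as a proportion of the
#'   box range (IFLA only).
#' @param sine_map_gain gain of the chaotic sine map used for initialization.
#' @return an object of class `optimizer_config`.
#' @export
optimizer_config <- function(population_size = 30L, max_iterations = 500L,
                             seed = 1L, variant = c("ifla", "fla", "random"),
                             overflow_fraction = 0.1, mutation_scale0 = 0.1,
                             sine_map_gain = 0.99) {
  variant <- match.arg(variant)
  if (population_size < 4L) stopf("population_size must be at least 4")
  if (max_iterations < 1L) stopf("max_iterations must be at least 1")
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), variant = variant,
                 overflow_fraction = overflow_fraction,
                 mutation_scale0 = mutation_scale0,
                 sine_map_gain = sine_map_gain),
            class = "optimizer_config")
}

#' Chaotic sine-map orbit
#'
#' Iterates `c_{k+1} = gain * |sin(pi * c_k)|`, the chaotic recurrence used to
#' spread IFLA's initial population more ergodically than uniform sampling.
#' Orbits falling below `1e-6` are restarted from a fresh uniform draw (using
#' the ambient RNG stream) to avoid the absorbing orbit at zero.
#'
#' @param c0 starting value in (0, 1).
#' @param gain map gain in (0, 1].
#' @param length number of iterates to return.
#' @return numeric vector of `length` iterates, all in `[0, gain]`.
#' @examples
#' sine_map_sequence(0.5, gain = 1, length = 2)  # first iterate is exactly 1
#' @export
sine_map_sequence <- function(c0, gain = 0.99, length = 1L) {
  if (!is.numeric(c0) || c0 <= 0 || c0 >= 1) stopf("c0 must lie strictly in (0, 1)")
  if (gain <= 0 || gain > 1) stopf("gain must lie in (0, 1]")
  out <- numeric(length)
  c_k <- c0
  for (k in seq_len(length)) {
    c_k <- gain * abs(sin(pi * c_k))
    if (c_k < 1e-6) c_k <- stats::runif(1)
    out[k] <- c_k
  }
  out
}

#' Initial population of candidate positions
#'
#' IFLA seeds each dimension from an independent sine-map orbit mapped onto
#' the box; FLA and random search use plain uniform draws. Deterministic given
#' `config$seed`.
#'
#' @param objective an [objective_fn()].
#' @param config an [optimizer_config()].
#' @return a `population_size` x `dim` matrix of in-bounds positions.
#' @export
initialize_population <- function(objective, config) {
  with_seed(config$seed, init_population_impl(objective, config))
}

init_population_impl <- function(objective, config) {
  n <- config$population_size
  d <- objective$dim
  rng <- objective$upper - objective$lower
  if (config$variant == "ifla") {
    cols <- lapply(seq_len(d), function(j) {
      orbit <- sine_map_sequence(stats::runif(1), config$sine_map_gain, n)
      objective$lower[j] + orbit * rng[j]
    })
    do.call(cbind, cols)
  } else {
    matrix(stats::runif(n * d), n, d) %*% diag(rng, d) +
      matrix(objective$lower, n, d, byrow = TRUE)
  }
}

#' Heavy-tailed Cauchy perturbation
#'
#' Adds `scale * C` to a position, where `C` is standard Cauchy sampled by
#' inverse CDF (`tan(pi * (u - 1/2))`, `u` uniform), then clips to the bounds.
#' The heavy tail produces occasional long jumps that let the search escape
#' local optima. Uses the ambient RNG stream.
#'
#' @param position numeric position vector.
#' @param scale positive per-dimension scale vector.
#' @param lower,upper box bounds for clipping.
#' @return the perturbed, clipped position.
#' @export
cauchy_perturb <- function(position, scale, lower, upper) {
  if (any(scale <= 0)) stopf("cauchy_perturb: scale must be positive")
  u <- stats::runif(length(position))
  clip(position + scale * tan(pi * (u - 0.5)), lower, upper)
}

eval_position <- function(objective, x) {
  f <- objective$fn(x)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
    stopf("objective '%s' returned a non-finite value at position (%s)",
          objective$name, paste(signif(x, 6), collapse = ", "))
  }
  f
}

eval_rows <- function(objective, X) {
  vapply(seq_len(nrow(X)), function(i) eval_position(objective, X[i, ]), 0)
}

#' Run the Flood Algorithm
#'
#' Population-based continuous minimizer. Each iteration every agent proposes
#' a "downhill flow" move toward the global best plus a differential diffusion
#' term, `y_i = x_i + r1 * (x_best - x_i) + r2 * (x_a - x_b)` with `r1`, `r2`
#' per-dimension uniform and `a`, `b` distinct random agents; proposals are
#' clipped to the box and accepted greedily. With a linearly decaying
#' probability an "overflow" event reinitializes the worst agents uniformly
#' (their proposal for that iteration). The IFLA variant additionally starts
#' from a chaotic sine-map population and, once per iteration, applies a
#' Cauchy mutation with linearly decaying scale to one random coordinate of
#' the global best; the mutant replaces the best on improvement and otherwise
#' reseeds the worst agent when it beats it. Best-so-far fitness is
#' non-increasing for every variant.
#'
#' @param objective an [objective_fn()].
#' @param config an [optimizer_config()].
#' @return an object of class `fla_result`: `best_position`, `best_fitness`,
#'   `history` (best-so-far per iteration, non-increasing), `evaluations`,
#'   and the `config` used.
#' @examples
#' sphere <- objective_fn(function(x) sum(x^2), dim = 2, lower = -5, upper = 5)
#' res <- fla_optimize(sphere, optimizer_config(seed = 1, max_iterations = 100))
#' res$best_fitness
#' @export
fla_optimize <- function(objective, config = optimizer_config()) {
  stopifnot(inherits(objective, "objective_fn"), inherits(config, "optimizer_config"))
  with_seed(config$seed, fla_optimize_impl(objective, config))
}

fla_optimize_impl <- function(objective, config) {
  n <- config$population_size
  d <- objective$dim
  lo <- objective$lower
  up <- objective$upper
  rng <- up - lo
  T_max <- config$max_iterations

  X <- init_population_impl(objective, config)
  f <- eval_rows(objective, X)
  evals <- n
  best_i <- which.min(f)
  best_x <- X[best_i, ]
  best_f <- f[best_i]
  history <- numeric(T_max)

  uniform_rows <- function(k) {
    matrix(stats::runif(k * d), k, d) %*% diag(rng, d) +
      matrix(lo, k, d, byrow = TRUE)
  }

  for (t in seq_len(T_max)) {
    if (config$variant == "random") {
      Y <- uniform_rows(n)
      fy <- eval_rows(objective, Y)
      evals <- evals + n
      X <- Y; f <- fy
    } else {
      # overflow: worst agents take a uniform reinit as this iteration's
      # proposal (unconditional), so the per-iteration budget stays n evals
      reinit <- rep(FALSE, n)
      p_overflow <- config$overflow_fraction * (1 - t / T_max)
      if (stats::runif(1) < p_overflow) {
        k <- ceiling(config$overflow_fraction * n)
        reinit[order(f, decreasing = TRUE)[seq_len(k)]] <- TRUE
      }
      ab <- t(vapply(seq_len(n), function(i) sample.int(n, 2L), c(0L, 0L)))
      r1 <- matrix(stats::runif(n * d), n, d)
      r2 <- matrix(stats::runif(n * d), n, d)
      Y <- X + r1 * (matrix(best_x, n, d, byrow = TRUE) - X) +
        r2 * (X[ab[, 1L], , drop = FALSE] - X[ab[, 2L], , drop = FALSE])
      Y <- clip(Y, matrix(lo, n, d, byrow = TRUE), matrix(up, n, d, byrow = TRUE))
      if (any(reinit)) Y[reinit, ] <- uniform_rows(sum(reinit))
      fy <- eval_rows(objective, Y)
      evals <- evals + n
      accept <- reinit | (fy < f)
      X[accept, ] <- Y[accept, , drop = FALSE]
      f[accept] <- fy[accept]
    }
    if (min(f) < best_f) {
      best_i <- which.min(f)
      best_x <- X[best_i, ]
      best_f <- f[best_i]
    }
    if (config$variant == "ifla") {
      scale0 <- config$mutation_scale0 * (1 - t / T_max)
      if (scale0 > 0) {
        # mutate a single random coordinate of the global best: a full-vector
        # heavy-tailed jump almost surely spoils every already-converged
        # coordinate, while a one-dimensional jump can hop between basins
        j <- sample.int(d, 1L)
        cand <- best_x
        cand[j] <- clip(best_x[j] + scale0 * rng[j] * tan(pi * (stats::runif(1) - 0.5)),
                        lo[j], up[j])
        fc <- eval_position(objective, cand)
        evals <- evals + 1L
        if (fc < best_f) {
          best_x <- cand
          best_f <- fc
        } else {
          # rejected mutants still reseed the worst agent when they beat it,
          # adding diversity without disturbing the monotone best-so-far
          wi <- which.max(f)
          if (fc < f[wi]) {
            X[wi, ] <- cand
            f[wi] <- fc
          }
        }
      }
    }
    history[t] <- best_f
  }

  structure(list(best_position = best_x, best_fitness = best_f,
                 history = history, evaluations = evals,
                 objective_name = objective$name, config = config),
            class = "fla_result")
}

#' @export
print.fla_result <- function(x, ...) {
  cat(sprintf("<fla_result> %s on '%s': best %.6g after %d evaluations\n",
              x$config$variant, x$objective_name, x$best_fitness, x$evaluations))
  invisible(x)
}

#' Repeated independent optimization runs
#'
#' Run `k` uses seed `config$seed + k`, giving independent but reproducible
#' replicates for stability statistics.
#'
#' @param objective an [objective_fn()].
#' @param config an [optimizer_config()]; its seed is the base seed.
#' @param n_runs number of independent runs.
#' @param keep_history if `TRUE`, also return the per-run best-so-far
#'   histories (as a `max_iterations` x `n_runs` matrix).
#' @return a list of class `fla_trials` with `per_run` best fitnesses and
#'   `mean`, `sd`, `median`, `min`, `max` summaries.
#' @export
run_trials <- function(objective, config, n_runs = 30L, keep_history = FALSE) {
  runs <- lapply(seq_len(n_runs), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    fla_optimize(objective, cfg)
  })
  per_run <- vapply(runs, `[[`, 0, "best_fitness")
  out <- list(per_run = per_run, mean = mean(per_run),
              sd = stats::sd(per_run), median = stats::median(per_run),
              min = min(per_run), max = max(per_run),
              variant = config$variant, objective_name = objective$name)
  if (keep_history) out$history <- vapply(runs, `[[`, numeric(config$max_iterations), "history")
  class(out) <- "fla_trials"
  out
}

#' Export a convergence history to CSV
#'
#' @param result an `fla_result`.
#' @param path output CSV path (columns `iteration`, `best_fitness`).
#' @export
write_history <- function(result, path) {
  utils::write.csv(data.frame(iteration = seq_along(result$history),
                              best_fitness = result$history),
                   path, row.names = FALSE)
  invisible(path)
}
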