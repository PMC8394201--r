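#' Genetic-algorithm configuration
#'
#' Settings of the multi-population genetic optimiser used for parameter
#' inference: three subpopulations of 20 individuals exchanging their best
#' 10% every 5 generations (ring topology); per generation and
#' subpopulation, 3 elite individuals survive, 60% of the remaining
#' children arise by scattered crossover between roulette-selected
#' parents and 40% by uniform mutation (each gene redrawn uniformly
#' within its bounds with probability 0.2); optimisation stops after 50
#' generations.
#'
#' @param subpopulations Number of subpopulations.
#' @param pop_size Individuals per subpopulation.
#' @param migration_fraction Fraction of a subpopulation migrating.
#' @param migration_interval Generations between migrations.
#' @param n_elite Elite individuals kept per subpopulation per generation.
#' @param crossover_fraction Fraction of non-elite children from
#'   crossover (the rest from mutation).
#' @param mutation_prob Per-gene mutation probability.
#' @param generations Number of generations.
#' @param reevaluate_elites Re-evaluate the elites' fitness every
#'   generation. With a stochastic objective (every simulation-based
#'   fitness is one) this prevents a single lucky evaluation from locking
#'   an individual into the elite set; for deterministic objectives it
#'   only costs a few extra evaluations.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(subpopulations = 3, pop_size = 20,
                      migration_fraction = 0.1, migration_interval = 5,
                      n_elite = 3, crossover_fraction = 0.6,
                      mutation_prob = 0.2, generations = 50,
                      reevaluate_elites = TRUE) {
  structure(list(subpopulations = subpopulations, pop_size = pop_size,
                 migration_fraction = migration_fraction,
                 migration_interval = migration_interval,
                 n_elite = n_elite, crossover_fraction = crossover_fraction,
                 mutation_prob = mutation_prob, generations = generations,
                 reevaluate_elites = reevaluate_elites),
            class = "ga_config")
}

#' Minimise an objective with the multi-population genetic algorithm
#'
#' Roulette-wheel parent selection acts on the transformed minimisation
#' rank `max(fitness) - fitness + eps` within each subpopulation, so the
#' smallest objective values are the most likely parents. Scattered
#' crossover copies each gene from either parent with probability 1/2;
#' uniform mutation redraws each gene uniformly within its bounds with
#' the configured probability. Every individual respects the bounds at
#' every generation, and elitism makes the best-so-far fitness trace
#' non-increasing.
#'
#' @param fn Objective function of a numeric parameter vector; finite on
#'   the box `[lower, upper]`.
#' @param lower,upper Numeric bounds (equal length).
#' @param config A [ga_config()].
#' @param seed Optional integer seed.
#' @return An object of class `ga_fit`: `best_par`, `best_fitness`,
#'   `trace` (tibble: `generation`, `best`, `mean`), `population`,
#'   `fitness`, `n_evaluations`, `config`, `seed`.
#' @export
ga_optimize <- function(fn, lower, upper, config = ga_config(),
                        seed = NULL) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  if (!is.null(seed)) set.seed(seed)
  npar <- length(lower)
  ns <- config$subpopulations
  np <- config$pop_size
  n_evals <- 0L

  eval_rows <- function(mat) {
    n_evals <<- n_evals + nrow(mat)
    apply(mat, 1, fn)
  }
  rand_pop <- function(n) {
    matrix(runif(n * npar, rep(lower, each = n), rep(upper, each = n)),
           nrow = n)
  }
  pops <- replicate(ns, rand_pop(np), simplify = FALSE)
  fits <- lapply(pops, eval_rows)

  roulette <- function(fit, n) {
    w <- max(fit) - fit + 1e-12 + 1e-6 * (max(fit) - min(fit))
    if (all(w == w[1])) w <- rep(1, length(fit))
    sample.int(length(fit), n, replace = TRUE, prob = w)
  }

  best_par <- NULL
  best_fit <- Inf
  trace <- vector("list", config$generations)
  for (s in seq_len(ns)) {
    i <- which.min(fits[[s]])
    if (fits[[s]][i] < best_fit) {
      best_fit <- fits[[s]][i]
      best_par <- pops[[s]][i, ]
    }
  }

  for (g in seq_len(config$generations)) {
    for (s in seq_len(ns)) {
      pop <- pops[[s]]
      fit <- fits[[s]]
      ord <- order(fit)
      elites <- pop[ord[seq_len(config$n_elite)], , drop = FALSE]
      elite_fit <- fit[ord[seq_len(config$n_elite)]]
      if (isTRUE(config$reevaluate_elites)) {
        elite_fit <- eval_rows(elites)
      }
      n_rest <- np - config$n_elite
      n_cross <- round(config$crossover_fraction * n_rest)
      n_mut <- n_rest - n_cross

      children <- matrix(NA_real_, n_rest, npar)
      if (n_cross > 0) {
        pa <- roulette(fit, n_cross)
        pb <- roulette(fit, n_cross)
        mask <- matrix(runif(n_cross * npar) < 0.5, n_cross, npar)
        children[seq_len(n_cross), ] <-
          ifelse(mask, pop[pa, , drop = FALSE], pop[pb, , drop = FALSE])
      }
      if (n_mut > 0) {
        pm <- roulette(fit, n_mut)
        base <- pop[pm, , drop = FALSE]
        mmask <- matrix(runif(n_mut * npar) < config$mutation_prob,
                        n_mut, npar)
        redraw <- matrix(runif(n_mut * npar, rep(lower, each = n_mut),
                               rep(upper, each = n_mut)), n_mut, npar)
        base[mmask] <- redraw[mmask]
        children[n_cross + seq_len(n_mut), ] <- base
      }
      child_fit <- eval_rows(children)
      pops[[s]] <- rbind(elites, children)
      fits[[s]] <- c(elite_fit, child_fit)
    }
    # ring migration of the best individuals (copies replace the worst)
    if (config$migration_interval > 0 &&
        g %% config$migration_interval == 0 && ns > 1) {
      n_mig <- ceiling(config$migration_fraction * np)
      snapshot <- pops
      fsnap <- fits
      for (s in seq_len(ns)) {
        src <- if (s == 1) ns else s - 1
        ord_src <- order(fsnap[[src]])[seq_len(n_mig)]
        ord_dst <- order(fits[[s]], decreasing = TRUE)[seq_len(n_mig)]
        pops[[s]][ord_dst, ] <- snapshot[[src]][ord_src, , drop = FALSE]
        fits[[s]][ord_dst] <- fsnap[[src]][ord_src]
      }
    }
    for (s in seq_len(ns)) {
      i <- which.min(fits[[s]])
      if (fits[[s]][i] < best_fit) {
        best_fit <- fits[[s]][i]
        best_par <- pops[[s]][i, ]
      }
    }
    trace[[g]] <- tibble(generation = g, best = best_fit,
                         mean = mean(unlist(fits)))
  }
  # best individual of the final population by its current fitness (for
  # stochastic objectives with elite re-evaluation this is less biased by
  # lucky draws than the minimum ever seen)
  final_fit <- unlist(fits)
  final_pop <- do.call(rbind, pops)
  i_fin <- which.min(final_fit)
  structure(list(best_par = best_par, best_fitness = best_fit,
                 final_par = final_pop[i_fin, ],
                 final_fitness = final_fit[i_fin],
                 trace = bind_rows(trace),
                 population = do.call(rbind, pops),
                 fitness = unlist(fits),
                 n_evaluations = n_evals,
                 config = config, seed = seed),
            class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("<ga_fit> best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$n_evaluations))
  cat("  best parameters:", paste(signif(x$best_par, 4), collapse = ", "),
      "\n")
  invisible(x)
}
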