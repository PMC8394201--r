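#' Fit model parameters to combing data by repeated genetic optimisation
#'
#' Couples the lattice simulator to the genetic algorithm: every objective
#' evaluation simulates one S phase with the proposed parameters, keeps the
#' lattice snapshots bracketing each sample's global replicated fraction,
#' shreds them with the sample's molecule-length distribution, reshapes the
#' resulting molecules, computes the six observables on the experimental
#' grids and sums the [curve_fitness()] over all samples. Because the
#' objective is stochastic and the parameter space is large, the
#' optimisation is repeated `repeats` times independently and only each
#' run's best elite individual is retained; the ensemble over runs is the
#' fit result.
#'
#' @param data A reshaped `combing_dataset`, or a list of them (samples of
#'   one condition at several global replicated fractions, fitted jointly).
#' @param variant Model variant to fit (`"MM1"` ... `"MM5"`).
#' @param L Lattice length used for the fitting simulations, kb.
#' @param config A [ga_config()]; lower `generations` for reduced budgets.
#' @param repeats Number of independent optimisation runs.
#' @param seed Integer seed for the whole ensemble.
#' @param round_cap Simulation round cap per evaluation; parameter sets
#'   that cannot reach the largest target fraction within the cap receive
#'   a penalty fitness.
#' @param f_bins,hist_binwidth,dt Passed to [observable_curves()].
#' @param condition Condition label stored with the ensemble.
#' @param origin_layout,mean_origin_spacing Potential-origin layout used
#'   in the fitting simulations.
#' @param n_shreds Independent shreds pooled per objective evaluation
#'   (more shreds, less objective variance, higher cost).
#' @return An object of class `replication_fit`: `runs` (tibble: one row
#'   per run with the best elite's parameters, fitness and seed),
#'   `ensemble` (per-parameter mean/sd), `experimental` curves, `config`
#'   and provenance. `tidy()` and `glance()` methods are provided.
#' @export
fit_condition <- function(data, variant = "MM5", L = 1e5,
                          config = ga_config(), repeats = 100,
                          seed = NULL, round_cap = 300,
                          f_bins = 20, hist_binwidth = 2, dt = 3,
                          condition = "condition",
                          origin_layout = "discrete",
                          mean_origin_spacing = 2.3,
                          n_shreds = 2) {
  if (inherits(data, "combing_dataset")) data <- list(data)
  stopifnot(all(vapply(data, inherits, TRUE, "combing_dataset")))
  if (!is.null(seed)) set.seed(seed)

  samples <- lapply(data, function(ds) {
    ds <- reshape_tracks(ds)
    list(target = global_fraction(ds),
         lengths = ds$molecules$length_kb,
         curves = observable_curves(ds, f_bins = f_bins,
                                    hist_binwidth = hist_binwidth, dt = dt))
  })
  targets <- vapply(samples, `[[`, numeric(1), "target")
  bounds <- parameter_bounds(variant)
  objective <- make_fit_objective(samples, targets, variant, L, round_cap,
                                  dt, origin_layout, mean_origin_spacing,
                                  n_shreds = n_shreds)

  run_seeds <- sample.int(2^31 - 2, repeats)
  runs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    ga <- ga_optimize(objective, bounds$lower, bounds$upper, config,
                      seed = run_seeds[r])
    par <- setNames(as.list(ga$final_par), bounds$parameter)
    runs[[r]] <- tibble(run = r, seed = run_seeds[r],
                        fitness = ga$final_fitness, !!!par)
  }
  runs <- bind_rows(runs)
  ensemble <- runs %>%
    tidyr::pivot_longer(dplyr::all_of(bounds$parameter),
                        names_to = "parameter", values_to = "value") %>%
    group_by(.data$parameter) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n = n(), .groups = "drop") %>%
    mutate(condition = condition)
  structure(list(runs = runs, ensemble = ensemble,
                 parameters = bounds$parameter,
                 variant = variant, condition = condition,
                 targets = targets, L = L, config = config,
                 repeats = repeats, seed = seed,
                 experimental = lapply(samples, `[[`, "curves")),
            class = "replication_fit")
}

# Build the stochastic GA objective: simulate -> fraction-match -> shred
# -> reshape -> curves -> fitness (summed over samples). Each lattice is
# shredded `n_shreds` times and the molecules pooled, which halves the
# shredding contribution to the objective variance at small cost.
make_fit_objective <- function(samples, targets, variant, L, round_cap,
                               dt, origin_layout, mean_origin_spacing,
                               n_shreds = 2) {
  f_top <- max(targets)
  targets_sorted <- sort(targets)
  use_local <- variant %in% c("MM3", "MM5")
  gen_spacing <- if (origin_layout == "discrete") mean_origin_spacing else 1
  no_eyes <- matrix(integer(0), ncol = 2)
  function(par) {
    p <- params_from_vector(par, variant, origin_layout,
                            mean_origin_spacing)
    # direct engine call with in-engine map/mask generation: this runs
    # thousands of times per fit, so the R-level container work of
    # run_simulation() is skipped
    raw <- sim_run_cpp(
      as.integer(L), p$N0, p$J, p$Pout, p$Pin, p$Plocal,
      use_local, as.integer(p$d), speed_choices_blocks(p),
      NULL, NULL, f_top, as.integer(round_cap), targets_sorted,
      FALSE, FALSE, no_eyes,
      sample.int(.Machine$integer.max, 1) - 1,
      sample.int(.Machine$integer.max, 1) - 1,
      gen_spacing = gen_spacing,
      gen_theta = if (variant %in% c("MM4", "MM5")) p$theta else -1)
    if (raw$f < f_top) {
      return(1e4 + 1e3 * (f_top - raw$f))
    }
    total <- 0
    for (k in seq_along(samples)) {
      # fraction matching: take the bracketing round whose genome fraction
      # is nearest the sample's global fraction, then shred (the shredded
      # fraction differs from the genome fraction only by sampling noise)
      snap <- NULL
      for (s in raw$snapshots) {
        if (!is.null(s) && abs(s$target - targets[k]) < 1e-12) snap <- s
      }
      if (is.null(snap)) return(1e4)
      use_at <- abs(snap$f_at - targets[k]) <= abs(snap$f_before - targets[k])
      x <- if (use_at) snap$x_at else snap$x_before
      eyes_g <- lattice_eyes(x)
      ds <- shred_from_eyes(eyes_g, L, samples[[k]]$lengths)
      if (n_shreds > 1) {
        for (j in seq_len(n_shreds - 1)) {
          extra <- shred_from_eyes(eyes_g, L, samples[[k]]$lengths)
          off <- max(ds$molecules$molecule_id)
          extra$molecules$molecule_id <- extra$molecules$molecule_id + off
          extra$eyes$molecule_id <- extra$eyes$molecule_id + off
          ds$molecules <- bind_rows(ds$molecules, extra$molecules)
          ds$eyes <- bind_rows(ds$eyes, extra$eyes)
        }
      }
      ds <- reshape_tracks(ds)
      sim_curves <- observable_curves(ds, dt = dt,
                                      template = samples[[k]]$curves)
      total <- total + as.numeric(curve_fitness(sim_curves,
                                                samples[[k]]$curves))
    }
    total
  }
}

# decode a GA parameter vector into a full model_parameters object
params_from_vector <- function(par, variant, origin_layout = "discrete",
                               mean_origin_spacing = 2.3) {
  names(par) <- active_parameters(variant)
  get <- function(nm, default) if (nm %in% names(par)) par[[nm]] else default
  model_parameters(
    N0 = get("N0", 0), J = get("J", 0),
    Pout = get("Pout", 0),
    Pin = get("Pin", get("Pout", 0)),
    Plocal = get("Plocal", get("Pout", 0)),
    theta = get("theta", 0), d = get("d", 0),
    variant = variant, origin_layout = origin_layout,
    mean_origin_spacing = mean_origin_spacing)
}

#' @export
print.replication_fit <- function(x, ...) {
  cat(sprintf(
    "<replication_fit> %s, %d runs, %d sample(s) at f = %s\n",
    x$variant, nrow(x$runs), length(x$targets),
    paste(signif(x$targets, 3), collapse = ", ")))
  print(x$ensemble)
  invisible(x)
}

#' @describeIn fit_condition One row per optimisation run and parameter.
#' @param x A `replication_fit`.
#' @param ... Unused.
#' @export
tidy.replication_fit <- function(x, ...) {
  x$runs %>%
    tidyr::pivot_longer(dplyr::all_of(x$parameters),
                        names_to = "parameter", values_to = "value") %>%
    dplyr::select("run", "seed", "parameter", "value", "fitness")
}

#' @describeIn fit_condition Ensemble summary (one row per parameter).
#' @export
glance.replication_fit <- function(x, ...) {
  tibble(variant = x$variant, condition = x$condition,
         n_runs = nrow(x$runs),
         best_fitness = min(x$runs$fitness),
         mean_fitness = mean(x$runs$fitness))
}

#' Parameter ensemble of a fit
#'
#' @param fit A `replication_fit`.
#' @return Tibble with `parameter`, `mean`, `sd`, `n`, `condition`.
#' @export
parameter_ensemble <- function(fit) {
  stopifnot(inherits(fit, "replication_fit"))
  fit$ensemble
}

#' Compare fitted parameters between two conditions
#'
#' Welch two-sample t-tests on the per-run best-elite parameter values of
#' two fits (e.g. control vs checkpoint-inhibited), with Bonferroni
#' adjustment across parameters.
#'
#' @param a,b `replication_fit` objects over the same parameter set.
#' @param alpha Family-wise significance level after adjustment.
#' @param adjust Multiple-testing adjustment method (see
#'   [stats::p.adjust()]).
#' @return Tibble with one row per parameter: means, difference,
#'   direction, test statistic, raw and adjusted p-values and a
#'   significance flag.
#' @export
compare_parameters <- function(a, b, alpha = 0.01, adjust = "bonferroni") {
  stopifnot(inherits(a, "replication_fit"), inherits(b, "replication_fit"))
  if (!identical(sort(a$parameters), sort(b$parameters))) {
    abort("fits have different parameter sets")
  }
  rows <- lapply(a$parameters, function(pm) {
    va <- a$runs[[pm]]
    vb <- b$runs[[pm]]
    if (sd(va) == 0 && sd(vb) == 0) {
      tt <- list(statistic = 0, p.value = if (mean(va) == mean(vb)) 1 else 0)
    } else {
      tt <- t.test(va, vb)
    }
    tibble(parameter = pm,
           mean_a = mean(va), mean_b = mean(vb),
           difference = mean(vb) - mean(va),
           direction = ifelse(mean(vb) > mean(va), "increase",
                              ifelse(mean(vb) < mean(va), "decrease",
                                     "none")),
           statistic = as.numeric(tt$statistic),
           p_value = tt$p.value)
  })
  out <- bind_rows(rows) %>%
    mutate(p_adjusted = p.adjust(.data$p_value, method = adjust),
           significant = .data$p_adjusted < alpha)
  out
}
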