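#' Molecule-length models for combing emulation
#'
#' Combed fibres have a broad, right-skewed length distribution; shredding
#' a simulated genome with the same distribution reproduces the
#' finite-length detection biases of the experiment. Three samplers are
#' provided: a lognormal model (default: median 100 kb, log-sd 0.5,
#' qualitatively matching combed-fibre length distributions), a point
#' mass, and resampling from an empirical length vector or histogram.
#'
#' @param kind `"lognormal"`, `"point"` or `"empirical"`.
#' @param median_kb Median length for the lognormal model, kb.
#' @param sdlog Log-scale standard deviation of the lognormal model.
#' @param length_kb Constant length for the point model, kb.
#' @param values,weights Observed lengths (and optional weights) for the
#'   empirical model; weights are renormalised to sum to one.
#' @param min_kb Smallest molecule length returned, kb (draws below are
#'   redrawn).
#' @return A sampler `function(n)` of class `length_model` with the model
#'   description attached.
#' @export
make_length_model <- function(kind = c("lognormal", "point", "empirical"),
                              median_kb = 100, sdlog = 0.5,
                              length_kb = 100,
                              values = NULL, weights = NULL,
                              min_kb = 2) {
  kind <- match.arg(kind)
  sampler <- switch(kind,
    lognormal = {
      meanlog <- log(median_kb)
      function(n) {
        out <- rlnorm(n, meanlog, sdlog)
        while (any(out < min_kb)) {
          out[out < min_kb] <- rlnorm(sum(out < min_kb), meanlog, sdlog)
        }
        out
      }
    },
    point = function(n) rep(length_kb, n),
    empirical = {
      if (is.null(values)) abort("empirical model needs `values`")
      w <- if (is.null(weights)) rep(1, length(values)) else weights
      w <- w / sum(w)
      function(n) sample(values, n, replace = TRUE, prob = w)
    })
  mean_kb <- switch(kind,
    lognormal = exp(log(median_kb) + sdlog^2 / 2),
    point = length_kb,
    empirical = sum(values * (if (is.null(weights)) rep(1 / length(values),
                                                        length(values))
                              else weights / sum(weights))))
  structure(sampler, class = c("length_model", "function"),
            kind = kind, mean_kb = mean_kb)
}

# accept a length_model, plain function or numeric vector of lengths
as_length_sampler <- function(length_model) {
  if (inherits(length_model, "length_model")) return(length_model)
  if (is.function(length_model)) return(length_model)
  if (is.numeric(length_model)) {
    values <- length_model
    return(structure(function(n) sample(values, n, replace = TRUE),
                     class = c("length_model", "function"),
                     kind = "empirical", mean_kb = mean(values)))
  }
  abort("length_model must be a sampler function or a numeric vector")
}

mean_length <- function(sampler) {
  m <- attr(sampler, "mean_kb")
  if (is.null(m)) m <- mean(sampler(256L))
  m
}

#' Specification of a synthetic combing experiment
#'
#' Ground-truth description used to generate pseudo-experimental combing
#' datasets: true model parameters, genome size, target global replicated
#' fractions, molecule-length model, molecule count per sample and an
#' optional measurement-noise model (eye-edge jitter and spurious gaps --
#' an artifact-robustness addition, off by default).
#'
#' Default parameters follow the published MM5 example set (N0 = 1231,
#' J = 287 per round, theta = 0.46, Pin = Plocal = 0.34, Pout = 0.01,
#' d = 138 kb, stated for a 1e6-kb genome); when `L` differs from 1e6
#' the default's extensive parameters `N0` and `J` are scaled
#' proportionally so per-kb dynamics are preserved. Explicitly supplied
#' `parameters` are used exactly as given, at the supplied `L`. Target
#' fractions default to the sample series studied experimentally (8%,
#' 19%, 22%, 46%, 53%).
#'
#' @param parameters True `model_parameters`, interpreted at genome size
#'   `L`; `NULL` for the scaled published default set.
#' @param L Genome size, kb.
#' @param fractions Target global replicated fractions.
#' @param n_molecules Molecules retained per sample (`Inf` keeps all).
#' @param length_model A [make_length_model()] sampler.
#' @param jitter_sd Gaussian eye-edge jitter SD, kb (0 = off).
#' @param false_gap_rate Per-eye probability of a spurious 1.5-kb gap
#'   splitting the eye (0 = off).
#' @param fraction_tol Accepted deviation of each sample's achieved
#'   global fraction from its target.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(parameters = NULL, L = 1e6,
                           fractions = c(0.08, 0.19, 0.22, 0.46, 0.53),
                           n_molecules = 500,
                           length_model = make_length_model(),
                           jitter_sd = 0, false_gap_rate = 0,
                           fraction_tol = 0.02) {
  if (is.null(parameters)) {
    parameters <- model_parameters(N0 = 1231, J = 287, theta = 0.46,
                                   Pin = 0.34, Plocal = 0.34, Pout = 0.01,
                                   d = 138, variant = "MM5",
                                   origin_layout = "discrete")
    scale <- L / 1e6
    parameters$N0 <- parameters$N0 * scale
    parameters$J <- parameters$J * scale
  }
  p <- parameters
  if (any(fractions <= 0 | fractions >= 1)) {
    abort("fractions must lie in (0, 1)")
  }
  structure(list(parameters = p, L = L, fractions = sort(fractions),
                 n_molecules = n_molecules, length_model = length_model,
                 jitter_sd = jitter_sd, false_gap_rate = false_gap_rate,
                 fraction_tol = fraction_tol),
            class = "synthetic_spec")
}

#' Generate a ground-truth synthetic combing dataset
#'
#' Simulates one S phase with the true parameters, keeps the lattice at
#' each target global fraction (fraction matching as for real samples),
#' shreds it with the molecule-length model, optionally applies the noise
#' model, reshapes, and subsamples to the requested molecule count. The
#' returned `truth` record carries everything needed to score parameter
#' recovery: the true parameters, per-sample matched rounds and achieved
#' fractions, and the initiation events falling inside retained
#' molecules.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_combing`: `datasets` (one reshaped
#'   `combing_dataset` per fraction), `truth`.
#' @export
generate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  p <- spec$parameters
  traj <- run_simulation(p, L = spec$L, stop_f = max(spec$fractions),
                         max_rounds = 5000,
                         snapshot_f = spec$fractions,
                         record_firings = TRUE)
  datasets <- list()
  sample_truth <- list()
  for (k in seq_along(spec$fractions)) {
    target <- spec$fractions[k]
    ds <- match_global_fraction(traj, spec$length_model, target,
                                tol = spec$fraction_tol)
    ds$provenance <- "synthetic"
    if (is.finite(spec$n_molecules) &&
        nrow(ds$molecules) > spec$n_molecules) {
      keep <- sort(sample(ds$molecules$molecule_id, spec$n_molecules))
      ds$molecules <- ds$molecules[ds$molecules$molecule_id %in% keep, ]
      ds$eyes <- ds$eyes[ds$eyes$molecule_id %in% keep, ]
    }
    if (spec$jitter_sd > 0 || spec$false_gap_rate > 0) {
      ds <- apply_track_noise(ds, spec$jitter_sd, spec$false_gap_rate)
    }
    ds <- reshape_tracks(ds)
    round_used <- ds$source$round
    n_init <- sum(traj$firings$round <= round_used)
    datasets[[k]] <- ds
    sample_truth[[k]] <- tibble(
      target = target, achieved = global_fraction(ds),
      genome_f = ds$source$genome_f, round = round_used,
      n_initiations_genome = n_init,
      n_initiations_retained = count_firings_in_molecules(
        traj$firings, ds, round_used, spec$L),
      n_molecules = nrow(ds$molecules))
  }
  names(datasets) <- sprintf("f%02.0f", 100 * spec$fractions)
  structure(list(datasets = datasets,
                 truth = list(parameters = p, L = spec$L,
                              samples = bind_rows(sample_truth),
                              firings = traj$firings,
                              seed = seed)),
            class = "synthetic_combing")
}

# initiation events (by the matched round) falling inside the retained
# molecules' genome windows; windows may wrap around the genome origin
count_firings_in_molecules <- function(firings, ds, round_used, L) {
  if (is.null(firings) || !"genome_start" %in% names(ds$molecules)) {
    return(NA_integer_)
  }
  pos <- firings$position[firings$round <= round_used]
  n <- 0L
  for (i in seq_len(nrow(ds$molecules))) {
    a <- ds$molecules$genome_start[i]
    b <- a + ds$molecules$length_kb[i]
    if (b <= L) {
      n <- n + sum(pos >= a & pos < b)
    } else {
      n <- n + sum(pos >= a | pos < (b - L))
    }
  }
  n
}

# measurement-noise model: Gaussian edge jitter and spurious gaps.
# Artifact addition for robustness testing; not part of the replication
# model itself.
apply_track_noise <- function(ds, jitter_sd, false_gap_rate) {
  eyes <- ds$eyes %>% left_join(ds$molecules, by = "molecule_id")
  if (jitter_sd > 0 && nrow(eyes) > 0) {
    eyes$start <- eyes$start + rnorm(nrow(eyes), 0, jitter_sd)
    eyes$end <- eyes$end + rnorm(nrow(eyes), 0, jitter_sd)
    eyes$start <- pmax(eyes$start, 0)
    eyes$end <- pmin(eyes$end, eyes$length_kb)
    keep <- eyes$end > eyes$start
    eyes <- eyes[keep, , drop = FALSE]
  }
  if (false_gap_rate > 0 && nrow(eyes) > 0) {
    split <- runif(nrow(eyes)) < false_gap_rate &
      (eyes$end - eyes$start) > 4
    if (any(split)) {
      gap_w <- 1.5
      mid <- (eyes$start[split] + eyes$end[split]) / 2
      left <- eyes[split, , drop = FALSE]
      right <- eyes[split, , drop = FALSE]
      left$end <- mid - gap_w / 2
      right$start <- mid + gap_w / 2
      eyes <- bind_rows(eyes[!split, , drop = FALSE], left, right)
    }
  }
  out <- ds
  out$eyes <- eyes %>%
    dplyr::select("molecule_id", "start", "end") %>%
    arrange(.data$molecule_id, .data$start)
  out
}

#' @export
print.synthetic_combing <- function(x, ...) {
  cat(sprintf("<synthetic_combing> %d samples from %s truth, L = %g kb\n",
              length(x$datasets), x$truth$parameters$variant, x$truth$L))
  print(x$truth$samples)
  invisible(x)
}
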