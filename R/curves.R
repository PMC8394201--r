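#' The six combing observables of a dataset
#'
#' Computes the observable set used to confront model and data:
#' the firing rate `I(f)` and fork density `Nfork(f)` curves (bin-averages
#' over molecules sorted by their own replicated fraction), the
#' distribution of per-molecule replicated fractions, and the eye-length,
#' gap-length and eye-to-eye-distance distributions (normalised to unit
#' mass). Gap lengths and eye-to-eye distances use interior gaps /
#' adjacent-eye centre distances; eye lengths include end-touching eyes.
#'
#' When `template` is supplied all grids are copied from it, which is how
#' simulated curves are aligned to an experimental reference before
#' computing a fitness.
#'
#' Within an f-bin, `I` and the fork density are computed as
#' ratio-of-sums estimates (total new firings over total unreplicated
#' exposure; total forks over total length) rather than unweighted means
#' of per-molecule ratios: a single short molecule otherwise dominates a
#' sparse bin and makes the fitness heavy-tailed. The unweighted
#' per-molecule version is available from [per_molecule_curves()].
#'
#' @param dataset A reshaped `combing_dataset`.
#' @param f_bins Number of equal-width bins of `f` on `[0, 1]`.
#' @param hist_binwidth Histogram bin width, kb.
#' @param dt Detection window for `I`, minutes.
#' @param template An `observable_curves` object whose grids to reuse.
#' @param min_exposure Minimum total unreplicated exposure
#'   (kb x minutes) for an f-bin's `I` to be defined; rate estimates
#'   from almost-fully-replicated bins are otherwise unbounded.
#' @param min_length Minimum total molecule length (kb) for an f-bin's
#'   fork density to be defined.
#' @return An object of class `observable_curves`: named list of tibbles
#'   (`grid`, `value`) for `i_rate`, `fork_density`, `fraction_dist`,
#'   `eye_length`, `gap_length`, `eted`, plus the grid definitions.
#' @export
observable_curves <- function(dataset, f_bins = 20, hist_binwidth = 2,
                              dt = 3, template = NULL,
                              min_exposure = 50, min_length = 20) {
  stopifnot(inherits(dataset, "combing_dataset"))
  mol <- molecule_stats(dataset, dt = dt)
  ann <- dataset_tracks(dataset)

  if (!is.null(template)) {
    f_breaks <- attr(template, "f_breaks")
    hist_breaks <- attr(template, "hist_breaks")
  } else {
    f_breaks <- seq(0, 1, length.out = f_bins + 1)
    hmax <- max(c(ann$eye_lengths, ann$gap_lengths, ann$eted, hist_binwidth))
    hist_breaks <- c(seq(0, ceiling(hmax / hist_binwidth) * hist_binwidth,
                         by = hist_binwidth), Inf)
  }
  mids <- (head(f_breaks, -1) + f_breaks[-1]) / 2
  bin <- cut(mol$f, breaks = f_breaks, include.lowest = TRUE, labels = FALSE)

  prop_hist <- function(values, breaks) {
    if (length(values) == 0) {
      return(rep(0, length(breaks) - 1))
    }
    h <- tabulate(cut(values, breaks = breaks, include.lowest = TRUE,
                      labels = FALSE), nbins = length(breaks) - 1)
    h / sum(h)
  }
  hist_mids <- head(hist_breaks, -1) + hist_binwidth / 2

  tb <- function(grid, value) {
    tibble::new_tibble(list(grid = grid, value = value),
                       nrow = length(grid))
  }
  bin_ratio <- function(num, den, min_den) {
    out <- rep(NA_real_, length(mids))
    ok <- !is.na(bin) & !is.na(num) & !is.na(den)
    if (any(ok)) {
      top <- rowsum(num[ok], bin[ok])
      bot <- rowsum(den[ok], bin[ok])
      out[as.integer(rownames(top))] <- ifelse(bot[, 1] >= min_den,
                                               top[, 1] / bot[, 1],
                                               NA_real_)
    }
    out
  }
  curves <- list(
    i_rate = tb(mids, bin_ratio(mol$n_new,
                                (1 - mol$f) * mol$length_kb * dt,
                                min_exposure)),
    fork_density = tb(mids, bin_ratio(mol$n_forks, mol$length_kb,
                                      min_length)),
    fraction_dist = tb(
      mids,
      tabulate(bin[!is.na(bin)], nbins = length(mids)) /
        max(1, sum(!is.na(bin)))),
    eye_length = tb(hist_mids, prop_hist(ann$eye_lengths, hist_breaks)),
    gap_length = tb(hist_mids, prop_hist(ann$gap_lengths, hist_breaks)),
    eted = tb(hist_mids, prop_hist(ann$eted, hist_breaks)))
  structure(curves, class = "observable_curves",
            f_breaks = f_breaks, hist_breaks = hist_breaks,
            n_molecules = nrow(mol), dt = dt,
            global_f = global_fraction(dataset))
}

# pooled eye/gap/eted length vectors of a dataset (interior gaps only)
dataset_tracks <- function(dataset) {
  ey <- dataset$eyes
  nr <- nrow(ey)
  if (nr == 0) {
    return(list(eye_lengths = numeric(0), gap_lengths = numeric(0),
                eted = numeric(0)))
  }
  o <- order(ey$molecule_id, ey$start)
  id <- ey$molecule_id[o]
  s <- ey$start[o]
  e <- ey$end[o]
  eye_lengths <- e - s
  same <- id[-1] == id[-nr]
  gap_lengths <- (s[-1] - e[-nr])[same]
  centres <- (s + e) / 2
  eted <- (centres[-1] - centres[-nr])[same]
  list(eye_lengths = eye_lengths,
       gap_lengths = gap_lengths[gap_lengths > 0], eted = eted)
}

#' @export
print.observable_curves <- function(x, ...) {
  cat(sprintf(
    "<observable_curves> %d molecules, global f = %.3f, %d f-bins, %d length bins\n",
    attr(x, "n_molecules"), attr(x, "global_f"),
    length(attr(x, "f_breaks")) - 1, length(attr(x, "hist_breaks")) - 1))
  invisible(x)
}

#' Pointwise average of observable curves
#'
#' Averages replicate experiments after binning (grids must match);
#' missing bins are ignored pointwise.
#'
#' @param curve_list List of `observable_curves` on identical grids.
#' @return An `observable_curves` object.
#' @export
average_curves <- function(curve_list) {
  stopifnot(length(curve_list) >= 1)
  ref <- curve_list[[1]]
  out <- ref
  for (nm in names(ref)) {
    vals <- vapply(curve_list, function(cc) cc[[nm]]$value,
                   numeric(nrow(ref[[nm]])))
    vals <- matrix(vals, nrow = nrow(ref[[nm]]))
    out[[nm]]$value <- rowMeans(vals, na.rm = TRUE)
    out[[nm]]$value[is.nan(out[[nm]]$value)] <- NA_real_
  }
  out
}

#' Fitness of simulated against experimental observables
#'
#' For each observable, the sum over grid points of the squared
#' simulated-minus-experimental difference, divided by the squared mean of
#' the experimental curve; the total fitness is the sum over the six
#' observables. Lower is better; identical curves give 0. Grid points
#' where the experimental curve is undefined are skipped; an undefined
#' simulated value is treated as 0 (no molecules observed there).
#'
#' @param simulated,experimental `observable_curves` on identical grids.
#' @return A non-negative scalar with attribute `by_observable`.
#' @export
curve_fitness <- function(simulated, experimental) {
  stopifnot(inherits(simulated, "observable_curves"),
            inherits(experimental, "observable_curves"))
  if (!isTRUE(all.equal(attr(simulated, "f_breaks"),
                        attr(experimental, "f_breaks"))) ||
      !isTRUE(all.equal(attr(simulated, "hist_breaks"),
                        attr(experimental, "hist_breaks")))) {
    abort("curves were computed on different grids; pass `template =` when building the simulated curves")
  }
  parts <- vapply(names(experimental), function(nm) {
    ev <- experimental[[nm]]$value
    sv <- simulated[[nm]]$value
    keep <- !is.na(ev)
    ev <- ev[keep]
    sv <- sv[keep]
    sv[is.na(sv)] <- 0
    m <- mean(ev)
    if (length(ev) == 0 || m == 0) return(0)
    sum((sv - ev)^2) / m^2
  }, numeric(1))
  structure(sum(parts), by_observable = parts)
}
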