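#' Simulate a replication-timing profile of a structured chromosome
#'
#' Builds a fictitious chromosome whose high-firing-probability (`Pin`)
#' regions are contiguous intervals (region-level mask), replicates it
#' `replicates` times independently with the same region layout, and
#' pools the runs: for each 1-kb position the mean replication time (in
#' minutes) and the firing abundance (fraction of runs in which an
#' initiation event occurred at that position) are recorded. This is the
#' in-silico analogue of population replication-timing profiles
#' (Repli-seq-like), where early plateaus correspond to high-probability
#' regions.
#'
#' @param p A `model_parameters` object (variant MM4/MM5 so `Pin`
#'   regions matter).
#' @param chrom_L Chromosome length, kb. The published example uses a
#'   2e5-kb chromosome with 398 regions; `scale` shrinks that setup
#'   proportionally (including `N0` and `J`) for desk-scale runs.
#' @param n_regions Number of Pin regions.
#' @param region_max Upper bound of the region-length draw, kb.
#' @param replicates Number of independent S phases pooled.
#' @param scale Proportional scaling factor applied to `chrom_L`,
#'   `n_regions`, `region_max`, `N0` and `J` (1 = as given).
#' @param seed Integer seed.
#' @param max_rounds Per-replicate round cap.
#' @return An object of class `timing_profile`: `profile` tibble
#'   (`position`, `mean_time`, `firing_abundance`, `in_region`),
#'   `firings` (replicate, position, round), `regions`, `params`.
#' @export
simulate_timing <- function(p, chrom_L = 2e5, n_regions = 398,
                            region_max = 3000, replicates = 100,
                            scale = 1, seed = NULL, max_rounds = 5000) {
  validate_parameters(p)
  if (!is.null(seed)) set.seed(seed)
  if (scale != 1) {
    chrom_L <- round(chrom_L * scale)
    n_regions <- max(1L, round(n_regions * scale))
    region_max <- max(1, round(region_max * scale))
    p$N0 <- p$N0 * scale
    p$J <- p$J * scale
  }
  mask <- generate_region_mask(chrom_L, p$theta, "region",
                               region_length_max = region_max,
                               n_regions = n_regions)
  times_sum <- numeric(chrom_L)
  fire_counts <- numeric(chrom_L)
  firings <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    tr <- run_simulation(p, L = chrom_L, max_rounds = max_rounds,
                         record_times = TRUE, record_firings = TRUE,
                         region_mask = mask)
    if (tr$f_final < 1) {
      abort("replicate did not complete within max_rounds")
    }
    times_sum <- times_sum + tr$times
    if (nrow(tr$firings) > 0) {
      fire_counts[tr$firings$position + 1L] <-
        fire_counts[tr$firings$position + 1L] + 1
      firings[[r]] <- tr$firings %>% mutate(replicate = r, .before = 1)
    }
  }
  profile <- tibble(
    position = seq_len(chrom_L) - 1L,
    mean_time = times_sum / replicates * p$round_minutes,
    firing_abundance = fire_counts / replicates,
    in_region = mask$mask)
  structure(list(profile = profile, firings = bind_rows(firings),
                 regions = mask$regions, params = p,
                 replicates = replicates, chrom_L = chrom_L,
                 seed = seed),
            class = "timing_profile")
}

#' @export
print.timing_profile <- function(x, ...) {
  cat(sprintf(
    "<timing_profile> %g kb chromosome, %d regions, %d replicates pooled\n",
    x$chrom_L, nrow(x$regions), x$replicates))
  invisible(x)
}

#' Smooth a timing profile by local regression
#'
#' Locally weighted regression (lowess) of mean replication time against
#' position, with the smoother span given as a fraction of the
#' chromosome.
#'
#' @param tp A `timing_profile`, or a tibble with `position` and
#'   `mean_time`.
#' @param span Smoother span in `(0, 1]`.
#' @return The input with a `smoothed` column added to the profile.
#' @export
smooth_profile <- function(tp, span = 0.02) {
  if (span <= 0 || span > 1) abort("span must lie in (0, 1]")
  prof <- if (inherits(tp, "timing_profile")) tp$profile else tp
  sm <- lowess(prof$position, prof$mean_time, f = span, iter = 0)
  prof$smoothed <- sm$y
  if (inherits(tp, "timing_profile")) {
    tp$profile <- prof
    tp
  } else {
    prof
  }
}

#' Segment a smoothed timing profile into CTRs and TTRs
#'
#' Contiguous runs where the absolute slope of the smoothed timing curve
#' stays below `slope_threshold` and that are at least `min_len` kb long
#' are constant timing regions (CTRs), classed early or late depending on
#' whether their mean timing lies below or above the chromosome median;
#' everything between CTRs is a timing transition region (TTR). The
#' segments tile the chromosome.
#'
#' @param tp A smoothed `timing_profile` (see [smooth_profile()]).
#' @param slope_threshold Maximum absolute CTR slope, minutes per kb.
#'   `NULL` (default) uses the root-mean-square slope of the smoothed
#'   profile, which adapts the plateau/transition split to the profile's
#'   own contrast: chromosomes of different sizes and replicate depths
#'   produce slope amplitudes differing by an order of magnitude, so no
#'   fixed value serves all runs.
#' @param min_len Minimum CTR length, kb.
#' @return Tibble of class `timing_segments`: `start`, `end` (0-based
#'   half-open kb), `class` (`early-CTR`, `late-CTR`, `TTR`),
#'   `mean_time`.
#' @export
segment_ctr_ttr <- function(tp, slope_threshold = NULL, min_len = 10) {
  prof <- if (inherits(tp, "timing_profile")) tp$profile else tp
  if (is.null(prof$smoothed)) abort("smooth the profile first")
  y <- prof$smoothed
  if (is.null(slope_threshold)) {
    slope_threshold <- max(sqrt(mean(diff(y)^2)), 1e-9)
  }
  if (slope_threshold <= 0 || min_len <= 0) {
    abort("slope_threshold and min_len must be > 0")
  }
  n <- length(y)
  slope <- c(diff(y), 0)
  slope[n] <- slope[n - 1]
  flat <- abs(slope) <= slope_threshold
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  segs <- tibble(start = starts, end = ends,
                 flat = r$values) %>%
    mutate(flat = .data$flat & (.data$end - .data$start) >= min_len)
  # merge neighbouring same-class runs after reclassifying short CTRs
  grp <- cumsum(c(TRUE, diff(as.integer(segs$flat)) != 0))
  segs <- segs %>%
    mutate(grp = grp) %>%
    group_by(.data$grp) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              flat = .data$flat[1], .groups = "drop")
  med <- median(y)
  segs <- segs %>%
    mutate(mean_time = vapply(seq_len(nrow(segs)), function(i) {
      mean(y[(segs$start[i] + 1):segs$end[i]])
    }, numeric(1)),
    class = ifelse(!.data$flat, "TTR",
                   ifelse(.data$mean_time <= med, "early-CTR",
                          "late-CTR"))) %>%
    dplyr::select("start", "end", "class", "mean_time")
  class(segs) <- c("timing_segments", class(segs))
  segs
}

#' Firing statistics per timing-segment class
#'
#' Summarises pooled initiation events by segment class: the density of
#' fired origins per kb per replicate, and the density of early firings
#' (events in the first quartile of firing times). In structured
#' chromosomes early firings are depleted inside TTRs and fired-origin
#' density is lower there than in CTRs.
#'
#' @param tp A `timing_profile`.
#' @param segments A `timing_segments` tibble from [segment_ctr_ttr()].
#' @return Tibble with one row per class: `kb`, `n_firings`,
#'   `firing_density`, `n_early`, `early_density`.
#' @export
segment_firing_stats <- function(tp, segments) {
  stopifnot(inherits(tp, "timing_profile"))
  fr <- tp$firings
  q1 <- quantile(fr$round, 0.25)
  cls <- rep(NA_character_, tp$chrom_L)
  for (i in seq_len(nrow(segments))) {
    cls[(segments$start[i] + 1):segments$end[i]] <- segments$class[i]
  }
  fr$class <- cls[fr$position + 1L]
  fr$early <- fr$round <= q1
  kb <- tapply(rep(1, tp$chrom_L), cls, sum)
  out <- fr %>%
    group_by(.data$class) %>%
    summarise(n_firings = n(), n_early = sum(.data$early),
              .groups = "drop") %>%
    mutate(kb = as.numeric(kb[.data$class]),
           firing_density = .data$n_firings / .data$kb / tp$replicates,
           early_density = .data$n_early / .data$kb / tp$replicates)
  out
}

#' Export timing results as genome-browser text
#'
#' `write_profile_bedgraph()` writes position/value rows (bedGraph-like,
#' 0-based half-open kb); `write_segments_bed()` writes the CTR/TTR
#' segments as BED with the class in the name field.
#'
#' @param tp A `timing_profile`.
#' @param segments A `timing_segments` tibble.
#' @param path Output file.
#' @param chrom Chromosome name.
#' @param column Profile column to export.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(tp, path, chrom = "chrS",
                                   column = "mean_time") {
  prof <- tp$profile
  df <- data.frame(chrom = chrom, start = prof$position,
                   end = prof$position + 1, value = prof[[column]])
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_profile_bedgraph
#' @export
write_segments_bed <- function(segments, path, chrom = "chrS") {
  df <- data.frame(chrom = chrom, start = segments$start,
                   end = segments$end, name = segments$class)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
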