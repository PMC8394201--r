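#' Construct a combing dataset
#'
#' A combing dataset is the tidy representation of a set of (real or
#' emulated) combed DNA fibres: one row per molecule plus one row per
#' replicated track (eye). All coordinates are kb from the molecule start,
#' half-open `[start, end)`.
#'
#' @param molecules Tibble with columns `molecule_id`, `length_kb`.
#' @param eyes Tibble with columns `molecule_id`, `start`, `end` (may have
#'   zero rows).
#' @param provenance `"experimental"` or `"shredded-simulation"`.
#' @param source Optional metadata (seed, simulation round, ...).
#' @return An object of class `combing_dataset`.
#' @export
combing_dataset <- function(molecules, eyes,
                            provenance = c("shredded-simulation",
                                           "experimental", "synthetic"),
                            source = list()) {
  provenance <- match.arg(provenance)
  molecules <- as_tibble(molecules)
  eyes <- as_tibble(eyes)
  stopifnot(all(c("molecule_id", "length_kb") %in% names(molecules)),
            all(c("molecule_id", "start", "end") %in% names(eyes)))
  if (any(molecules$length_kb <= 0)) abort("every molecule length must be > 0")
  if (nrow(eyes) > 0 && any(eyes$end <= eyes$start))
    abort("every eye must have positive length")
  structure(list(molecules = molecules,
                 eyes = eyes %>% arrange(.data$molecule_id, .data$start),
                 provenance = provenance, source = source),
            class = "combing_dataset")
}

#' Global replicated fraction of a combing dataset
#'
#' Sum of all eye lengths divided by the sum of all molecule lengths.
#'
#' @param dataset A `combing_dataset`.
#' @return A number in `[0, 1]`.
#' @export
global_fraction <- function(dataset) {
  stopifnot(inherits(dataset, "combing_dataset"))
  sum(dataset$eyes$end - dataset$eyes$start) / sum(dataset$molecules$length_kb)
}

#' @export
print.combing_dataset <- function(x, ...) {
  cat(sprintf(
    "<combing_dataset> %d molecules (%.0f kb total), %d eyes, f = %.3f [%s]\n",
    nrow(x$molecules), sum(x$molecules$length_kb), nrow(x$eyes),
    global_fraction(x), x$provenance))
  invisible(x)
}

#' Shred a simulated genome into combing-equivalent molecules
#'
#' Emulates the finite fibre length of DNA combing: molecule lengths are
#' drawn i.i.d. from `length_model` and laid end to end from a uniformly
#' random offset around the (circularised) genome until its length is
#' used up; the final partial fragment is discarded. Circular wrapping of
#' the shredding frame avoids discarding, on average, half the genome at
#' the ends while leaving per-molecule tracks linear.
#'
#' @param x Lattice (0/1 integer vector) or a `lattice_state`.
#' @param length_model A sampler created by [make_length_model()], or a
#'   numeric vector of observed lengths to resample from.
#' @param min_length Minimum molecule length retained, kb.
#' @param source Metadata list stored in the dataset.
#' @return A `combing_dataset`.
#' @export
shred_genome <- function(x, length_model, min_length = 1,
                         source = list()) {
  v <- if (inherits(x, "lattice_state")) x$blocks else as.integer(x)
  shred_from_eyes(lattice_eyes(v), length(v), length_model,
                  min_length = min_length, source = source)
}

# shredding core working from a precomputed genome eye table, so several
# shreds of one lattice share a single run-length extraction
shred_from_eyes <- function(eyes_g, L, length_model, min_length = 1,
                            source = list()) {
  sampler <- as_length_sampler(length_model)
  # draw lengths until the genome is exhausted
  lens <- numeric(0)
  total <- 0
  while (total < L) {
    need <- max(32L, ceiling((L - total) / max(mean_length(sampler), 1)))
    new <- sampler(need)
    lens <- c(lens, new)
    total <- total + sum(new)
  }
  cum <- cumsum(lens)
  n_keep <- sum(cum <= L)        # final partial fragment discarded
  lens <- lens[seq_len(n_keep)]
  lens <- pmax(lens, min_length)
  offset <- floor(runif(1, 0, L))
  # rotate the genome so the shredding frame starts at 0; an eye crossing
  # the rotation point is split into two (it spans the last and first
  # molecule of the frame)
  if (offset > 0 && nrow(eyes_g) > 0) {
    s <- (eyes_g$start - offset) %% L
    e <- s + (eyes_g$end - eyes_g$start)
    wrap <- e > L
    s2 <- c(s[!wrap], s[wrap], rep(0, sum(wrap)))
    e2 <- c(e[!wrap], rep(L, sum(wrap)), e[wrap] - L)
    o <- order(s2)
    eyes_g <- list(start = s2[o], end = e2[o])
  }
  starts <- c(0, cumsum(head(lens, -1)))
  ends <- cumsum(lens)
  molecules <- tibble(molecule_id = seq_along(lens), length_kb = lens,
                      genome_start = (starts + offset) %% L)
  eyes <- clip_intervals_to_windows(eyes_g, starts, ends)
  # eyes arrive sorted by construction; build the object directly
  structure(list(molecules = molecules, eyes = eyes,
                 provenance = "shredded-simulation", source = source),
            class = "combing_dataset")
}

# Vectorised clipping of genome-coordinate intervals into per-molecule
# windows [starts_i, ends_i); returns molecule-relative coordinates.
clip_intervals_to_windows <- function(intervals, starts, ends) {
  is <- intervals$start
  ie <- intervals$end
  if (length(is) == 0 || length(starts) == 0) {
    return(tibble(molecule_id = integer(0), start = numeric(0),
                  end = numeric(0)))
  }
  # first interval with end > window start; last interval with start < end
  lo <- findInterval(starts, ie, left.open = TRUE) + 1L
  hi <- findInterval(ends - 1e-9, is)
  n_i <- pmax(hi - lo + 1L, 0L)
  mol <- rep.int(seq_along(starts), n_i)
  idx <- sequence(n_i) + rep.int(lo - 1L, n_i)
  s <- pmax(is[idx], starts[mol]) - starts[mol]
  e <- pmin(ie[idx], ends[mol]) - starts[mol]
  keep <- e > s
  tibble::new_tibble(list(molecule_id = mol[keep], start = s[keep],
                          end = e[keep]), nrow = sum(keep))
}

#' Reshape replication tracks to combing resolution
#'
#' Applies the scoring rules used for combed fibres so that simulated and
#' experimental molecules share the same resolution and biases: interior
#' gaps of 1 kb or less are not significant and are merged into their
#' flanking eyes; eyes must be larger than 1 kb to be scored (smaller ones
#' revert to gap). Merging runs before filtering and both are iterated to
#' a fixed point, which removes any dependence on processing order.
#'
#' @param x A `combing_dataset`, a `track_annotation`, or a 0/1 vector.
#' @param min_gap Largest non-significant gap, kb (merged; default 1).
#' @param min_eye Largest non-scored eye, kb (dropped; strict inequality:
#'   an exactly 1-kb eye is not scored).
#' @return Object of the same type with reshaped eyes.
#' @examples
#' m <- c(1, 1, 0, 1, 1)            # eye 2 kb / gap 1 kb / eye 2 kb
#' reshape_tracks(extract_tracks(m))$eyes   # single 5-kb eye
#' @export
reshape_tracks <- function(x, min_gap = 1, min_eye = 1) {
  if (inherits(x, "combing_dataset")) {
    eyes <- x$eyes
    out <- reshape_eye_table(eyes, min_gap, min_eye)
    res <- x
    res$eyes <- out
    return(res)
  }
  if (inherits(x, "track_annotation")) {
    eyes <- x$eyes %>% mutate(molecule_id = 1L)
    out <- reshape_eye_table(eyes, min_gap, min_eye)
    return(extract_tracks(out[, c("start", "end")],
                          molecule_length = x$molecule_length))
  }
  # binary vector
  ann <- extract_tracks(x)
  reshape_tracks(ann, min_gap, min_eye)
}

# Batch reshaping over a table of eyes from many molecules; fully
# vectorised (base R in the hot path: this runs inside every genetic
# algorithm objective evaluation).
reshape_eye_table <- function(eyes, min_gap = 1, min_eye = 1) {
  tol <- 1e-9
  o <- order(eyes$molecule_id, eyes$start)
  id <- eyes$molecule_id[o]
  s <- as.numeric(eyes$start[o])
  e <- as.numeric(eyes$end[o])
  repeat {
    n_before <- length(s)
    if (n_before == 0) break
    # merge interior gaps <= min_gap
    repeat {
      n <- length(s)
      if (n <= 1) break
      mergeable <- c(FALSE, id[-1] == id[-n] & s[-1] - e[-n] <= min_gap + tol)
      if (!any(mergeable)) break
      grp <- cumsum(!mergeable)
      keep <- !mergeable
      e <- as.numeric(tapply(e, grp, max))
      id <- id[keep]
      s <- s[keep]
    }
    # drop eyes not larger than min_eye
    keep <- e - s > min_eye + tol
    id <- id[keep]
    s <- s[keep]
    e <- e[keep]
    if (length(s) == n_before) break
  }
  tibble(molecule_id = id, start = s, end = e)
}

#' Count new origin-firing events on a molecule
#'
#' After reshaping, eyes whose length lies in `(lower, upper]` kb (1 to
#' 3 kb by default) are scored as new origin firing events: they appeared
#' within the last `detection_interval()` minutes.
#'
#' @param x A reshaped `combing_dataset` or `track_annotation`.
#' @param lower,upper Length window, kb; the lower bound is strict, for
#'   consistency with the "larger than 1 kb" eye-scoring rule.
#' @return For a dataset: tibble (`molecule_id`, `n_new`); for a single
#'   annotation: an integer count.
#' @export
classify_new_firings <- function(x, lower = 1, upper = 3) {
  tol <- 1e-9
  if (inherits(x, "track_annotation")) {
    len <- x$eyes$length
    return(sum(len > lower + tol & len <= upper + tol))
  }
  stopifnot(inherits(x, "combing_dataset"))
  len <- x$eyes$end - x$eyes$start
  new <- x$eyes$molecule_id[len > lower + tol & len <= upper + tol]
  counts <- table(factor(new, levels = x$molecules$molecule_id))
  tibble(molecule_id = x$molecules$molecule_id,
         n_new = as.integer(counts))
}

#' Select the simulation time matching an experimental global fraction
#'
#' Shreds the lattice snapshots bracketing the requested replicated
#' fraction and returns the shredded dataset whose global replicated
#' fraction is nearest the target (and within `tol`), mirroring the
#' "same global replication fraction" matching rule used when comparing
#' simulations to combing samples.
#'
#' @param traj A `replication_trajectory` run with `snapshot_f` covering
#'   `target`.
#' @param length_model Sampler or length vector for [shred_genome()].
#' @param target Target global replicated fraction.
#' @param tol Acceptance tolerance on the achieved fraction.
#' @return A `combing_dataset` (with `source$round`, `source$genome_f`).
#' @export
match_global_fraction <- function(traj, length_model, target, tol = 0.005) {
  stopifnot(inherits(traj, "replication_trajectory"))
  snap <- NULL
  for (s in traj$snapshots) {
    if (!is.null(s) && abs(s$target - target) < 1e-12) { snap <- s; break }
  }
  if (is.null(snap)) {
    abort(sprintf(
      "trajectory has no snapshot for target %.3f (reached f = %.3f)",
      target, traj$f_final))
  }
  cand <- list(
    list(x = snap$x_before, round = snap$round_before, f = snap$f_before),
    list(x = snap$x_at, round = snap$round_at, f = snap$f_at))
  best <- NULL
  for (cc in cand) {
    ds <- shred_genome(cc$x, length_model,
                       source = list(round = cc$round, genome_f = cc$f,
                                     target = target))
    gf <- global_fraction(ds)
    if (is.null(best) || abs(gf - target) < abs(best$gf - target)) {
      best <- list(ds = ds, gf = gf)
    }
  }
  if (abs(best$gf - target) > tol) {
    abort(sprintf(
      "no simulation time within tolerance: nearest shredded fraction %.4f vs target %.4f (tol %.4f)",
      best$gf, target, tol))
  }
  best$ds
}

#' Per-molecule observables and binned curves
#'
#' Computes, for each (reshaped) molecule, its replicated fraction `f`,
#' the number of new firing events, the firing rate
#' `I = n_new / ((1 - f) length dt)` and the fork count (2 per interior
#' eye, 1 per eye touching one molecule end, 0 for an eye spanning the
#' molecule), then averages `I` and the fork density over molecules within
#' equal-width bins of `f` -- molecules sorted by their own replicated
#' fraction, as in per-molecule combing analyses.
#'
#' @param dataset A reshaped `combing_dataset`.
#' @param f_bins Number of equal-width bins on `[0, 1]`.
#' @param dt Detection window, minutes.
#' @return A list with `molecules` (per-molecule tibble) and `curves`
#'   (tibble: `f_mid`, `I`, `fork_density`, `n_molecules`).
#' @export
per_molecule_curves <- function(dataset, f_bins = 20, dt = 3) {
  stopifnot(inherits(dataset, "combing_dataset"))
  mol <- molecule_stats(dataset, dt = dt)
  breaks <- seq(0, 1, length.out = f_bins + 1)
  bin <- cut(mol$f, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  curves <- mol %>%
    mutate(bin = bin) %>%
    filter(!is.na(.data$I)) %>%
    group_by(.data$bin) %>%
    summarise(I = mean(.data$I),
              fork_density = mean(.data$fork_density),
              n_molecules = n(), .groups = "drop") %>%
    mutate(f_mid = (breaks[.data$bin] + breaks[.data$bin + 1]) / 2,
           .before = 1)
  list(molecules = mol, curves = curves)
}

# per-molecule statistics table (internal, shared with observable_curves;
# base R: runs inside every objective evaluation)
molecule_stats <- function(dataset, dt = 3) {
  tol <- 1e-9
  mol_id <- dataset$molecules$molecule_id
  mol_len <- dataset$molecules$length_kb
  n <- length(mol_id)
  ey <- dataset$eyes
  eye_kb <- numeric(n)
  n_new <- numeric(n)
  n_forks <- numeric(n)
  if (nrow(ey) > 0) {
    idx <- match(ey$molecule_id, mol_id)
    elen <- ey$end - ey$start
    mlen <- mol_len[idx]
    interior <- ey$start > tol & ey$end < mlen - tol
    spanning <- ey$start <= tol & ey$end >= mlen - tol
    forks <- ifelse(spanning, 0, ifelse(interior, 2, 1))
    is_new <- elen > 1 + tol & elen <= 3 + tol
    add_by <- function(v) {
      out <- numeric(n)
      rs <- rowsum(v, idx)
      out[as.integer(rownames(rs))] <- rs[, 1]
      out
    }
    eye_kb <- add_by(elen)
    n_new <- add_by(as.numeric(is_new))
    n_forks <- add_by(forks)
  }
  f <- eye_kb / mol_len
  tibble(molecule_id = mol_id, length_kb = mol_len, eye_kb = eye_kb,
         n_new = n_new, n_forks = n_forks, f = f,
         I = ifelse(f >= 1 - tol, NA_real_,
                    n_new / ((1 - f) * mol_len * dt)),
         fork_density = n_forks / mol_len)
}

#' Read / write the molecule track table format
#'
#' Tab-delimited text with columns `molecule_id`, `length_kb`, `eyes`;
#' the `eyes` field lists `start:end` pairs (kb, half-open) separated by
#' `;`, empty for unreplicated molecules.
#'
#' @param path File path.
#' @param dataset A `combing_dataset`.
#' @return `read_molecules()` returns a `combing_dataset`;
#'   `write_molecules()` returns `path` invisibly.
#' @export
read_molecules <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    molecule_id = readr::col_integer(),
    length_kb = readr::col_double(),
    eyes = readr::col_character()))
  eys <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
    s <- df$eyes[i]
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble(molecule_id = df$molecule_id[i],
           start = as.numeric(vapply(parts, `[`, "", 1)),
           end = as.numeric(vapply(parts, `[`, "", 2)))
  })
  if (nrow(eys) == 0) {
    eys <- tibble(molecule_id = integer(0), start = numeric(0),
                  end = numeric(0))
  }
  combing_dataset(df[, c("molecule_id", "length_kb")], eys, "experimental",
                  source = list(path = path))
}

#' @rdname read_molecules
#' @export
write_molecules <- function(dataset, path) {
  stopifnot(inherits(dataset, "combing_dataset"))
  fmt <- function(id) {
    e <- dataset$eyes[dataset$eyes$molecule_id == id, ]
    if (nrow(e) == 0) return("")
    paste(sprintf("%.10g:%.10g", e$start, e$end), collapse = ";")
  }
  df <- dataset$molecules %>%
    mutate(eyes = vapply(.data$molecule_id, fmt, ""))
  readr::write_tsv(df, path)
  invisible(path)
}
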