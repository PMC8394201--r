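#' Replicated fraction
#'
#' Mean of the binary lattice (or molecule track): the fraction of the
#' genome (molecule) already duplicated.
#'
#' @param x A `lattice_state`, a 0/1 vector, or a `track_annotation`.
#' @return A number in `[0, 1]`.
#' @export
replicated_fraction <- function(x) {
  if (inherits(x, "lattice_state")) return(mean(x$blocks))
  if (inherits(x, "track_annotation")) {
    return(sum(x$eyes$length) / x$molecule_length)
  }
  mean(as.numeric(x))
}

#' Rate of origin firing per unreplicated length per time
#'
#' `I = N1 / ((1 - f) * L * dt)`, the number of new initiation events per
#' kb of unreplicated DNA per minute, evaluated over a detection window of
#' `dt` minutes (3 min by default: the time for a new eye to become
#' distinguishable, growing to 3 kb at 0.5 kb/min per fork).
#'
#' @param n1 Number of new initiation events in the window.
#' @param f Replicated fraction (must be < 1 when `n1 > 0`).
#' @param L Genome or molecule length in kb.
#' @param dt Window length in minutes.
#' @return Initiations per kb per minute (vectorised).
#' @export
initiation_rate <- function(n1, f, L, dt = 3) {
  if (any(f >= 1 & n1 > 0)) {
    abort("initiation rate undefined at f = 1 with n1 > 0 (division by zero)")
  }
  ifelse(n1 == 0, 0, n1 / ((1 - f) * L * dt))
}

#' Density of replication forks
#'
#' Counts "01" and "10" boundaries along the lattice and divides by its
#' length. Eyes touching a lattice end contribute no fork on that side.
#'
#' @param x A `lattice_state` or 0/1 vector.
#' @return Forks per kb.
#' @export
fork_density <- function(x) {
  v <- if (inherits(x, "lattice_state")) x$blocks else as.integer(x)
  sum(diff(v) != 0L) / length(v)
}

#' Annotate eyes, gaps and eye-to-eye distances of a molecule
#'
#' Maximal runs of 1s are eyes (replicated tracks), runs of 0s are gaps.
#' Eye-to-eye distances (ETEDs) are measured centre-to-centre between
#' adjacent eyes, the standard DNA-combing convention.
#'
#' @param x Binary track of the molecule (0/1 vector, 1 kb per element),
#'   or a two-column matrix/tibble of eye intervals (`start`, `end`,
#'   half-open kb) together with `molecule_length`.
#' @param molecule_length Molecule length in kb (required for interval
#'   input).
#' @return An object of class `track_annotation`: list with tibbles
#'   `eyes` and `gaps` (`start`, `end`, `length`), numeric `eted`,
#'   `molecule_length` and replicated fraction `f`.
#' @examples
#' ann <- extract_tracks(c(0, 0, 1, 1, 0, 0, 1, 1))
#' ann$eyes$length   # 2 2
#' ann$eted          # 4
#' @export
extract_tracks <- function(x, molecule_length = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    if (is.null(molecule_length)) abort("molecule_length required")
    eyes <- if (is.data.frame(x)) {
      tibble(start = as.numeric(x$start), end = as.numeric(x$end))
    } else {
      tibble(start = as.numeric(x[, 1]), end = as.numeric(x[, 2]))
    }
    eyes <- eyes %>% arrange(.data$start)
  } else {
    if (length(x) < 1) abort("molecule must span at least one block")
    molecule_length <- length(x)
    r <- rle(as.integer(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values == 1L
    eyes <- tibble(start = as.numeric(starts[keep]),
                   end = as.numeric(ends[keep]))
  }
  eyes$length <- eyes$end - eyes$start
  bounds <- c(0, as.vector(rbind(eyes$start, eyes$end)), molecule_length)
  gs <- bounds[seq(1, length(bounds), by = 2)]
  ge <- bounds[seq(2, length(bounds), by = 2)]
  gaps <- tibble(start = gs, end = ge) %>%
    filter(.data$end > .data$start) %>%
    mutate(length = .data$end - .data$start)
  centres <- (eyes$start + eyes$end) / 2
  eted <- if (length(centres) >= 2) diff(centres) else numeric(0)
  structure(list(eyes = eyes, gaps = gaps, eted = eted,
                 molecule_length = molecule_length,
                 f = sum(eyes$length) / molecule_length),
            class = "track_annotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.track_annotation <- function(x, ...) {
  cat(sprintf("<track_annotation> %g kb, f = %.3f, %d eyes, %d gaps\n",
              x$molecule_length, x$f, nrow(x$eyes), nrow(x$gaps)))
  invisible(x)
}
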