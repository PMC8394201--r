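#' Initialise a lattice state
#'
#' All blocks start unreplicated; no factors are bound; time is zero.
#' Lattice coordinates are 0-based block indices throughout, one block per
#' kb, with half-open `[start, end)` interval conventions.
#'
#' @param p A `model_parameters` object.
#' @param origin_map An `origin_map` of matching length.
#' @param region_mask A `region_mask` of matching length.
#' @param L Lattice length in blocks; defaults to the map length.
#' @return An object of class `lattice_state`: list with `blocks`
#'   (integer 0/1 vector), `t` (completed rounds) and `fired_total`.
#' @export
init_state <- function(p, origin_map = NULL, region_mask = NULL, L = NULL) {
  validate_parameters(p)
  if (is.null(L)) {
    L <- if (!is.null(origin_map)) length(origin_map$eligible)
         else if (!is.null(region_mask)) length(region_mask$mask)
         else abort("supply L or an origin map / region mask")
  }
  if (!is.null(origin_map) && length(origin_map$eligible) != L)
    abort("origin map length does not match L")
  if (!is.null(region_mask) && length(region_mask$mask) != L)
    abort("region mask length does not match L")
  structure(list(blocks = integer(L), t = 0L, fired_total = 0),
            class = "lattice_state")
}

#' Eyes (replicated runs) of a lattice state
#'
#' @param state A `lattice_state` or a 0/1 integer vector.
#' @return Tibble with `start`, `end` (0-based half-open kb).
#' @export
lattice_eyes <- function(state) {
  x <- if (inherits(state, "lattice_state")) state$blocks else state
  r <- rle(as.integer(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  tibble(start = starts[keep], end = ends[keep])
}

#' Active replication forks of a lattice state
#'
#' A fork is a boundary between replicated and unreplicated DNA; eyes
#' touching a lattice end have no fork on that side (the fork terminated).
#'
#' @param state A `lattice_state` or 0/1 vector.
#' @return Tibble with `pos` (0-based block index of the replicated edge
#'   block) and `direction` (`"left"`/`"right"`, the direction of travel).
#' @export
fork_positions <- function(state) {
  x <- if (inherits(state, "lattice_state")) state$blocks else state
  L <- length(x)
  eyes <- lattice_eyes(x)
  left <- eyes$start[eyes$start > 0]
  right <- eyes$end[eyes$end < L] - 1L
  tibble(pos = c(left, right),
         direction = rep(c("left", "right"), c(length(left), length(right)))) %>%
    arrange(.data$pos)
}

#' Number of bound limiting factors
#'
#' One factor is sequestered per initiation and released when its two
#' forks have coalesced with converging neighbours; a fork terminating at
#' a lattice end contributes half a release. This makes `Nb` equal to half
#' the number of active forks (and possibly half-integer transiently).
#'
#' @param state A `lattice_state` or 0/1 vector.
#' @return `Nb` as a (possibly half-integer) number.
#' @export
bound_factors <- function(state) {
  nrow(fork_positions(state)) / 2
}

#' Fork-proximal stimulated zone
#'
#' The set of unreplicated blocks lying within `d` kb downstream of an
#' active fork (in its direction of travel), truncated at lattice ends and
#' at the next replicated block. In MM3/MM5 these blocks fire with
#' probability `Plocal`.
#'
#' @param state A `lattice_state` or 0/1 vector.
#' @param d Zone width in kb.
#' @return Integer vector of 0-based block indices.
#' @export
fork_proximal_zone <- function(state, d) {
  x <- if (inherits(state, "lattice_state")) state$blocks else state
  if (d < 0) abort("d must be >= 0")
  if (d == 0) return(integer(0))
  L <- length(x)
  forks <- fork_positions(x)
  zone <- integer(0)
  for (i in seq_len(nrow(forks))) {
    p0 <- forks$pos[i]
    idx <- if (forks$direction[i] == "right") {
      seq2(p0 + 1L, min(p0 + d, L - 1L))
    } else {
      seq2(max(p0 - d, 0L), p0 - 1L)
    }
    if (length(idx)) {
      repl <- x[idx + 1L] == 1L
      if (forks$direction[i] == "right") {
        stopidx <- which(repl)
        if (length(stopidx)) idx <- idx[seq_len(stopidx[1] - 1L)]
      } else {
        stopidx <- which(repl)
        if (length(stopidx)) idx <- idx[idx > idx[stopidx[length(stopidx)]]]
      }
    }
    zone <- c(zone, idx)
  }
  sort(unique(zone))
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Candidate blocks for origin firing in one round
#'
#' Every unreplicated, origin-eligible block draws a uniform number and
#' becomes a candidate when the draw falls strictly below its reference
#' probability: `Plocal` in the fork-proximal zone (MM3/MM5), otherwise
#' `Pin` or `Pout` according to the region mask. Replicated blocks never
#' fire (origins are inactivated by passive replication).
#'
#' @param state A `lattice_state`.
#' @param p A `model_parameters` object.
#' @param origin_map,region_mask Optional map/mask; `NULL` means all
#'   blocks eligible / all OUT.
#' @return Integer vector of 0-based candidate block indices.
#' @export
candidate_blocks <- function(state, p, origin_map = NULL, region_mask = NULL) {
  x <- state$blocks
  L <- length(x)
  prob <- rep(p$Pout, L)
  if (!is.null(region_mask)) prob[region_mask$mask] <- p$Pin
  if (p$variant %in% c("MM3", "MM5") && p$d > 0) {
    zone <- fork_proximal_zone(state, p$d)
    prob[zone + 1L] <- p$Plocal
  }
  if (!is.null(origin_map)) prob[!origin_map$eligible] <- 0
  prob[x == 1L] <- 0
  which(runif(L) < prob) - 1L
}

#' Apply the limiting-factor cap to a candidate set
#'
#' The number of available factors is `Nf(t) = floor(N0 + J t) - Nb`. If
#' more candidates than available factors exist, a uniform random subset
#' of size `Nf(t)` fires.
#'
#' @param candidates Integer vector of candidate block indices.
#' @param state A `lattice_state`.
#' @param p A `model_parameters` object.
#' @return Integer vector of firing block indices.
#' @export
apply_factor_cap <- function(candidates, state, p) {
  avail <- floor(p$N0 + p$J * state$t) - bound_factors(state)
  k <- max(0, floor(avail + 1e-9))
  if (length(candidates) <= k) return(candidates)
  if (k == 0) return(integer(0))
  sort(sample(candidates, k))
}

#' Fire origins and propagate forks for one round
#'
#' Each firing block becomes a 1-block eye with two nascent forks; every
#' pre-existing active fork then advances `v * round_minutes` blocks (MM2:
#' an independent draw from \{0,1,2,3\} kb/min per fork per round).
#' Converging forks that meet or cross coalesce; forks reaching a lattice
#' end terminate. All propagation uses the start-of-round state, so the
#' outcome is order-independent.
#'
#' @param state A `lattice_state`.
#' @param firing Integer vector of firing block indices (must be
#'   unreplicated).
#' @param p A `model_parameters` object.
#' @return The updated `lattice_state` (time not yet advanced).
#' @export
fire_and_propagate <- function(state, firing, p) {
  x <- state$blocks
  L <- length(x)
  if (any(x[firing + 1L] == 1L)) abort("firing block already replicated")
  eyes <- lattice_eyes(x)
  sp <- speed_choices_blocks(p)
  n <- nrow(eyes)
  if (n > 0) {
    sL <- if (length(sp) == 1L) rep(sp, n) else sample(sp, n, replace = TRUE)
    sR <- if (length(sp) == 1L) rep(sp, n) else sample(sp, n, replace = TRUE)
    sL[eyes$start == 0L] <- 0L   # terminated left forks do not move
    sR[eyes$end == L] <- 0L
    eyes$start <- pmax(eyes$start - sL, 0L)
    eyes$end <- pmin(eyes$end + sR, L)
  }
  if (length(firing)) {
    eyes <- bind_rows(eyes, tibble(start = as.integer(firing),
                                   end = as.integer(firing) + 1L))
  }
  x_new <- integer(L)
  for (i in seq_len(nrow(eyes))) {
    x_new[(eyes$start[i] + 1L):eyes$end[i]] <- 1L
  }
  state$blocks <- x_new
  state$fired_total <- state$fired_total + length(firing)
  state
}

#' Advance the simulation by one round
#'
#' Composes [candidate_blocks()], [apply_factor_cap()] and
#' [fire_and_propagate()], then increments time.
#'
#' @inheritParams candidate_blocks
#' @return Updated `lattice_state` with attribute `n_fired` (initiations
#'   this round).
#' @export
step <- function(state, p, origin_map = NULL, region_mask = NULL) {
  cand <- candidate_blocks(state, p, origin_map, region_mask)
  firing <- apply_factor_cap(cand, state, p)
  state <- fire_and_propagate(state, firing, p)
  state$t <- state$t + 1L
  attr(state, "n_fired") <- length(firing)
  state
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> L = %d, t = %d rounds, f = %.4f, forks = %d\n",
              length(x$blocks), x$t, mean(x$blocks), nrow(fork_positions(x))))
  invisible(x)
}

#' Run one S phase of the origin-firing model
#'
#' Simulates replication of an `L`-block genome under any of MM1-MM5 until
#' the replicated fraction reaches `stop_f` (or completion), recording the
#' per-round replicated fraction, initiation count, newly replicated
#' blocks, fork count and factor ledger.
#'
#' The default engine is compiled and fast enough for genome-scale runs
#' and optimisation loops; `engine = "R"` uses the step-by-step reference
#' implementation ([step()]) and is intended for small lattices and
#' validation.
#'
#' @param p A `model_parameters` object.
#' @param L Lattice length in blocks (1 kb each).
#' @param seed Integer seed; if `NULL`, the current RNG stream is used.
#' @param stop_f Stop once the replicated fraction reaches this value.
#' @param max_rounds Round cap; exceeding it before `stop_f` is flagged in
#'   the result (`hit_round_cap`), never silent.
#' @param engine `"cpp"` or `"R"`.
#' @param snapshot_f Numeric vector of replicated fractions at which to
#'   keep full lattice copies (the lattice just before and just after each
#'   crossing is stored, for fraction matching).
#' @param record_times Record the round at which each block replicated.
#' @param record_firings Record every initiation event (position, round).
#' @param origin_map,region_mask Optional pre-built map/mask; generated
#'   from `p` when `NULL` (block-level mask with fraction `theta`).
#' @param initial_eyes Optional integer matrix (columns: start, end,
#'   0-based inclusive blocks) of pre-replicated intervals, each counted
#'   as one initiation; used e.g. to seed a single origin.
#' @return An object of class `replication_trajectory`: list with
#'   `trajectory` (tibble: `round`, `minutes`, `f`, `n_initiations`,
#'   `n_new_blocks`, `n_forks`, `nb`, `n_available`), `final_blocks`,
#'   `snapshots`, counters and the call parameters.
#' @examples
#' p <- model_parameters(N0 = 50, J = 5, Pout = 0.002, Pin = 0.2,
#'                       theta = 0.3, Plocal = 0.2, d = 20)
#' tr <- run_simulation(p, L = 5000, seed = 1)
#' head(tr$trajectory)
#' @export
run_simulation <- function(p, L, seed = NULL, stop_f = 1,
                           max_rounds = 5000L,
                           engine = c("cpp", "R"),
                           snapshot_f = numeric(0),
                           record_times = FALSE, record_firings = FALSE,
                           origin_map = NULL, region_mask = NULL,
                           initial_eyes = NULL) {
  engine <- match.arg(engine)
  validate_parameters(p)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(origin_map)) {
    origin_map <- generate_origin_map(L, p$origin_layout,
                                      p$mean_origin_spacing)
  }
  if (is.null(region_mask) && p$variant %in% c("MM4", "MM5") && p$theta > 0) {
    region_mask <- generate_region_mask(L, p$theta, "block")
  }
  use_local <- p$variant %in% c("MM3", "MM5")
  if (is.null(initial_eyes)) {
    initial_eyes <- matrix(integer(0), ncol = 2)
  }
  storage.mode(initial_eyes) <- "integer"

  if (engine == "cpp") {
    elig <- if (origin_map$layout == "continuous") NULL else origin_map$eligible
    msk <- if (is.null(region_mask)) NULL else region_mask$mask
    raw <- sim_run_cpp(
      L = as.integer(L), n0 = p$N0, j_rate = p$J,
      pout = p$Pout, pin = p$Pin, plocal = p$Plocal,
      use_local = use_local, d = as.integer(p$d),
      speed_choices = speed_choices_blocks(p),
      eligible_ = elig, in_mask_ = msk,
      f_stop = stop_f, max_rounds = as.integer(max_rounds),
      snapshot_f = as.numeric(snapshot_f),
      record_times = record_times, record_firings = record_firings,
      initial_eyes = initial_eyes,
      seed_lo = sample.int(.Machine$integer.max, 1) - 1,
      seed_hi = sample.int(.Machine$integer.max, 1) - 1)
    tr <- raw$trajectory
    colnames(tr) <- c("round", "f", "n_initiations", "n_new_blocks",
                      "n_forks", "nb", "n_available")
    trajectory <- as_tibble(as.data.frame(tr)) %>%
      mutate(minutes = .data$round * p$round_minutes,
             .after = "round")
    out <- list(trajectory = trajectory,
                final_blocks = raw$x,
                fired_total = raw$fired_total,
                released_total = raw$released_total,
                n_forks_final = raw$edges,
                f_final = raw$f,
                rounds = raw$rounds,
                hit_round_cap = raw$hit_round_cap,
                snapshots = raw$snapshots,
                times = if (record_times) raw$times else NULL,
                firings = if (record_firings)
                  as_tibble(as.data.frame(raw$firings)) else NULL)
  } else {
    state <- init_state(p, origin_map, region_mask, L)
    rows <- list()
    snapshots <- vector("list", length(snapshot_f))
    snapshot_f <- sort(snapshot_f)
    next_target <- 1L
    prev_blocks <- state$blocks
    prev_f <- 0
    hit_cap <- FALSE
    firings <- list()
    times <- rep(NA_integer_, L)
    repeat {
      f_now <- mean(state$blocks)
      if (f_now >= stop_f || f_now == 1) break
      if (state$t >= max_rounds) { hit_cap <- TRUE; break }
      prev_blocks <- state$blocks
      prev_f <- f_now
      before <- state$blocks
      state <- step(state, p, origin_map, region_mask)
      newly <- which(state$blocks == 1L & before == 0L)
      if (record_times) times[newly] <- state$t
      f_now <- mean(state$blocks)
      rows[[state$t]] <- tibble(
        round = state$t, minutes = state$t * p$round_minutes, f = f_now,
        n_initiations = attr(state, "n_fired"),
        n_new_blocks = length(newly),
        n_forks = nrow(fork_positions(state)),
        nb = bound_factors(state),
        n_available = floor(p$N0 + p$J * (state$t - 1L)) -
          nrow(fork_positions(prev_blocks)) / 2)
      while (next_target <= length(snapshot_f) &&
             f_now >= snapshot_f[next_target]) {
        snapshots[[next_target]] <- list(
          target = snapshot_f[next_target],
          round_before = state$t - 1L, round_at = state$t,
          f_before = prev_f, f_at = f_now,
          x_before = prev_blocks, x_at = state$blocks)
        next_target <- next_target + 1L
      }
    }
    edges <- nrow(fork_positions(state))
    out <- list(trajectory = bind_rows(rows),
                final_blocks = state$blocks,
                fired_total = state$fired_total,
                released_total = state$fired_total - edges / 2,
                n_forks_final = edges,
                f_final = mean(state$blocks),
                rounds = state$t,
                hit_round_cap = hit_cap,
                snapshots = snapshots,
                times = if (record_times) times else NULL,
                firings = NULL)
  }
  out$params <- p
  out$L <- L
  out$seed <- seed
  out$engine <- engine
  structure(out, class = "replication_trajectory")
}

#' @export
print.replication_trajectory <- function(x, ...) {
  cat(sprintf(
    "<replication_trajectory> %s, L = %d kb, %d rounds, f = %.3f%s\n",
    x$params$variant, x$L, x$rounds, x$f_final,
    if (isTRUE(x$hit_round_cap)) " (round cap reached)" else ""))
  cat(sprintf("  %g initiations, %g factors released\n",
              x$fired_total, x$released_total))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' @param traj A `replication_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(traj$trajectory, path)
  invisible(path)
}
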