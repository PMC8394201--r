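# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact nucleation-and-growth (KJMA-type) replicated fraction for the
# lattice model with per-block per-round firing probability p, unlimited
# factors, continuous origins and constant fork displacement v_b blocks
# per round. A block is unreplicated after t rounds iff no nucleation
# succeeded in its backward cone: an origin fired at round s covers, by
# round t, all blocks within v_b * (t - s) of itself plus its own block,
# so the cone holds sum_{k=0}^{t-1} (2 v_b k + 1) independent Bernoulli
# draws. Phantom nuclei in covered regions expand no faster than the eye
# covering them, so independence is exact (away from lattice ends).
kjma_fraction <- function(t, p, v_b = 1) {
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    n_draws <- sum(2 * v_b * (seq_len(tt) - 1) + 1)
    1 - (1 - p)^n_draws
  }, numeric(1))
}

# Brute-force reshaping oracle. Scoring rule: interior gaps <= min_gap
# are merged (iterated to a fixed point, enumerating EVERY possible merge
# order depth-first with memoisation and checking they all converge to
# the same eye set), then eyes <= min_eye are dropped. After a full merge
# pass all surviving interior gaps exceed min_gap, so dropping an eye can
# only create still-larger gaps and no new merge or drop ever becomes
# possible: one merge fixed point plus one drop pass is the fixed point
# of the whole procedure. Tracks are eye interval matrices (start, end).
reshape_oracle <- function(eyes, min_gap = 1, min_eye = 1) {
  memo <- new.env(parent = emptyenv())
  key <- function(m) paste(t(m), collapse = ",")
  merge_all <- function(m) {
    if (nrow(m) == 0) return(m)
    k <- key(m)
    if (!is.null(memo[[k]])) return(memo[[k]])
    n <- nrow(m)
    results <- list()
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        if (m[i + 1, 1] - m[i, 2] <= min_gap) {
          m2 <- m[-(i + 1), , drop = FALSE]
          m2[i, 2] <- max(m[i, 2], m[i + 1, 2])
          results[[length(results) + 1]] <- merge_all(m2)
        }
      }
    }
    if (length(results) == 0) {
      out <- m  # no mergeable gap left
    } else {
      out <- results[[1]]
      for (r in results[-1]) {
        if (!identical(r, out)) {
          stop("reshape oracle: merge order changed the result for ", k)
        }
      }
    }
    memo[[k]] <- out
    out
  }
  m <- merge_all(eyes)
  m[m[, 2] - m[, 1] > min_eye, , drop = FALSE]
}

# compare a reshaped annotation's eyes with an oracle interval matrix
expect_eyes_equal <- function(eyes_tbl, oracle) {
  testthat::expect_equal(nrow(eyes_tbl), nrow(oracle))
  if (nrow(oracle) > 0) {
    testthat::expect_equal(as.numeric(eyes_tbl$start),
                           as.numeric(oracle[, 1]))
    testthat::expect_equal(as.numeric(eyes_tbl$end),
                           as.numeric(oracle[, 2]))
  }
}

# eyes matrix from a binary vector (1 kb blocks)
eyes_from_bits <- function(bits) {
  r <- rle(as.integer(bits))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values == 1], ends[r$values == 1])
}

# enumerate all binary vectors of length n as rows
all_bit_strings <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  m[, rev(seq_len(n)), drop = FALSE]
}
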