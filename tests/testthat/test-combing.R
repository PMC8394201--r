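test_that("shredding with a point-mass length model tiles the genome", {
  set.seed(1)
  x <- integer(1e4)
  ds <- shred_genome(x, make_length_model("point", length_kb = 1e4))
  expect_equal(nrow(ds$molecules), 1)
  ds2 <- shred_genome(x, make_length_model("point", length_kb = 100))
  expect_equal(nrow(ds2$molecules), 100)
  expect_true(all(ds2$molecules$length_kb == 100))
})

test_that("shredded molecule lengths follow the length model (KS oracle)", {
  set.seed(2)
  lm_ <- make_length_model("lognormal", median_kb = 100, sdlog = 0.5)
  x <- integer(1e6)
  ds <- shred_genome(x, lm_)
  ref <- lm_(nrow(ds$molecules))
  ks <- suppressWarnings(ks.test(ds$molecules$length_kb, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("shredding preserves the replication content", {
  set.seed(3)
  p <- quick_params()
  tr <- run_simulation(p, 2e4, stop_f = 0.35)
  x <- tr$final_blocks
  for (i in 1:5) {
    ds <- shred_genome(x, make_length_model())
    # wrap-around shredding: only the final partial fragment is lost, so
    # the shredded global fraction tracks the genome fraction closely
    expect_lt(abs(global_fraction(ds) - mean(x)), 0.01)
    expect_lte(sum(ds$molecules$length_kb), 2e4)
    expect_gt(sum(ds$molecules$length_kb), 2e4 - 1000)
  }
})

test_that("reshaping merges small gaps and drops small eyes", {
  # eye 2 kb / gap 1 kb / eye 2 kb -> one 5 kb eye
  ann <- reshape_tracks(extract_tracks(c(1, 1, 0, 1, 1)))
  expect_equal(nrow(ann$eyes), 1)
  expect_equal(ann$eyes$length, 5)
  # an isolated 1 kb eye is not scored
  ann2 <- reshape_tracks(extract_tracks(c(0, 0, 1, 0, 0)))
  expect_equal(nrow(ann2$eyes), 0)
  # a 2 kb gap is significant and survives
  ann3 <- reshape_tracks(extract_tracks(c(1, 1, 0, 0, 1, 1)))
  expect_equal(ann3$eyes$length, c(2, 2))
})

test_that("reshaping equals the exhaustive merge-order oracle on all short tracks", {
  # longer tracks are covered exhaustively in the acceptance suite
  for (n in 2:8) {
    bits <- all_bit_strings(n)
    tracks <- lapply(seq_len(nrow(bits)), function(i) bits[i, ])
    ds <- dataset_from_tracks(tracks)
    got <- reshape_tracks(ds)$eyes
    oracle <- purrr::map_dfr(seq_len(nrow(bits)), function(i) {
      m <- reshape_oracle(eyes_from_bits(bits[i, ]))
      if (nrow(m) == 0) return(NULL)
      tibble::tibble(molecule_id = i, start = m[, 1], end = m[, 2])
    })
    expect_equal(as.data.frame(got), as.data.frame(oracle),
                 ignore_attr = TRUE)
  }
})

test_that("reshaping agrees with the oracle on random length-20 tracks and is idempotent", {
  set.seed(20)
  for (i in 1:300) {
    v <- sample(0:1, 20, replace = TRUE, prob = c(0.6, 0.4))
    ann <- reshape_tracks(extract_tracks(v))
    expect_eyes_equal(ann$eyes, reshape_oracle(eyes_from_bits(v)))
    twice <- reshape_tracks(ann)
    expect_equal(twice$eyes, ann$eyes)
  }
})

test_that("reshaping never decreases mean eye length nor increases eye count", {
  set.seed(6)
  for (i in 1:40) {
    v <- sample(0:1, 80, replace = TRUE)
    before <- extract_tracks(v)
    after <- reshape_tracks(before)
    expect_lte(nrow(after$eyes), nrow(before$eyes))
    if (nrow(after$eyes) > 0 && nrow(before$eyes) > 0) {
      expect_gte(mean(after$eyes$length), mean(before$eyes$length))
    }
  }
})

test_that("new firing events are eyes of length in (1, 3] kb", {
  ds <- dataset_from_tracks(list(
    c(0, 1, 1, 0, 0, 0, 1, 1, 1, 1),   # eyes 2 and 4 kb
    c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0),   # eye 3 kb
    integer(10)))
  counts <- classify_new_firings(reshape_tracks(ds))
  expect_equal(counts$n_new, c(1L, 1L, 0L))
  # a single annotation: 2 kb eye counts, 4 kb does not, 1 kb was dropped
  ann <- reshape_tracks(extract_tracks(c(1, 0, 0, 1, 1, 0, 0, 1, 1, 1, 1)))
  expect_equal(ann$eyes$length, c(2, 4))
  expect_equal(classify_new_firings(ann), 1L)
})

test_that("fraction matching returns the nearest simulated time within tolerance", {
  set.seed(9)
  p <- quick_params()
  tr <- run_simulation(p, 5e4, snapshot_f = c(0.08, 0.3), stop_f = 0.4)
  lm_ <- make_length_model()
  ds <- match_global_fraction(tr, lm_, 0.08, tol = 0.05)
  expect_lt(abs(global_fraction(ds) - 0.08), 0.05)
  expect_true(ds$source$round %in%
                c(tr$snapshots[[1]]$round_before, tr$snapshots[[1]]$round_at))
  # an impossible tolerance errors rather than returning silently
  expect_error(match_global_fraction(tr, lm_, 0.08, tol = 1e-6),
               "tolerance")
  # a fraction with no snapshot errors
  expect_error(match_global_fraction(tr, lm_, 0.9), "no snapshot")
})

test_that("per-molecule curves reproduce a brute-force group-by", {
  set.seed(10)
  tracks <- replicate(20, sample(0:1, 50, replace = TRUE), simplify = FALSE)
  ds <- reshape_tracks(dataset_from_tracks(tracks))
  pmc <- per_molecule_curves(ds, f_bins = 5, dt = 3)
  mol <- pmc$molecules
  # brute force per molecule
  for (i in seq_along(tracks)) {
    ann <- reshape_tracks(extract_tracks(tracks[[i]]))
    f <- sum(ann$eyes$length) / 50
    expect_equal(mol$f[mol$molecule_id == i], f)
    n_new <- classify_new_firings(ann)
    expect_equal(mol$n_new[mol$molecule_id == i], n_new)
    if (f < 1) {
      expect_equal(mol$I[mol$molecule_id == i], n_new / ((1 - f) * 50 * 3))
    }
    interior <- ann$eyes$start > 0 & ann$eyes$end < 50
    spanning <- ann$eyes$start <= 0 & ann$eyes$end >= 50
    expect_equal(mol$n_forks[mol$molecule_id == i],
                 sum(2 * interior + 1 * (!interior & !spanning)))
  }
  # bin averages equal the group-by mean of per-molecule values
  brute <- tapply(mol$I[!is.na(mol$I)],
                  cut(mol$f[!is.na(mol$I)], seq(0, 1, by = 0.2),
                      include.lowest = TRUE),
                  mean)
  got <- pmc$curves$I
  expect_equal(unname(got), as.numeric(brute[!is.na(brute)]))

  # degenerate cases
  ds0 <- dataset_from_tracks(list(integer(30)))
  m0 <- per_molecule_curves(ds0)$molecules
  expect_equal(m0$I, 0)
  expect_equal(m0$n_forks, 0)
})

test_that("molecule tables round-trip through the TSV format", {
  set.seed(12)
  p <- quick_params()
  tr <- run_simulation(p, 2e4, stop_f = 0.3)
  ds <- reshape_tracks(shred_genome(tr$final_blocks, make_length_model()))
  ds$molecules$genome_start <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write_molecules(ds, path)
  back <- read_molecules(path)
  expect_equal(back$molecules$length_kb, ds$molecules$length_kb)
  expect_equal(back$eyes$start, ds$eyes$start)
  expect_equal(back$eyes$end, ds$eyes$end)
  expect_equal(global_fraction(back), global_fraction(ds))
})

test_that("finite molecules under-detect long inter-initiation distances", {
  # end truncation: the mean observed eye-to-eye distance cannot exceed
  # the genome-wide mean distance between adjacent initiation events
  set.seed(14)
  p <- quick_params()
  tr <- run_simulation(p, 1e5, stop_f = 0.25, record_firings = TRUE)
  ds <- reshape_tracks(shred_genome(tr$final_blocks, make_length_model()))
  obs <- replifire:::dataset_tracks(ds)$eted
  genome_eted <- diff(sort(tr$firings$position))
  expect_lt(mean(obs), mean(genome_eted[genome_eted > 0]) * 1.05)
})
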