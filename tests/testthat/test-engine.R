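# The compiled engine and the R reference stepper implement the same
# model; the engine is additionally checked against analytic laws.

test_that("trajectories conserve factors and are monotone (both engines)", {
  set.seed(31)
  for (engine in c("cpp", "R")) {
    L <- if (engine == "cpp") 5000 else 800
    p <- quick_params()
    tr <- run_simulation(p, L = L, engine = engine, max_rounds = 2000)
    expect_equal(tr$f_final, 1)
    # at completion every sequestered factor has been released
    expect_equal(tr$fired_total, tr$released_total)
    tj <- tr$trajectory
    expect_true(all(diff(tj$f) >= 0))
    expect_true(all(tj$nb >= 0))
    expect_true(all(tj$nb <= p$N0 + p$J * tj$round))
    # fork edges = 2 Nb at all times
    expect_equal(tj$n_forks, 2 * tj$nb)
  }
})

test_that("zero firing probability leaves the lattice untouched until the cap", {
  p <- quick_params(Pout = 0, Pin = 0, Plocal = 0)
  tr <- run_simulation(p, L = 1000, seed = 1, max_rounds = 25)
  expect_equal(tr$f_final, 0)
  expect_true(tr$hit_round_cap)
  expect_equal(tr$rounds, 25)
})

test_that("same seed gives identical runs; different seeds differ", {
  p <- quick_params()
  a <- run_simulation(p, L = 3000, seed = 99)
  b <- run_simulation(p, L = 3000, seed = 99)
  d <- run_simulation(p, L = 3000, seed = 100)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_blocks, b$final_blocks)
  expect_false(identical(a$trajectory, d$trajectory))
})

test_that("snapshots bracket the requested fractions", {
  p <- quick_params()
  tr <- run_simulation(p, L = 5000, seed = 3, snapshot_f = c(0.2, 0.6))
  for (s in tr$snapshots) {
    expect_lt(s$f_before, s$target)
    expect_gte(s$f_at, s$target)
    expect_equal(mean(s$x_before), s$f_before)
    expect_equal(mean(s$x_at), s$f_at)
    expect_equal(s$round_at, s$round_before + 1)
  }
})

test_that("recorded replication times match the final lattice", {
  p <- quick_params()
  tr <- run_simulation(p, L = 2000, seed = 17, record_times = TRUE)
  expect_true(all(!is.na(tr$times)))
  expect_true(all(tr$times >= 1))
  expect_true(all(tr$times <= tr$rounds))
  # firing positions replicate at their firing round
  tr2 <- run_simulation(p, L = 2000, seed = 23, record_times = TRUE,
                        record_firings = TRUE)
  idx <- tr2$firings$position + 1L
  expect_equal(tr2$times[idx], tr2$firings$round)
  expect_equal(nrow(tr2$firings), tr2$fired_total)
})

test_that("single seeded origin grows one block per fork per round", {
  p <- quick_params(Pout = 0, Pin = 0, Plocal = 0, N0 = 1, J = 0)
  tr <- run_simulation(p, L = 2001, seed = 1, max_rounds = 500,
                       initial_eyes = matrix(c(1000L, 1000L), 1))
  tj <- tr$trajectory
  # eye length after t rounds is 1 + 2t until the ends are reached
  grow <- tj$f * 2001
  t_free <- tj$round[grow < 2001]
  expect_equal(grow[seq_along(t_free)], 1 + 2 * t_free)
  # per-fork velocity from half-eye length vs time: 0.5 kb/min
  half <- (grow[seq_along(t_free)] - 1) / 2
  fitv <- coef(lm(half ~ tj$minutes[seq_along(t_free)]))[2]
  expect_equal(unname(fitv), 0.5, tolerance = 1e-12)
})

test_that("engines agree distributionally on mean f(t)", {
  set.seed(77)
  p <- quick_params(N0 = 20, J = 2, Pout = 0.001, Pin = 0.05,
                    theta = 0.3, Plocal = 0.08, d = 10)
  L <- 1200
  n <- 50
  rounds <- 25
  fmat <- function(engine) {
    replicate(n, {
      tr <- run_simulation(p, L = L, engine = engine, stop_f = 1,
                           max_rounds = rounds)
      f <- tr$trajectory$f
      length(f) <- rounds
      f[is.na(f)] <- 1
      f
    })
  }
  fc <- fmat("cpp")
  fr <- fmat("R")
  mc <- rowMeans(fc)
  mr <- rowMeans(fr)
  se <- sqrt(apply(fc, 1, var) / n + apply(fr, 1, var) / n)
  keep <- se > 0
  expect_true(all(abs(mc - mr)[keep] < 4 * se[keep]))
  expect_lt(mean(abs(mc - mr)[keep] / se[keep]), 1.5)
})

test_that("one-round firing counts follow the truncated binomial law", {
  # fresh lattice, one round: firings ~ min(Binomial(L, Pout), N0)
  set.seed(19)
  L <- 400; pfire <- 0.02; cap <- 6
  p <- quick_params(N0 = cap, J = 0, Pout = pfire, variant = "MM1",
                    origin_layout = "continuous")
  sims <- replicate(2000, {
    tr <- run_simulation(p, L = L, max_rounds = 1, stop_f = 2)
    tr$trajectory$n_initiations[1]
  })
  # brute-force oracle distribution, low-mass left tail pooled so the
  # chi-squared approximation is sound
  pk <- dbinom(0:L, L, pfire)
  oracle <- c(sum(pk[1:4]), pk[5:cap], sum(pk[(cap + 1):(L + 1)]))
  counts <- tabulate(sims + 1, nbins = cap + 1)
  obs <- c(sum(counts[1:4]), counts[5:(cap + 1)])
  expect_gt(chisq.test(obs, p = oracle)$p.value, 0.01)
})
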