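test_that("initial state is empty with N0 factors available", {
  p <- quick_params()
  st <- init_state(p, L = 100)
  expect_equal(mean(st$blocks), 0)
  expect_equal(bound_factors(st), 0)
  expect_equal(st$t, 0L)
  # available factors at t = 0 equal N0
  expect_equal(floor(p$N0 + p$J * st$t) - bound_factors(st), p$N0)
  om <- generate_origin_map(50, "continuous")
  expect_error(init_state(p, om, L = 100), "does not match")
})

test_that("candidate draws respect probabilities, masks and replication state", {
  p0 <- quick_params(Pout = 0, Pin = 0, Plocal = 0)
  st <- init_state(p0, L = 200)
  expect_length(candidate_blocks(st, p0), 0)

  p1 <- quick_params(Pout = 1, Pin = 1, Plocal = 1, theta = 1)
  expect_length(candidate_blocks(st, p1), 200)

  # replicated blocks never fire
  st$blocks[1:50] <- 1L
  expect_true(all(candidate_blocks(st, p1) >= 50))

  # ineligible blocks never fire
  set.seed(4)
  om <- generate_origin_map(200, "discrete", 3)
  cand <- candidate_blocks(init_state(p1, om), p1, origin_map = om)
  expect_setequal(cand, which(om$eligible) - 1L)

  # Monte Carlo mean candidate count on a fresh lattice is L * Pout
  set.seed(8)
  p <- quick_params(Pout = 0.05, variant = "MM1")
  st <- init_state(p, L = 500)
  counts <- replicate(400, length(candidate_blocks(st, p)))
  expected <- 500 * 0.05
  sd_bin <- sqrt(500 * 0.05 * 0.95)
  expect_lt(abs(mean(counts) - expected), 3 * sd_bin / sqrt(400))
})

test_that("fork-proximal zone is truncated at ends and replicated blocks", {
  x <- integer(60)
  x[21:30] <- 1L   # eye [20, 30); right fork at 29, left fork at 20
  st <- init_state(quick_params(), L = 60)
  st$blocks <- x
  expect_length(fork_proximal_zone(st, 0), 0)
  z3 <- fork_proximal_zone(st, 3)
  expect_setequal(z3, c(17, 18, 19, 30, 31, 32))
  # truncation at a neighbouring eye: zone stops at next replicated block
  x2 <- x; x2[34:35] <- 1L
  st$blocks <- x2
  z <- fork_proximal_zone(st, 10)
  expect_true(all(c(30, 31, 32) %in% z))
  expect_false(33 %in% z)           # replicated: zone stops there
  expect_true(36 %in% z)            # ahead of the second eye's right fork
  # truncation at the lattice end
  x3 <- integer(60); x3[59:60] <- 1L
  st$blocks <- x3
  expect_setequal(fork_proximal_zone(st, 5), 53:57)
})

test_that("factor cap limits firing to the available pool", {
  p <- quick_params(N0 = 10, J = 0)
  st <- init_state(p, L = 100)
  expect_equal(apply_factor_cap(c(1, 5, 9), st, p), c(1, 5, 9))
  set.seed(2)
  fired <- apply_factor_cap(0:99, st, p)
  expect_length(fired, 10)
  expect_true(all(fired %in% 0:99))
  p0 <- quick_params(N0 = 0, J = 0)
  expect_length(apply_factor_cap(0:99, st, p0), 0)
})

test_that("eyes grow symmetrically by 2 blocks and coalesce with fork loss", {
  p <- quick_params(Pout = 0, Pin = 0, Plocal = 0)
  st <- init_state(p, L = 100)
  st$blocks[41:45] <- 1L                      # eye of 5 blocks
  st2 <- step(st, p)
  expect_equal(sum(st2$blocks), 7)            # +2 blocks per round
  expect_equal(lattice_eyes(st2)$start, 39)
  expect_equal(lattice_eyes(st2)$end, 46)

  # two eyes separated by one block coalesce; fork count drops by 2
  st$blocks <- integer(100)
  st$blocks[c(40:42, 44:46)] <- 1L
  expect_equal(nrow(fork_positions(st)), 4)
  st3 <- step(st, p)
  expect_equal(nrow(lattice_eyes(st3)), 1)
  expect_equal(nrow(fork_positions(st3)), 2)
  expect_equal(bound_factors(st3), 1)
})

test_that("MM2 fork displacement has mean 3 blocks per round", {
  set.seed(13)
  p <- quick_params(variant = "MM2", Pout = 0, Pin = 0)
  st <- init_state(p, L = 5000)
  st$blocks[2500] <- 1L
  disp <- replicate(300, {
    s2 <- step(st, p)
    (sum(s2$blocks) - 1) / 2          # per-fork displacement
  })
  # mean of {0,1,2,3} kb/min over 2 min = 3 blocks; SE of the mean
  se <- sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp) - 3), 3 * se)
  expect_setequal(sort(unique(disp)), c(0, 1, 2, 3, 4, 5, 6) / 1)
})

test_that("a full step conserves factors and leaves f non-decreasing", {
  set.seed(5)
  p <- quick_params()
  om <- generate_origin_map(2000, "discrete", 2.3)
  mk <- generate_region_mask(2000, p$theta, "block")
  st <- init_state(p, om, mk)
  f_prev <- 0
  for (i in 1:40) {
    st <- step(st, p, om, mk)
    f <- mean(st$blocks)
    expect_gte(f, f_prev)
    f_prev <- f
    nb <- bound_factors(st)
    expect_gte(nb, 0)
    expect_lte(nb, p$N0 + p$J * st$t)
  }
  # nothing happens when no factors and no candidates
  p0 <- quick_params(N0 = 0, J = 0)
  st0 <- init_state(p0, L = 500)
  st1 <- step(st0, p0)
  expect_equal(st1$blocks, st0$blocks)
  expect_equal(st1$t, 1L)
})

test_that("saturating probabilities with ample factors finish in one round", {
  p <- model_parameters(N0 = 1000, J = 0, Pin = 1, Pout = 1, Plocal = 1,
                        theta = 1, d = 0, variant = "MM4",
                        origin_layout = "continuous")
  st <- init_state(p, L = 500)
  mk <- generate_region_mask(500, 1, "block")
  st <- step(st, p, NULL, mk)
  expect_equal(mean(st$blocks), 1)
})
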