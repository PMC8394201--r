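test_that("fitness closed forms hold exactly", {
  exp_c <- make_toy_curves(c(1, 2, 3))
  # identical curves -> 0
  expect_equal(as.numeric(curve_fitness(exp_c, exp_c)), 0)
  # offset by mean(exp) at each of n points -> n
  sim <- exp_c
  sim$i_rate$value <- exp_c$i_rate$value + mean(exp_c$i_rate$value)
  expect_equal(as.numeric(curve_fitness(sim, exp_c)), 3)
  # hand toy: exp (1,2,3) vs sim (1,2,4) -> (0+0+1)/2^2 = 1/4
  sim2 <- exp_c
  sim2$i_rate$value <- c(1, 2, 4)
  expect_equal(as.numeric(curve_fitness(sim2, exp_c)), 1 / 4)
})

test_that("fitness is reorder-invariant and positive for differing curves", {
  exp_c <- make_toy_curves(c(2, 4, 6, 8))
  sim <- exp_c
  sim$i_rate$value <- c(8, 2, 6, 4)   # same multiset, different positions
  f1 <- as.numeric(curve_fitness(sim, exp_c))
  # permuting the point order within both curves together leaves it unchanged
  perm <- c(3, 1, 4, 2)
  exp_p <- exp_c; exp_p$i_rate$value <- exp_c$i_rate$value[perm]
  sim_p <- sim;  sim_p$i_rate$value <- sim$i_rate$value[perm]
  expect_equal(as.numeric(curve_fitness(sim_p, exp_p)), f1)
  expect_gt(f1, 0)
  # mismatched grids are refused
  other <- make_toy_curves(c(1, 2, 3))
  expect_error(curve_fitness(other, exp_c), "grids")
})

test_that("curve averaging is pointwise over replicate experiments", {
  a <- make_toy_curves(c(1, 2, 3))
  b <- make_toy_curves(c(3, 2, 1))
  av <- average_curves(list(a, b))
  expect_equal(av$i_rate$value, c(2, 2, 2))
})

test_that("the genetic algorithm minimises a convex surrogate within bounds", {
  set.seed(5)
  target <- c(120, 0.3, 800)
  lower <- c(1, 0, 0)
  upper <- c(2000, 1, 4000)
  fn <- function(x) sum(((x - target) / (upper - lower))^2)
  cfg <- ga_config(generations = 25)
  fit <- ga_optimize(fn, lower, upper, cfg, seed = 1)
  expect_true(all(fit$population >= rep(lower, each = nrow(fit$population))))
  expect_true(all(fit$population <= rep(upper, each = nrow(fit$population))))
  expect_true(all(diff(fit$trace$best) <= 0))      # elitism monotonicity
  expect_true(all(abs(fit$best_par - target) / (upper - lower) < 0.05))
  # determinism under a fixed seed
  fit2 <- ga_optimize(fn, lower, upper, cfg, seed = 1)
  expect_identical(fit$best_par, fit2$best_par)
})

test_that("parameter vectors decode into the right variant defaults", {
  p1 <- replifire:::params_from_vector(c(100, 10, 0.05), "MM1")
  expect_equal(p1$Pout, 0.05)
  expect_equal(p1$Pin, 0.05)     # inactive Pin collapses onto Pout
  expect_equal(p1$theta, 0)
  p5 <- replifire:::params_from_vector(c(100, 10, 0.05, 0.3, 0.4, 0.5, 50),
                                       "MM5")
  expect_equal(p5$Plocal, 0.4)
  expect_equal(p5$d, 50)
})

test_that("fit_condition optimises MM1 fits end to end", {
  # end-to-end machinery check: the coupled simulate/shred/reshape/
  # fitness objective is minimised well below a random-search baseline
  # at a small budget. Recovery tolerances are the acceptance suite's
  # job (and need the full budget).
  spec <- synthetic_spec(
    parameters = model_parameters(N0 = 600, J = 60, Pout = 0.04,
                                  Pin = 0.04, Plocal = 0.04, theta = 0,
                                  d = 0, variant = "MM1",
                                  origin_layout = "continuous"),
    L = 1e5, fractions = c(0.15, 0.4), n_molecules = 800)
  syn <- generate_dataset(spec, seed = 21)
  cfg <- ga_config(generations = 6)
  fit <- fit_condition(unname(syn$datasets), variant = "MM1", L = 5e4,
                       config = cfg, repeats = 2, seed = 31,
                       round_cap = 250, origin_layout = "continuous")
  expect_s3_class(fit, "replication_fit")
  expect_equal(nrow(fit$runs), 2)
  ens <- parameter_ensemble(fit)
  expect_setequal(ens$parameter, c("N0", "J", "Pout"))
  expect_true(all(ens$sd >= 0))
  # random-search baseline on the same objective
  ds2 <- lapply(unname(syn$datasets), reshape_tracks)
  samples <- lapply(ds2, function(d) {
    list(target = global_fraction(d), lengths = d$molecules$length_kb,
         curves = observable_curves(d))
  })
  targets <- vapply(samples, `[[`, numeric(1), "target")
  objective <- replifire:::make_fit_objective(
    samples, targets, "MM1", 5e4, 250, 3, "continuous", 1)
  b <- parameter_bounds("MM1")
  set.seed(77)
  baseline <- replicate(20, objective(runif(3, b$lower, b$upper)))
  expect_lt(max(fit$runs$fitness), median(baseline) / 2)
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_setequal(unique(td$parameter), c("N0", "J", "Pout"))
  expect_equal(nrow(glance(fit)), 1)
})

test_that("ensembles from identical seeds show no significant differences", {
  rf <- function(seed, shift = 0) {
    runs <- tibble::tibble(run = 1:20, seed = seed,
                           fitness = 1,
                           N0 = rnorm(20, 100 + shift, 5),
                           J = rnorm(20, 10, 1),
                           Pout = rnorm(20, 0.01, 0.001))
    structure(list(runs = runs, parameters = c("N0", "J", "Pout")),
              class = "replication_fit")
  }
  set.seed(1); a <- rf(1)
  set.seed(1); b <- rf(1)
  cmp <- compare_parameters(a, b)
  expect_equal(nrow(cmp), 3)
  expect_false(any(cmp$significant))
  # a 5-SD shift in N0 only flags N0
  set.seed(2); a2 <- rf(1)
  set.seed(3); b2 <- rf(1, shift = 25)
  cmp2 <- compare_parameters(a2, b2)
  expect_true(cmp2$significant[cmp2$parameter == "N0"])
  expect_false(any(cmp2$significant[cmp2$parameter != "N0"]))
  expect_equal(cmp2$direction[cmp2$parameter == "N0"], "increase")
})

test_that("wrong-J ensembles are flagged on J alone across replicates", {
  # simulation of the Welch-test decision over repeated draws
  set.seed(9)
  hits <- replicate(40, {
    a <- tibble::tibble(run = 1:15, seed = 1, fitness = 1,
                        N0 = rnorm(15, 100, 10), J = rnorm(15, 10, 1))
    b <- tibble::tibble(run = 1:15, seed = 2, fitness = 1,
                        N0 = rnorm(15, 100, 10), J = rnorm(15, 15, 1))
    fa <- structure(list(runs = a, parameters = c("N0", "J")),
                    class = "replication_fit")
    fb <- structure(list(runs = b, parameters = c("N0", "J")),
                    class = "replication_fit")
    cmp <- compare_parameters(fa, fb)
    cmp$significant[cmp$parameter == "J"] &&
      !cmp$significant[cmp$parameter == "N0"]
  })
  expect_gte(mean(hits), 0.95)
})
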