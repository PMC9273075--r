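test_that("population initialisation is seeded, clamped and N(1,1)-shaped", {
  cfg <- ga_config()
  set.seed(5); p1 <- init_population(cfg, K = 3)
  set.seed(5); p2 <- init_population(cfg, K = 3)
  expect_identical(p1, p2)                       # determinism contract
  expect_equal(dim(p1), c(500L, 3L))             # 1500 genes
  expect_true(all(p1 >= cfg$clamp_floor))
  # empirical gene mean ~ clamped-normal mean (closed-form oracle)
  a <- cfg$clamp_floor; z <- (a - 1) / 1
  mu_trunc <- a * pnorm(z) + 1 * (1 - pnorm(z)) + 1 * dnorm(z)
  se <- sd(p1) / sqrt(length(p1))
  expect_lt(abs(mean(p1) - mu_trunc), 3 * se)
})

test_that("breeding keeps the population size and the crossover contract", {
  cfg <- ga_config(pop_size = 40, n_parents = 20, n_elite = 6,
                   p_mutation = 0)
  K <- 5
  # each individual is a constant row, so gene provenance is identifiable
  pop <- matrix(rep(1:40, K), 40, K)
  fitness <- as.numeric(1:40)       # already sorted: parents are rows 1..20
  set.seed(6)
  nxt <- breed(pop, fitness, cfg)
  expect_equal(dim(nxt), dim(pop))                     # constant pop size
  expect_identical(nxt[1:6, ], pop[1:6, ] + 0)         # elites unchanged
  # with p_mutation = 0 every child gene comes from a top-20 parent
  kids <- nxt[7:40, ]
  expect_true(all(kids %in% 1:20))
  # and each child mixes exactly two distinct parents
  n_parents_per_kid <- apply(kids, 1, function(g) length(unique(g)))
  expect_true(all(n_parents_per_kid <= 2))

  # unevaluated individuals cannot be bred
  expect_error(breed(pop, c(NA, fitness[-1]), cfg), "unevaluated")
})

test_that("selection is truncation by fitness with stable ties", {
  cfg <- ga_config(pop_size = 30, n_parents = 10, n_elite = 4,
                   p_mutation = 0)
  pop <- matrix(rep(1:30, 2), 30, 2)
  fitness <- rev(seq(10, 300, by = 10))   # best individuals are at the bottom
  set.seed(7)
  nxt <- breed(pop, fitness, cfg)
  # every parent fitness <= every discarded fitness: genes only from rows
  # whose fitness ranks in the top 10 (rows 21..30 here)
  expect_true(all(nxt[5:30, ] %in% 21:30))
  expect_identical(nxt[1:4, 1], c(30, 29, 28, 27))  # elites in fitness order
})

test_that("degenerate elitism reproduces the population unchanged", {
  cfg <- ga_config(pop_size = 12, n_parents = 12, n_elite = 12)
  pop <- matrix(runif(12 * 3, 0.5, 2), 12, 3)
  fitness <- runif(12)
  nxt <- breed(pop, fitness, cfg)
  expect_equal(nxt, pop[order(fitness), ])
})

test_that("mutation perturbs at most one gene per child and clamps", {
  cfg <- ga_config(pop_size = 200, n_parents = 100, n_elite = 10,
                   p_mutation = 1)
  pop <- matrix(1, 200, 4)          # identical parents: crossover is identity
  set.seed(8)
  nxt <- breed(pop, rep(1, 200), cfg)
  kids <- nxt[11:200, ]
  changed <- rowSums(kids != 1)
  expect_true(all(changed == 1))    # exactly one gene moved per child
  expect_true(all(kids >= cfg$clamp_floor))
  # perturbations are standard normal draws around the parent gene
  deltas <- kids[kids != 1] - 1
  big <- abs(deltas) < 3            # clamping truncates the left tail
  expect_gt(length(deltas), 150)
  expect_lt(abs(mean(deltas[deltas > -0.9]) ), 0.35)
})

test_that("the GA run is deterministic under a fixed seed and elitist", {
  spec <- small_spec(seed = 9)
  r <- make_banded_raster(spec)
  sites <- simulate_sites(r, spec)
  cfg <- sim_config(spec$t0, spec$v0, origin = spec$origin)
  ga <- ga_config(pop_size = 60, n_parents = 30, n_elite = 6,
                  n_generations = 6, seed = 99)
  f1 <- run_ga(r, sites, cfg, ga)
  f2 <- run_ga(r, sites, cfg, ga)
  expect_identical(f1$trace, f2$trace)           # bit-identical trace
  expect_identical(f1$best_costs, f2$best_costs)
  expect_true(all(diff(f1$trace$best_rmse) <= 0))  # elitism monotonicity
  expect_equal(f1$best_rmse, min(f1$trace$best_rmse))
})

test_that("single-class recovery matches the closed-form optimum within 5%", {
  # On a one-class raster the optimum is cost = v0 * (t0 - t_i) / D_i for
  # every site simultaneously (noiseless data), i.e. the true cost.
  spec <- synth_spec(n_rows = 20, n_cols = 40, cell_size = 10, K = 1,
                     true_speeds = 1.25, n_sites = 10, t0 = 3000, seed = 10)
  r <- make_banded_raster(spec)
  sites <- simulate_sites(r, spec)
  # closed form from any single site: unweighted (cost = 1) distance vs lag
  D_unit <- accumulate_cost(r, 1, origin = spec$origin,
                            targets = cell_from_xy(r, sites$x, sites$y))
  expect_equal(spec$v0 * (spec$t0 - sites$observed_cal_bp[5]) / D_unit[5],
               spec$true_costs, tolerance = 1e-9)
  cfg <- sim_config(spec$t0, spec$v0, origin = spec$origin)
  fit <- run_ga(r, sites, cfg, ga_config(seed = 10))
  expect_lt(abs(fit$best_speeds - 1.25) / 1.25, 0.05)
})
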