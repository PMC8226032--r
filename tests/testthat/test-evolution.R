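test_that("the 2- and 3-neuron models have 20 and 30 evolvable parameters", {
  expect_identical(genotype_length(2), 20L)
  expect_identical(genotype_length(3), 30L)
  # layout arithmetic: n^2 recurrent + 2n sensor + 3n actuator + 6 shared
  expect_identical(genotype_length(2), 4L + 4L + 6L + 6L)
  expect_identical(genotype_length(3), 9L + 6L + 9L + 6L)
})

test_that("decoding maps [-1, 1] linearly onto each parameter range", {
  rng <- scaling_ranges()
  p_lo <- decode_genotype(rep(-1, 20), 2, rng)
  p_hi <- decode_genotype(rep(1, 20), 2, rng)
  p_mid <- decode_genotype(rep(0, 20), 2, rng)
  expect_equal(unique(as.vector(p_lo$w_rec)), rng$weights[1])
  expect_equal(unique(as.vector(p_hi$w_rec)), rng$weights[2])
  expect_equal(unique(as.vector(p_mid$w_sens)), mean(rng$weights))
  expect_equal(p_lo$tau, rep(rng$taus[1], 2))
  expect_equal(p_hi$tau, rep(rng$taus[2], 2))
  expect_equal(p_mid$gain, rep(mean(rng$gains), 2))
  expect_equal(p_mid$sensor_bias, mean(rng$biases))
  expect_error(decode_genotype(rep(0, 21), 2), "length")
  expect_error(decode_genotype(rep(2, 20), 2), "\\[-1, 1\\]")
})

test_that("decoding is injective for distinct genotypes", {
  set.seed(31)
  g1 <- random_genotype(2)
  g2 <- g1
  g2[7] <- g2[7] + 0.01 * sign(0.5 - g2[7])
  p1 <- decode_genotype(g1, 2)
  p2 <- decode_genotype(g2, 2)
  expect_false(isTRUE(all.equal(p1, p2)))
})

test_that("evaluation is deterministic and bounded", {
  set.seed(32)
  cfg <- ga_config("desk", trial_duration = 20)
  g <- random_genotype(2)
  f1 <- evaluate_genotype(g, "IE", 2, cfg)
  f2 <- evaluate_genotype(g, "IE", 2, cfg)
  expect_identical(f1, f2)
  expect_gte(f1, 0)
  expect_lte(f1, 1)
  gp <- random_genotype(2, pair = TRUE)
  expect_identical(evaluate_genotype(gp, "SE", 2, cfg),
                   evaluate_genotype(gp, "SE", 2, cfg))
})

test_that("a genotype decoding to midpoint weights yields near-zero entropy", {
  # all-zero weights: constant neural outputs, a single occupied cell
  cfg <- ga_config("desk", trial_duration = 20)
  g <- rep(0, 20)  # weight classes have symmetric ranges, so 0 -> 0
  f <- evaluate_genotype(g, "IE", 2, cfg)
  expect_lt(f, 0.02)
})

test_that("a silent emitter makes pair members match their decoupled entropy", {
  set.seed(33)
  cfg <- ga_config("desk", trial_duration = 50)
  g1 <- random_genotype(2)
  # force the emitter actuator silent: zero its column weights and set
  # its shared bias strongly negative via the actuator-bias gene
  g1[11:16] <- 0           # actuator weights
  g1[20] <- -1             # actuator bias -> range minimum (-8)
  p <- decode_genotype(g1, 2)
  p$w_act[, 3] <- 0
  p$actuator_bias <- -30   # emitter output ~ sigmoid(-30) ~ 0
  spec <- make_trials("SE")[[1]]
  coupled <- run_trial(spec, list(p, p), duration = 50)
  solo <- run_trial(make_trials("IE")[[1]], p, duration = 50,
                    sense_input = FALSE)
  e_coupled <- multidim_entropy(
    as.matrix(coupled[coupled$agent_id == 1, c("out_1", "out_2")]), 50)
  e_solo <- multidim_entropy(as.matrix(solo[, c("out_1", "out_2")]), 50)
  expect_equal(e_coupled, e_solo, tolerance = 1e-6)
})

test_that("elites are copied verbatim and sized by the ceiling rule", {
  set.seed(34)
  cfg <- ga_config("full")
  pop <- matrix(runif(96 * 20, -1, 1), 96, 20)
  fit <- runif(96)
  ng <- next_generation(pop, fit, cfg)
  expect_identical(ng$n_elite, 4)            # ceiling(0.04 * 96)
  best4 <- pop[order(fit, decreasing = TRUE)[1:4], ]
  expect_equal(ng$population[1:4, ], best4)
  expect_identical(ng$elite_fitness, sort(fit, decreasing = TRUE)[1:4])
  expect_equal(dim(ng$population), c(96L, 20L))
})

test_that("degenerate operators reproduce the parent exactly", {
  set.seed(35)
  cfg <- ga_config("desk", population = 10, mutation_variance = 0,
                   crossover_prob = 0)
  pop <- matrix(runif(10 * 20, -1, 1), 10, 20)
  fit <- seq(0.1, 1, length.out = 10)
  ng <- next_generation(pop, fit, cfg)
  parent <- pop[which.max(fit), ]
  for (i in (ng$n_elite + 1):10)
    expect_equal(unname(ng$population[i, ]), parent)
})

test_that("GA operations preserve genotype bounds", {
  set.seed(36)
  cfg <- ga_config("desk", population = 20, mutation_variance = 1)
  pop <- matrix(runif(20 * 30, -1, 1), 20, 30)
  for (it in 1:10) {
    ng <- next_generation(pop, runif(20), cfg)
    pop <- ng$population
    expect_true(all(pop >= -1 & pop <= 1))
  }
})

test_that("evolution runs are monotone in best fitness and seed-reproducible", {
  cfg <- ga_config("desk", population = 8, generations = 6,
                   trial_duration = 20)
  r1 <- evolve_run("IE", 2, cfg, seed = 99)
  r2 <- evolve_run("IE", 2, cfg, seed = 99)
  expect_true(all(diff(r1$history$best) >= 0))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_genotype, r2$best_genotype)
  expect_identical(r1$best_fitness, max(r1$history$best))
  r3 <- evolve_run("SE", 2, cfg, seed = 100)
  expect_true(all(diff(r3$history$best) >= 0))
  expect_length(r3$best_genotype, 40L)
})

test_that("short evolution improves over the initial random population", {
  # optimization sanity oracle at reduced scale, paired across seeds
  cfg <- ga_config("desk", population = 12, generations = 15,
                   trial_duration = 50)
  gains <- vapply(1:5, function(s) {
    r <- evolve_run("IE", 2, cfg, seed = 200 + s)
    r$best_fitness - r$history$best[1]
  }, numeric(1))
  expect_true(all(gains >= 0))
  expect_gt(mean(gains), 0.01)
})
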