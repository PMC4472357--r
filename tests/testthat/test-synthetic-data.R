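m13 <- bdm_model(1, 3)

test_that("simulation configs validate their fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_plants = 0), "n_plants")
  expect_error(sim_config(epsilon = 0.5), "epsilon")
  expect_error(sim_config(epsilon = -0.1), "epsilon")
  expect_error(sim_config(seeds_per_plant = 0.5), "seeds_per_plant")
  expect_error(sim_config(overdispersion = 1), "overdispersion")
  expect_error(sim_config(seed = 1.5), "seed")
})

test_that("simulators are bit-reproducible from the config seed", {
  cfg <- sim_config(model = m13, n_plants = 60, seed = 77)
  expect_identical(simulate_f2_cohort(cfg), simulate_f2_cohort(cfg))
  sim1 <- simulate_f2_experiment(cfg)
  sim2 <- simulate_f2_experiment(cfg)
  expect_identical(sim1$records, sim2$records)
  expect_identical(simulate_f1_selfing(cfg), simulate_f1_selfing(cfg))
  expect_identical(simulate_ril_panel(cfg, n_generations = 3),
                   simulate_ril_panel(cfg, n_generations = 3))
  # a different seed moves the draws
  cfg2 <- sim_config(model = m13, n_plants = 60, seed = 78)
  expect_false(identical(simulate_f2_cohort(cfg), simulate_f2_cohort(cfg2)))
})

test_that("F2 cohort frequencies converge to the exact class distribution", {
  n <- 2e4
  cfg <- sim_config(model = m13, n_plants = n, seed = 5)
  cohort <- simulate_f2_cohort(cfg)
  d <- f2_class_distribution(m13)
  q <- bdmseed:::.donor_rates(cohort$genotype, m13)
  for (i in seq_along(d$class)) {
    f <- as.numeric(d$freq[i])
    emp <- mean(q == as.numeric(d$class[i]))
    se <- sqrt(f * (1 - f) / n)
    expect_lt(abs(emp - f), 3 * se + 1e-9)
  }
  # unconditioned sampling restores the 1/64 mass of the 100% class
  cfg_u <- sim_config(model = m13, n_plants = n, seed = 6,
                      conditioned = FALSE)
  qu <- bdmseed:::.donor_rates(simulate_f2_cohort(cfg_u)$genotype, m13)
  f_u <- 1 / 64
  expect_lt(abs(mean(qu == 1) - f_u), 3 * sqrt(f_u * (1 - f_u) / n))
})

test_that("backcross panels abort at the genotype-determined binomial rate", {
  cfg0 <- sim_config(model = m13, n_plants = 400, epsilon = 0, seed = 9,
                     fixed_seeds = TRUE, seeds_per_plant = 30)
  # class-0 donors never abort, class-1 donors always do (eps = 0)
  cohort0 <- data.frame(plant_id = paste0("z", 1:400),
                        genotype = "rr|aabbcc")
  rec0 <- simulate_backcross_panel(cohort0, cfg0)
  expect_true(all(rec0$n_aborted == 0))
  cohort1 <- data.frame(plant_id = paste0("o", 1:400),
                        genotype = "rr|AABBCC")
  rec1 <- simulate_backcross_panel(cohort1, cfg0)
  expect_true(all(rec1$n_aborted == rec1$n_seeds))

  # mean observed rate of a 1/8-class donor approaches 0.125
  n <- 5000
  cfg8 <- sim_config(model = m13, n_plants = n, epsilon = 0, seed = 10,
                     fixed_seeds = TRUE, seeds_per_plant = 30)
  cohort8 <- data.frame(plant_id = paste0("e", 1:n),
                        genotype = "rr|AaBbCc")
  rec8 <- simulate_backcross_panel(cohort8, cfg8)
  pooled <- sum(rec8$n_aborted) / sum(rec8$n_seeds)
  se <- sqrt(0.125 * 0.875 / (30 * n))
  expect_lt(abs(pooled - 0.125), 3 * se)

  # seeds-per-plant is truncated at one seed
  cfg_tp <- sim_config(model = m13, n_plants = 500, seeds_per_plant = 1.2,
                       seed = 11)
  rec_tp <- simulate_backcross_panel(
    data.frame(genotype = rep("rr|aabbcc", 500)), cfg_tp)
  expect_true(all(rec_tp$n_seeds >= 1))
})

test_that("scoring noise flips calls at rate epsilon", {
  n <- 4000
  cfg <- sim_config(model = m13, n_plants = n, epsilon = 0.05, seed = 12,
                    fixed_seeds = TRUE, seeds_per_plant = 50)
  rec <- simulate_backcross_panel(
    data.frame(genotype = rep("rr|aabbcc", n)), cfg)
  pooled <- sum(rec$n_aborted) / sum(rec$n_seeds)
  se <- sqrt(0.05 * 0.95 / (50 * n))
  expect_lt(abs(pooled - 0.05), 3 * se)
})

test_that("F1 selfing series matches the model abortion rate", {
  cfg <- sim_config(model = m13, epsilon = 0, seed = 13)
  rec <- simulate_f1_selfing(cfg)
  expect_equal(nrow(rec), 7L)
  expect_equal(sum(rec$n_seeds), 207)
  # pooled over many replicate series, the abortion fraction approaches 1/16
  set.seed(14)
  cfg0 <- sim_config(model = m13, epsilon = 0)
  pooled <- replicate(300, {
    r <- simulate_f1_selfing(cfg0)
    sum(r$n_aborted) / sum(r$n_seeds)
  })
  se <- sqrt(1 / 16 * 15 / 16 / 207) / sqrt(300)
  expect_lt(abs(mean(pooled) - 1 / 16), 4 * se)
  # the 1x2 model aborts at 1/8 instead
  cfg2 <- sim_config(model = bdm_model(1, 2), epsilon = 0, seed = 15)
  set.seed(15)
  pooled2 <- replicate(300, {
    r <- simulate_f1_selfing(sim_config(model = bdm_model(1, 2), epsilon = 0))
    sum(r$n_aborted) / sum(r$n_seeds)
  })
  expect_lt(abs(mean(pooled2) - 1 / 8), 4 * sqrt(1 / 8 * 7 / 8 / 207 / 300))
})

test_that("simulated single-seed descent matches the exact propagator", {
  # one generation: empirical genotype frequencies within 3 SE of the exact
  # survivor distribution of the selfed F1
  n <- 2e4
  cfg <- sim_config(model = m13, seed = 16)
  ril1 <- simulate_ril_panel(cfg, n_generations = 1, n_lines = n)
  exact <- self_cross(f1_genotype(m13), m13)
  tab <- table(ril1$genotype)
  for (k in sample(exact$survivors$genotype, 25)) {
    f <- as.numeric(exact$survivors$freq[exact$survivors$genotype == k])
    emp <- if (k %in% names(tab)) tab[[k]] / n else 0
    expect_lt(abs(emp - f), 3 * sqrt(f * (1 - f) / n) + 1e-9)
  }

  # deep panels purge: the abortion-triggering fraction falls below the
  # no-selection fixation bound 1/8 and most lines trigger nothing
  cfg2 <- sim_config(model = m13, seed = 17)
  ril6 <- simulate_ril_panel(cfg2, n_generations = 6, n_lines = 2000)
  q <- bdmseed:::.donor_rates(ril6$genotype, m13)
  expect_lt(mean(q > 0), 1 / 8)
  expect_gt(mean(q == 0), 0.5)
  # and the empirical trigger fraction sits near the exact value
  exact6 <- as.numeric(ril_panel_distribution(m13, 6)$trigger_fraction)
  expect_lt(abs(mean(q > 0) - exact6),
            3 * sqrt(exact6 * (1 - exact6) / 2000))
})

test_that("beta-binomial overdispersion widens per-plant variation", {
  n <- 3000
  base <- sim_config(model = m13, n_plants = n, epsilon = 0, seed = 18,
                     fixed_seeds = TRUE, seeds_per_plant = 40)
  over <- sim_config(model = m13, n_plants = n, epsilon = 0, seed = 18,
                     fixed_seeds = TRUE, seeds_per_plant = 40,
                     overdispersion = 0.3)
  cohort <- data.frame(genotype = rep("rr|AaBbCc", n))
  v0 <- var(simulate_backcross_panel(cohort, base)$n_aborted)
  v1 <- var(simulate_backcross_panel(cohort, over)$n_aborted)
  expect_gt(v1, 1.5 * v0)
})
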