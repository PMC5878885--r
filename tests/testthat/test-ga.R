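# A cheap deterministic fitness seam: separable weighted bit sum, whose
# global optimum is "select exactly the positive-weight bits".
weighted_fitness <- function(weights) {
  function(mask) 0.5 + sum(weights * mask) / (4 * sum(abs(weights)))
}

test_that("initial populations are fair coins and seed-reproducible", {
  p1 <- evospec:::with_seed(5, init_population(50, 200))
  p2 <- evospec:::with_seed(5, init_population(50, 200))
  expect_identical(p1, p2)
  expect_identical(dim(p1), c(200L, 50L))
  expect_true(all(p1 %in% c(0L, 1L)))
  expect_gt(mean(p1), 0.45)
  expect_lt(mean(p1), 0.55)
})

test_that("tournament selection frequency matches enumeration", {
  pop <- rbind(c(0L, 0L), c(1L, 1L), c(1L, 0L))
  fits <- c(0.5, 0.7, 0.6)
  wins <- evospec:::with_seed(9, {
    mean(replicate(4000, all(tournament_select(pop, fits, 3) == c(1L, 1L))))
  })
  # P(best of 3 draws with replacement includes index 2) = 1 - (2/3)^3
  expect_equal(wins, 1 - (2 / 3)^3, tolerance = 0.03)

  # symmetric fitness: every individual wins about 1/3 of tournaments
  sym <- evospec:::with_seed(10, {
    mean(replicate(3000, tournament_select(pop, c(1, 1, 1), 3)[1] == 0L))
  })
  expect_equal(sym, 1 / 3, tolerance = 0.05)

  one <- matrix(c(1L, 0L, 1L), nrow = 1)
  expect_identical(tournament_select(one, 0.4, 1), one[1, ])
  expect_error(tournament_select(matrix(integer(0), 0, 3), numeric(0), 2),
               class = "evospec_validation_error")
})

test_that("uniform crossover exchanges the expected number of bits", {
  a <- rep(1L, 40)
  b <- rep(0L, 40)
  ch <- evospec:::with_seed(1, uniform_crossover(a, b, 0))
  expect_identical(ch$child_a, a)
  expect_identical(ch$child_b, b)
  ch <- evospec:::with_seed(1, uniform_crossover(a, a, 0.7))
  expect_identical(ch$child_a, a)

  hams <- evospec:::with_seed(2, {
    replicate(2000, sum(uniform_crossover(a, b, 0.2)$child_a != a))
  })
  expect_equal(mean(hams), 0.2 * sum(a != b), tolerance = 0.05)
  expect_error(uniform_crossover(a, b[-1], 0.2),
               class = "evospec_validation_error")
})

test_that("bit-flip mutation inverts bits at the configured rate", {
  m <- rep_len(c(0L, 1L), 100)
  expect_identical(evospec:::with_seed(1, bit_flip_mutate(m, 0)), m)
  expect_identical(evospec:::with_seed(1, bit_flip_mutate(m, 1)), 1L - m)
  flips <- evospec:::with_seed(3, {
    replicate(3000, sum(bit_flip_mutate(m, 0.05) != m))
  })
  expect_equal(mean(flips), 100 * 0.05, tolerance = 0.05)
})

test_that("ga_config carries the standard control parameters and validates", {
  cfg <- ga_config()
  expect_identical(cfg$population_size, 40L)
  expect_identical(cfg$generations, 100L)
  expect_identical(cfg$tournament_k, 3L)
  expect_equal(cfg$crossover_rate, 0.6)
  expect_equal(cfg$mixing_ratio, 0.2)
  expect_equal(cfg$mutation_rate, 0.2)
  expect_equal(cfg$bit_flip_rate, 0.05)
  expect_identical(cfg$k_folds, 5L)
  expect_error(ga_config(crossover_rate = 1.4),
               class = "evospec_validation_error")
  expect_error(ga_config(population_size = 1),
               class = "evospec_validation_error")
  expect_error(ga_config(tournament_k = 99),
               class = "evospec_validation_error")
})

test_that("evolve finds the optimum of a separable landscape", {
  co <- small_cohort(40)  # hierarchy supplies n; fitness_fn replaces CV
  weights <- evospec:::with_seed(8, runif(6, -1, 1))
  fn <- weighted_fitness(weights)
  cfg <- ga_config(generations = 25, rng_seed = 2, mode = "flattened")
  res <- evolve(co, cfg, fitness_fn = fn)
  expect_identical(res$best_mask, as.integer(weights > 0))
  expect_equal(res$best_fitness, fn(as.integer(weights > 0)))
  # elitism: best fitness never decreases
  expect_true(all(diff(res$history$best) >= 0))
  # hall of fame is sorted by fitness, masks distinct
  expect_true(all(diff(res$hall_of_fame$fitness) <= 0))
  expect_identical(anyDuplicated(apply(res$hall_of_fame$masks, 1, paste,
                                       collapse = "")), 0L)
})

test_that("evolve is reproducible and generation zero degenerates cleanly", {
  sim <- tiny_sim(2500)
  cfg <- ga_config(generations = 4, rng_seed = 31, fold_seed = 17,
                   population_size = 12, mode = "hierarchical")
  r1 <- evolve(sim$cohort, cfg)
  r2 <- evolve(sim$cohort, cfg)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$hall_of_fame, r2$hall_of_fame)

  r0 <- evolve(sim$cohort, ga_config(generations = 0, rng_seed = 31,
                                     fold_seed = 17, population_size = 12))
  expect_identical(nrow(r0$history), 1L)
  expect_identical(r0$evaluations, r0$fitness_calls)
})

test_that("cached fitness equals a fresh evaluation", {
  sim <- tiny_sim(2500)
  cfg <- ga_config(generations = 3, rng_seed = 4, fold_seed = 23,
                   population_size = 10, mode = "flattened")
  res <- evolve(sim$cohort, cfg)
  fresh <- cv_fitness(sim$cohort, res$best_mask, "flattened",
                      fold_seed = 23)$auc
  expect_identical(res$best_fitness, fresh)
  # the hall of fame fitness values are pure functions of the masks too
  for (i in seq_len(min(3, nrow(res$hall_of_fame$masks)))) {
    expect_identical(
      res$hall_of_fame$fitness[i],
      cv_fitness(sim$cohort, res$hall_of_fame$masks[i, ], "flattened",
                 fold_seed = 23)$auc)
  }
})

test_that("exhaustive search enumerates every mask and matches brute force", {
  h <- complaint_hierarchy(c(fever = "infection"))
  co_rec <- make_records(20, h)
  co1 <- new_cohort(co_rec, h)
  ex <- exhaustive_search(co1, "flattened", fold_seed = 3, k_folds = 2)
  expect_identical(nrow(ex$table), 2L)

  co <- small_cohort(40)
  weights <- evospec:::with_seed(12, runif(6, -1, 1))
  fn <- weighted_fitness(weights)
  ex <- exhaustive_search(co, "flattened", fitness_fn = fn)
  expect_identical(nrow(ex$table), 64L)
  all_fits <- vapply(0:63, function(i) {
    fn(as.integer(intToBits(i))[1:6])
  }, numeric(1))
  expect_equal(ex$best_fitness, max(all_fits))
  expect_gte(ex$best_fitness, fn(rep(0L, 6)))
  expect_error(exhaustive_search(co, "flattened", max_n = 5),
               class = "evospec_domain_error")
})
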