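test_that("initial model sizes cover the configured range uniformly", {
  d <- make_random_dataset(n = 30L, m = 20L, seed = 41L)
  ek <- build_expert_knowledge(d)
  # collapsed range
  cfg1 <- search_config(init_size_center = 1L, init_size_delta = 0L)
  withr::with_seed(6L, {
    sizes1 <- replicate(200, length(sample_initial_model(ek, 20L, cfg1)))
  })
  expect_true(all(sizes1 == 1L))
  # defaults: sizes 1..5 approximately uniform over 10,000 draws
  cfg <- search_config()
  withr::with_seed(7L, {
    sizes <- replicate(10000, length(sample_initial_model(ek, 20L, cfg)))
  })
  expect_setequal(sort(unique(sizes)), 1:5)
  expect_gt(stats::chisq.test(table(factor(sizes, levels = 1:5)))$p.value,
            0.001)
})

test_that("forced expert-knowledge path pairs a SNP with its best partner", {
  d <- make_random_dataset(n = 30L, m = 10L, seed = 43L)
  ek <- build_expert_knowledge(d)
  cfg <- search_config(init_size_center = 2L, init_size_delta = 0L,
                       ek_seed_prob = 1)
  withr::with_seed(8L, {
    for (i in 1:100) {
      m <- sample_initial_model(ek, 10L, cfg)
      expect_identical(m[2], ek$best_partner[m[1]])
    }
  })
})

test_that("any-point crossover swaps tails, dedups and can grow children", {
  # identical parents: children are subsets of the parent SNP set, and
  # whenever the two cut points coincide the children equal the parents
  found_equal <- FALSE
  for (s in 1:50) {
    kids <- withr::with_seed(s, any_point_crossover(c(1L, 2L, 3L),
                                                    c(1L, 2L, 3L)))
    expect_true(all(unlist(kids) %in% 1:3))
    if (identical(kids, list(c(1L, 2L, 3L), c(1L, 2L, 3L)))) found_equal <- TRUE
  }
  expect_true(found_equal)
  # find a seed that draws cut points (1, 1) for 2-SNP parents
  found <- FALSE
  for (s in 1:200) {
    kids <- withr::with_seed(s, any_point_crossover(c(1L, 2L), c(3L, 4L)))
    if (identical(kids, list(c(1L, 4L), c(3L, 2L)))) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
  # growth beyond either parent's length
  lens <- vapply(1:200, function(s) {
    kids <- withr::with_seed(s, any_point_crossover(c(1L, 2L, 3L), c(2L, 5L)))
    max(lengths(kids))
  }, 0L)
  expect_identical(max(lens), 4L)
  # children never contain duplicates and never exceed the cap
  withr::with_seed(10L, {
    for (i in 1:200) {
      a <- sample.int(30L, sample(1:8, 1))
      b <- sample.int(30L, sample(1:8, 1))
      kids <- any_point_crossover(a, b, max_size = 10L)
      for (k in kids) {
        expect_identical(anyDuplicated(k), 0L)
        expect_gte(length(k), 1L)
        expect_lte(length(k), 10L)
      }
    }
  })
})

test_that("mutation hits positions at the configured rate", {
  m <- c(3L, 7L, 11L)
  expect_identical(mutate_model(m, 20L, 0), m)
  withr::with_seed(11L, {
    m1 <- mutate_model(m, 20L, 1)
  })
  expect_true(all(m1 != m))
  expect_identical(anyDuplicated(m1), 0L)
  withr::with_seed(12L, {
    hits <- replicate(20000, sum(mutate_model(m, 1000L, 0.05) != m))
  })
  rate_hat <- mean(hits) / 3
  se <- sqrt(0.05 * 0.95 / (3 * 20000))
  expect_lt(abs(rate_hat - 0.05), 3 * se)
})

test_that("invalid configurations are rejected before any evaluation", {
  expect_error(search_config(ek_seed_prob = 1.5), "0, 1")
  expect_error(search_config(task_pop = 0), "sizes")
  d <- make_random_dataset(n = 30L, m = 10L, seed = 45L)
  expect_error(
    run_mdr_search(d, search_config(steady_state_pop = 100L,
                                    evaluation_budget = 50L), seed = 1L),
    "at least"
  )
})

test_that("the evaluation cache scores each SNP set once", {
  d <- make_random_dataset(n = 40L, m = 8L, seed = 47L)
  ek <- build_expert_knowledge(d)
  ev <- epiqmdr:::make_evaluator(d, ek, budget = 10L)
  s1 <- ev$evaluate(list(c(1L, 3L), c(3L, 1L), c(2L, 5L)))
  expect_identical(ev$evals(), 2L)          # {1,3} scored once despite reorder
  expect_equal(s1[1, ], s1[2, ])
  s2 <- ev$evaluate(list(c(1L, 3L)))
  expect_identical(ev$evals(), 2L)          # cache hit consumes no budget
  expect_equal(s2[1, ], s1[1, ])
})

test_that("a zero-generation task returns its seed population unchanged", {
  sim <- make_planted_fixture(seed = 49L, n = 200L, m = 12L)
  ek <- build_expert_knowledge(sim$dataset)
  ev <- epiqmdr:::make_evaluator(sim$dataset, ek, budget = 100L)
  seeds <- list(c(1L, 2L), c(3L, 4L, 5L), 6L)
  sc <- ev$evaluate(seeds)
  cfg <- search_config(task_generations = 0L)
  res <- epiqmdr:::run_evolutionary_task(seeds, sc, ev, 12L, cfg)
  expect_identical(res$pop$models, seeds)
  expect_false(res$exhausted)
  expect_identical(ev$evals(), 3L)
})

test_that("searches are reproducible and respect the evaluation budget", {
  sim <- make_planted_fixture(seed = 51L, n = 300L, m = 20L)
  cfg <- search_config(steady_state_pop = 60L, task_pop = 20L,
                       task_generations = 5L, n_tasks_per_round = 2L,
                       evaluation_budget = 1500L)
  r1 <- run_mdr_search(sim$dataset, cfg, seed = 5L)
  r2 <- run_mdr_search(sim$dataset, cfg, seed = 5L)
  expect_identical(r1$pareto_front, r2$pareto_front)
  expect_identical(r1$evaluations, r2$evaluations)
  expect_identical(r1$history, r2$history)
  expect_lte(r1$evaluations, cfg$evaluation_budget)
  # every front model respects the size and distinctness invariants
  expect_true(all(vapply(r1$pareto_front$snps, anyDuplicated, 0L) == 0L))
  expect_true(all(r1$pareto_front$size >= 1L &
                    r1$pareto_front$size <= cfg$max_model_size))
  # front models are mutually nondominated
  f <- r1$pareto_front
  expect_true(all(oracle_nds(f$t_statistic, f$interaction_info, f$size) == 0L))
  b1 <- run_random_search(sim$dataset, cfg, seed = 6L, budget = 1500L)
  b2 <- run_random_search(sim$dataset, cfg, seed = 6L, budget = 1500L)
  expect_identical(b1$pareto_front, b2$pareto_front)
  expect_identical(b1$evaluations, 1500L)
})

test_that("a budget-1 random search returns its single model as the front", {
  d <- make_random_dataset(n = 40L, m = 10L, seed = 53L)
  r <- run_random_search(d, search_config(), seed = 7L, budget = 1L)
  expect_identical(nrow(r$pareto_front), 1L)
  expect_identical(r$evaluations, 1L)
  expect_identical(r$pareto_front$pareto_rank, 0L)
})

test_that("elitism keeps the best t-statistic from round to round", {
  sim <- make_planted_fixture(seed = 55L, n = 400L, m = 20L)
  cfg <- search_config(steady_state_pop = 50L, task_pop = 20L,
                       task_generations = 5L, n_tasks_per_round = 2L,
                       evaluation_budget = 2000L)
  res <- run_mdr_search(sim$dataset, cfg, seed = 9L)
  expect_true(all(diff(res$history$best_t) >= 0))
  expect_true(all(diff(res$history$evaluations) > 0))
})
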