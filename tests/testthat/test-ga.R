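test_that("wrapper fitness is the inverse-shifted objective", {
  df <- data.frame(a = c(1, 2, 3, 4))
  y <- c(0, 0, 1, 1)
  for (g in c(0, 1, 3)) {
    out <- wrapper_fitness(df, y, 1L, objective = function(x, yy) g)
    expect_equal(out$fitness, 1 / (1 + g))
    expect_equal(out$objective, g)
  }
  # strictly decreasing in g, bounded in (0, 1]
  gs <- seq(0, 10, by = 0.5)
  fs <- vapply(
    gs, function(g) wrapper_fitness(df, y, 1L, objective = function(...) g)$fitness,
    numeric(1)
  )
  expect_true(all(diff(fs) < 0))
  expect_true(all(fs > 0 & fs <= 1))
  expect_error(wrapper_fitness(df, y, 0L), "empty")
})

test_that("the default random-forest objective is seeded and reproducible", {
  co <- tiny_cohort()
  a <- wrapper_fitness(co$data, co$labels, rep(1L, 13), num_trees = 30, seed = 5)
  b <- wrapper_fitness(co$data, co$labels, rep(1L, 13), num_trees = 30, seed = 5)
  expect_identical(a, b)
  expect_gt(a$objective, 0)
  expect_lt(a$fitness, 1)
})

test_that("the memoised fitness closure returns cached values verbatim", {
  calls <- 0
  fn <- fitness_function(
    data.frame(a = 1:4, b = 4:1), c(0, 1, 0, 1),
    objective = function(x, y) {
      calls <<- calls + 1
      ncol(x)
    }
  )
  m <- c(1L, 1L)
  expect_equal(fn(m), fn(m))
  expect_equal(calls, 1)
  fn(c(1L, 0L))
  expect_equal(calls, 2)
})

test_that("initial populations are non-empty, sized, and seed-reproducible", {
  pop <- init_population(13, 20, seed = 7)
  expect_length(pop, 20)
  expect_true(all(vapply(pop, sum, numeric(1)) >= 1))
  expect_true(all(vapply(pop, length, integer(1)) == 13))
  expect_identical(pop, init_population(13, 20, seed = 7))
  # one feature: repair forces the only bit
  expect_true(all(vapply(init_population(1, 10, seed = 1), identical, logical(1), 1L)))
})

test_that("subset-based fitness-proportional selection follows the stated law", {
  pop <- lapply(1:5, function(i) {
    m <- integer(5)
    m[i] <- 1L
    m
  })
  # degenerate proportionality: the only fit individual always wins
  fits <- c(1, 0, 0, 0, 0)
  picks <- replicate(50, select_parent(pop, fits, subset_size = 5),
                     simplify = FALSE)
  expect_true(all(vapply(picks, identical, logical(1), pop[[1]])))

  # subset larger than the population clamps to the whole population
  expect_silent(select_parent(pop[1:3], c(1, 1, 1), subset_size = 5, seed = 1))

  # equal fitness: empirical selection frequencies uniform within +/- 0.02
  pop_id <- lapply(1:5, function(i) c(i, 1L))
  counts <- integer(5)
  with_seed_drawn <- withr::with_seed(123, {
    for (r in 1:10000) {
      pick <- select_parent(pop_id, rep(1, 5), subset_size = 5)
      counts[pick[1]] <- counts[pick[1]] + 1L
    }
  })
  expect_true(all(abs(counts / 10000 - 0.2) < 0.02))

  expect_warning(select_parent(pop, rep(0, 5), seed = 1), "zero")
})

test_that("single-point crossover swaps tails and conserves set bits", {
  kids <- crossover_single_point(rep(1L, 7), rep(0L, 7), cut = 3)
  expect_equal(kids[[1]], c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(kids[[2]], c(0L, 0L, 0L, 1L, 1L, 1L, 1L))

  p <- c(1L, 0L, 1L, 1L)
  expect_equal(crossover_single_point(p, p, seed = 1), list(p, p))

  set.seed(21)
  for (i in 1:50) {
    a <- rbinom(10, 1, 0.5)
    b <- rbinom(10, 1, 0.5)
    a[1] <- 1L; b[2] <- 1L # keep pre-repair masks non-empty
    cut <- sample(1:9, 1)
    kids <- crossover_single_point(a, b, cut = cut)
    expect_equal(sum(kids[[1]]) + sum(kids[[2]]), sum(a) + sum(b))
  }
  expect_error(crossover_single_point(1L, 1L), "at least 2")
  expect_error(crossover_single_point(c(1L, 0L), c(1L, 0L, 1L)), "equal length")
})

test_that("bit-flip mutation matches its binomial law and repairs empties", {
  m <- c(1L, 0L, 1L, 0L)
  expect_equal(mutate_mask(m, 0, seed = 1), m)
  expect_equal(mutate_mask(m, 1, seed = 1), c(0L, 1L, 0L, 1L))
  # prob 1 on an all-ones mask flips everything, then repair turns one bit on
  expect_equal(sum(mutate_mask(rep(1L, 5), 1, seed = 3)), 1)

  flips <- withr::with_seed(77, {
    vapply(1:100, function(i) {
      base <- rep(0:1, length.out = 1000)
      sum(mutate_mask(base, 0.1) != base)
    }, numeric(1))
  })
  expect_lt(abs(mean(flips) - 100), 10)
})

test_that("the GA trace is non-decreasing under elitism and runs are seed-stable", {
  co <- tiny_cohort()
  cfg <- ga_config(population_size = 10, generations = 8, seed = 31)
  res <- run_ga(co$data, co$labels, cfg, fitness = tiny_fitness())
  expect_s3_class(res, "optimization_result")
  expect_length(res$trace, 8)
  expect_true(all(diff(res$trace) >= 0))
  expect_equal(res$best_fitness, max(res$trace))
  expect_gte(sum(res$best_mask), 1)

  res2 <- run_ga(co$data, co$labels, cfg, fitness = tiny_fitness())
  expect_identical(res$best_mask, res2$best_mask)
  expect_identical(res$trace, res2$trace)

  gl <- glance(res)
  expect_equal(gl$n_selected, sum(res$best_mask))
  td <- tidy(res)
  expect_equal(td$best_fitness, res$trace)
})

test_that("with no mutation, no crossover and full elitism the population is invariant", {
  co <- tiny_cohort()
  cfg <- ga_config(
    population_size = 6, generations = 5, per_gene_mutation_prob = 0,
    elitism = 6, crossover = FALSE, seed = 4
  )
  res <- run_ga(co$data, co$labels, cfg, fitness = tiny_fitness())
  expect_true(all(res$trace == res$trace[1]))
})

test_that("GA recovers informative features more often than noise", {
  co <- tiny_cohort()
  fn <- tiny_fitness()
  runs <- lapply(1:8, function(s) {
    run_ga(
      co$data, co$labels,
      ga_config(population_size = 12, generations = 10, seed = 100 + s),
      fitness = fn
    )
  })
  freq <- selection_frequency(runs)
  margin <- recovery_margin(freq, co$truth$informative)
  expect_gt(margin$margin, 0)
})
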