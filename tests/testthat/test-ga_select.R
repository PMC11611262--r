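# A deliberately small GA setup keeps fitness evaluations cheap: tiny
# chromosomes over a small feature space with a fast 3-fold fitness.
tiny_data <- function(seed = 1) {
  generate_feature_matrix(planted_matrix_spec(
    n_samples = 60, n_features = 20, n_informative = 3, effect_size = 2,
    seed = seed))
}
tiny_config <- function(...) {
  ga_config(population_size = 6L, generations = 2L, chromosome_size = 5L,
            crossover_repeats = 3L, cv_folds = 3L, seed = 1L, ...)
}

test_that("init_population draws uniform fixed-size subsets, seeded", {
  cfg <- ga_config(population_size = 60L, chromosome_size = 100L, seed = 9L)
  pop <- init_population(499L, cfg)
  expect_length(pop, 60L)
  expect_true(all(vapply(pop, length, integer(1)) == 100L))
  expect_true(all(vapply(pop, anyDuplicated, integer(1)) == 0L))
  expect_true(all(unlist(pop) >= 1L & unlist(pop) <= 499L))
  expect_identical(pop, init_population(499L, cfg))
  expect_error(init_population(99L, cfg), "chromosome_size")

  # gene frequency approximately uniform at 100/499 over many chromosomes
  big <- init_population(499L, ga_config(population_size = 1000L,
                                         chromosome_size = 100L, seed = 3L))
  freq <- tabulate(unlist(big), nbins = 499L) / 1000
  expect_equal(mean(freq), 100 / 499, tolerance = 1e-9)
  expect_true(all(abs(freq - 100 / 499) < 0.06))
})

test_that("fitness is CV AUC on the chromosome's columns, with caching", {
  g <- tiny_data()
  cfg <- tiny_config()
  folds <- make_cv_folds(g$y, 3, 1)
  cache <- new.env(parent = emptyenv())
  genes <- sort(c(g$informative, setdiff(1:20, g$informative)[1:2]))
  f1 <- evaluate_fitness(genes, g$X, g$y, cfg, folds, cache)
  expect_gt(f1, 0.9)                      # contains the separating features
  n1 <- cache$.n_evals
  f2 <- evaluate_fitness(genes, g$X, g$y, cfg, folds, cache)
  expect_identical(f2, f1)
  expect_identical(cache$.n_evals, n1)    # served from cache, no retraining
  # pure-noise chromosome hovers near chance
  noise <- sort(setdiff(1:20, g$informative)[1:5])
  expect_lt(abs(evaluate_fitness(noise, g$X, g$y, cfg, folds, cache) - 0.5), 0.35)
})

test_that("select_parents takes the top third by fitness, stable on ties", {
  cfg <- ga_config(population_size = 60L, chromosome_size = 3L)
  pop <- lapply(1:60, function(i) c(i, i + 100L, i + 200L))
  fit <- seq(1, 0.9, length.out = 60)
  par <- select_parents(pop, fit, cfg)
  expect_length(par, 20L)
  expect_identical(par, pop[1:20])        # brute-force top third
  # worst chromosome never selected under a strict ordering
  expect_false(any(vapply(par, identical, logical(1), pop[[60]])))
  # ties broken by insertion order
  par2 <- select_parents(pop, rep(0.5, 60), cfg)
  expect_identical(par2, pop[1:20])
})

test_that("mutation preserves cardinality and escalates passes", {
  cfg <- ga_config(chromosome_size = 100L, mutation_prob = 0)
  genes <- sort(sample.int(499L, 100L))
  expect_identical(mutate(genes, 499L, cfg, 0L), genes)  # prob 0 -> identity
  # pass count: 1 at generation 0, 3 at generation 12 (escalate every 5)
  expect_identical(1L + 0L %/% 5L, 1L)
  expect_identical(1L + 12L %/% 5L, 3L)
  # Monte-Carlo: expected replacements per pass ~ 100 * 3e-4 = 0.03
  cfg2 <- ga_config(chromosome_size = 100L, mutation_prob = 3e-4)
  nrep <- withr::with_seed(8, {
    sum(vapply(1:20000, function(i) {
      sum(!(mutate(genes, 499L, cfg2, 0L) %in% genes))
    }, numeric(1)))
  })
  expect_equal(nrep / 20000, 0.03, tolerance = 0.15)
  # mutated chromosomes stay valid
  withr::with_seed(9, {
    for (i in 1:50) {
      m <- mutate(genes, 499L, ga_config(mutation_prob = 0.2), 12L)
      expect_length(m, 100L)
      expect_identical(anyDuplicated(m), 0L)
    }
  })
})

test_that("offspring competition returns a valid winner at least as fit as its rivals", {
  g <- tiny_data()
  cfg <- tiny_config()
  folds <- make_cv_folds(g$y, 3, 1)
  cache <- new.env(parent = emptyenv())
  withr::with_seed(10, {
    for (trial in 1:10) {
      pa <- sort(sample.int(20L, 5L)); pb <- sort(sample.int(20L, 5L))
      win <- crossover_offspring_competition(pa, pb, g$X, g$y, cfg, 0L,
                                             folds, cache)
      expect_length(win$genes, 5L)
      expect_identical(anyDuplicated(win$genes), 0L)
      # winner's fitness is the maximum over the competing candidates
      expect_gte(win$fitness,
                 evaluate_fitness(win$genes, g$X, g$y, cfg, folds, cache) - 1e-12)
    }
    # identical parents with mutation off reproduce themselves
    cfg0 <- tiny_config(mutation_prob = 0)
    pa <- sort(sample.int(20L, 5L))
    win0 <- crossover_offspring_competition(pa, pa, g$X, g$y, cfg0, 0L,
                                            folds, cache)
    expect_identical(win0$genes, pa)
  })
})

test_that("evolve keeps population invariants, monotone elitism and reproducibility", {
  g <- tiny_data()
  cfg <- tiny_config()
  r1 <- evolve(g$X, g$y, cfg)
  r2 <- evolve(g$X, g$y, cfg)
  expect_identical(r1$best, r2$best)              # bit-reproducible
  expect_identical(r1$history, r2$history)
  expect_length(r1$best$genes, 5L)
  expect_identical(anyDuplicated(r1$best$genes), 0L)
  # best fitness never decreases (elitist carry-over)
  expect_true(all(diff(r1$history$best_fitness) >= 0))
  expect_identical(nrow(r1$history), 2L)
  expect_error(evolve(g$X[, 1:3], g$y, cfg), "chromosome_size")
})

test_that("the GA enriches planted informative features over random subsets", {
  g <- generate_feature_matrix(planted_matrix_spec(
    n_samples = 80, n_features = 60, n_informative = 8, effect_size = 1.5,
    seed = 11))
  cfg <- ga_config(population_size = 10L, generations = 2L,
                   chromosome_size = 15L, crossover_repeats = 4L,
                   cv_folds = 3L, seed = 2L)
  r <- evolve(g$X, g$y, cfg)
  got <- sum(r$best$genes %in% g$informative)
  random_expect <- 15 * 8 / 60            # = 2
  expect_gt(got, random_expect)
})
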