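# Offspring-competition genetic algorithm: selects a fixed-cardinality
# feature subset (chromosome) maximizing cross-validated SVM AUC.
# Per generation: the top third of the population by fitness become parents;
# random parent pairs each produce `crossover_repeats` candidate offspring by
# two-point crossover + mutation, and only the fittest candidate survives
# (the "offspring competition"); pairing rounds repeat until the population
# is refilled; the best individual is carried over (elitism).

#' Genetic-algorithm configuration
#'
#' Defaults are the published operating point: population 60, 150
#' generations, 100-gene chromosomes, per-gene mutation probability 3e-4,
#' 10 competing offspring per parent pair, top third as parents, mutation
#' passes escalating every 5 generations.
#'
#' @param population_size chromosomes per generation.
#' @param generations number of generations.
#' @param chromosome_size genes (features) per chromosome.
#' @param mutation_prob per-gene replacement probability per mutation pass.
#' @param crossover_repeats candidate offspring per parent pair.
#' @param parent_fraction fraction of the population kept as parents.
#' @param breeding_rounds nominal pairing rounds per generation (pairing in
#'   fact repeats until the population is refilled).
#' @param mutation_escalation_period generations between mutation-pass
#'   increments (`passes = 1 + floor(generation / period)`).
#' @param seed integer seed driving the whole run.
#' @param cv_folds folds of the fitness cross-validation.
#' @param cost,gamma fitness SVM hyperparameters (`gamma = NULL`:
#'   `1/chromosome_size`).
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 60L, generations = 150L,
                      chromosome_size = 100L, mutation_prob = 3e-4,
                      crossover_repeats = 10L, parent_fraction = 1 / 3,
                      breeding_rounds = 3L, mutation_escalation_period = 5L,
                      seed = 1L, cv_folds = 5L, cost = 1, gamma = NULL) {
  stopifnot(population_size >= 2L, generations >= 1L, chromosome_size >= 1L,
            mutation_prob >= 0, mutation_prob <= 1, crossover_repeats >= 1L,
            parent_fraction > 0, parent_fraction <= 1,
            mutation_escalation_period >= 1L, cv_folds >= 2L)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 chromosome_size = as.integer(chromosome_size),
                 mutation_prob = mutation_prob,
                 crossover_repeats = as.integer(crossover_repeats),
                 parent_fraction = parent_fraction,
                 breeding_rounds = as.integer(breeding_rounds),
                 mutation_escalation_period = as.integer(mutation_escalation_period),
                 seed = as.integer(seed), cv_folds = as.integer(cv_folds),
                 cost = cost, gamma = gamma),
            class = "ga_config")
}

# Chromosomes are kept as sorted integer vectors of distinct feature indices.
.validate_chromosome <- function(genes, feature_count, size) {
  stopifnot(length(genes) == size, !anyDuplicated(genes),
            all(genes >= 1L), all(genes <= feature_count))
  invisible(genes)
}

.random_chromosome <- function(feature_count, size) {
  sort(sample.int(feature_count, size))
}

#' Initialize a random population
#'
#' Uniform random fixed-size subsets of the feature indices, seeded by
#' `config$seed`.
#'
#' @param feature_count number of available features (must be >=
#'   `chromosome_size`).
#' @param config a [ga_config()].
#' @return list of sorted integer gene vectors.
#' @export
init_population <- function(feature_count, config = ga_config()) {
  if (feature_count < config$chromosome_size) {
    stop("feature_count (", feature_count, ") < chromosome_size (",
         config$chromosome_size, ")")
  }
  withr::with_seed(config$seed, .init_population_rng(feature_count, config))
}

.init_population_rng <- function(feature_count, config) {
  lapply(seq_len(config$population_size),
         function(i) .random_chromosome(feature_count, config$chromosome_size))
}

#' Fitness of a chromosome
#'
#' Mean cross-validated AUC of the RBF-SVM restricted to the chromosome's
#' feature columns. Results are cached per gene-set, so an identical
#' chromosome is never re-evaluated.
#'
#' @param genes sorted integer vector of feature indices.
#' @param X numeric matrix (samples x features).
#' @param y 0/1 labels.
#' @param config a [ga_config()].
#' @param folds fold ids (defaults to a fresh stratified assignment from
#'   `config$seed`).
#' @param cache environment used as fitness cache (optional).
#' @return AUC in `[0, 1]`.
#' @export
evaluate_fitness <- function(genes, X, y, config = ga_config(), folds = NULL,
                             cache = NULL) {
  .validate_chromosome(genes, ncol(X), length(genes))
  if (is.null(folds)) folds <- make_cv_folds(y, config$cv_folds, config$seed)
  key <- paste(genes, collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  fit <- svm_cv_auc(X[, genes, drop = FALSE], y, folds,
                    cost = config$cost,
                    gamma = if (is.null(config$gamma)) 1 / length(genes)
                            else config$gamma)
  if (!is.null(cache)) {
    cache[[key]] <- fit
    cache$.n_evals <- (if (is.null(cache$.n_evals)) 0L else cache$.n_evals) + 1L
  }
  fit
}

#' Select the parent pool
#'
#' The top `ceiling(population_size * parent_fraction)` chromosomes by
#' fitness, ties broken by position in the population (insertion order).
#'
#' @param population list of gene vectors.
#' @param fitness numeric fitness per chromosome.
#' @param config a [ga_config()].
#' @return list of gene vectors (the parents, best first).
#' @export
select_parents <- function(population, fitness, config = ga_config()) {
  stopifnot(length(population) == length(fitness), !anyNA(fitness))
  n_par <- ceiling(config$population_size * config$parent_fraction)
  ord <- order(-fitness, seq_along(fitness))
  population[ord[seq_len(n_par)]]
}

# Two-point crossover on the sorted gene arrays: the segment between two
# random cut positions is taken from parent b, the rest from parent a;
# duplicate genes created by the swap are repaired by uniform resampling from
# features unused by the child, keeping cardinality exact.
.crossover_two_point <- function(a, b, feature_count) {
  size <- length(a)
  cuts <- sort(sample.int(size, 2L))
  child <- a
  child[cuts[1]:cuts[2]] <- b[cuts[1]:cuts[2]]
  child <- unique(child)
  deficit <- size - length(child)
  if (deficit > 0L) {
    pool <- setdiff(seq_len(feature_count), child)
    if (length(pool) < deficit) stop("cannot repair chromosome: feature space too small")
    child <- c(child, sample(pool, deficit))
  }
  sort(child)
}

#' Mutate a chromosome
#'
#' Applies `1 + floor(generation / mutation_escalation_period)` mutation
#' passes; in each pass every gene is independently replaced, with
#' probability `mutation_prob`, by a uniformly chosen unused feature.
#' Cardinality is preserved.
#'
#' @param genes sorted integer gene vector.
#' @param feature_count total number of features.
#' @param config a [ga_config()].
#' @param generation 0-based generation counter.
#' @return mutated sorted gene vector.
#' @export
mutate <- function(genes, feature_count, config = ga_config(), generation = 0L) {
  passes <- 1L + generation %/% config$mutation_escalation_period
  if (config$mutation_prob <= 0) return(genes)
  for (p in seq_len(passes)) {
    hit <- which(stats::runif(length(genes)) < config$mutation_prob)
    for (g in hit) {
      pool <- setdiff(seq_len(feature_count), genes)
      if (length(pool) == 0L) break
      genes[g] <- sample(pool, 1L)
    }
  }
  sort(genes)
}

#' Offspring competition for one parent pair
#'
#' Generates `crossover_repeats` candidate offspring (two-point crossover,
#' duplicate repair, mutation), evaluates them all, and returns the fittest.
#'
#' @param parent_a,parent_b sorted gene vectors.
#' @param X,y data and labels.
#' @param config a [ga_config()].
#' @param generation 0-based generation counter (mutation escalation).
#' @param folds fitness CV folds.
#' @param cache fitness cache environment.
#' @return list with `genes` and `fitness` of the winning offspring.
#' @export
crossover_offspring_competition <- function(parent_a, parent_b, X, y,
                                            config = ga_config(),
                                            generation = 0L, folds = NULL,
                                            cache = NULL) {
  feature_count <- ncol(X)
  cands <- lapply(seq_len(config$crossover_repeats), function(r) {
    child <- .crossover_two_point(parent_a, parent_b, feature_count)
    mutate(child, feature_count, config, generation)
  })
  fits <- vapply(cands, function(g) {
    evaluate_fitness(g, X, y, config, folds = folds, cache = cache)
  }, numeric(1))
  best <- which.max(fits)
  list(genes = cands[[best]], fitness = fits[best])
}

#' Run the offspring-competition genetic algorithm
#'
#' Evolves fixed-size feature subsets for `config$generations` generations
#' and returns the best-ever chromosome plus the per-generation history.
#' The whole run is driven by `config$seed` and is bit-reproducible.
#'
#' @param X numeric matrix (samples x features), width >= chromosome size.
#' @param y 0/1 labels.
#' @param config a [ga_config()].
#' @param verbose print per-generation progress.
#' @return object of class `ga_result`: `best` (list with `genes`,
#'   `fitness`), `history` (data.frame generation / best_fitness /
#'   mean_fitness), `best_per_generation` (list of gene vectors), `n_evals`
#'   (fitness evaluations actually run, after caching).
#' @export
evolve <- function(X, y, config = ga_config(), verbose = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) < config$chromosome_size) {
    stop("matrix width (", ncol(X), ") < chromosome_size (",
         config$chromosome_size, ")")
  }
  withr::with_seed(config$seed, {
    folds <- make_cv_folds(y, config$cv_folds, config$seed)
    cache <- new.env(parent = emptyenv())
    pop <- .init_population_rng(ncol(X), config)
    fitness <- vapply(pop, function(g) {
      evaluate_fitness(g, X, y, config, folds = folds, cache = cache)
    }, numeric(1))
    best_idx <- which.max(fitness)
    best <- list(genes = pop[[best_idx]], fitness = fitness[best_idx])
    history <- data.frame(generation = integer(0), best_fitness = numeric(0),
                          mean_fitness = numeric(0))
    best_per_gen <- vector("list", config$generations)

    for (gen in seq_len(config$generations) - 1L) {
      parents <- select_parents(pop, fitness, config)
      offspring <- list(); off_fit <- numeric(0)
      while (length(offspring) < config$population_size) {
        # one pairing round: shuffle parents, pair consecutively
        shuffled <- parents[sample.int(length(parents))]
        n_pairs <- length(shuffled) %/% 2L
        for (p in seq_len(n_pairs)) {
          if (length(offspring) >= config$population_size) break
          win <- crossover_offspring_competition(
            shuffled[[2L * p - 1L]], shuffled[[2L * p]], X, y, config,
            generation = gen, folds = folds, cache = cache)
          offspring[[length(offspring) + 1L]] <- win$genes
          off_fit <- c(off_fit, win$fitness)
        }
      }
      # elitism: best-ever individual replaces the worst offspring
      worst <- which.min(off_fit)
      offspring[[worst]] <- best$genes
      off_fit[worst] <- best$fitness
      pop <- offspring
      fitness <- off_fit
      gen_best <- which.max(fitness)
      if (fitness[gen_best] > best$fitness) {
        best <- list(genes = pop[[gen_best]], fitness = fitness[gen_best])
      }
      history <- rbind(history, data.frame(
        generation = gen, best_fitness = max(fitness),
        mean_fitness = mean(fitness)))
      best_per_gen[[gen + 1L]] <- pop[[gen_best]]
      if (verbose) {
        message(sprintf("generation %d: best %.4f mean %.4f (evals %d)",
                        gen, max(fitness), mean(fitness), cache$.n_evals))
      }
    }
    structure(list(best = best, history = history,
                   best_per_generation = best_per_gen,
                   n_evals = cache$.n_evals, config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result: ", length(x$best$genes), " features, fitness ",
      round(x$best$fitness, 4), " after ", nrow(x$history), " generations (",
      x$n_evals, " fitness evaluations)>\n", sep = "")
  invisible(x)
}
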