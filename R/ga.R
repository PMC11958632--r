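#' Genetic-algorithm search configuration
#'
#' Defaults follow the reference setup for the Cleveland-scale problem:
#' population 20, 50 generations (100 in longer runs), fitness-proportional
#' selection within a random subset of 5 individuals, single-point crossover
#' on every selected pair, bit-flip mutation, and one elite individual
#' carried forward so the best-fitness trace never decreases. The mutation
#' rate settings 1000/100/5 correspond to per-gene flip probabilities
#' 1/1000, 1/100 and 1/5; the default is 1/100.
#'
#' @param population_size Number of chromosomes, at least 2.
#' @param generations Stopping criterion: number of generations.
#' @param subset_size_for_selection Individuals sampled into each selection
#'   subset.
#' @param per_gene_mutation_prob Probability of flipping each bit.
#' @param elitism Number of best individuals copied unchanged into the next
#'   generation (0 disables).
#' @param crossover Apply single-point crossover to every selected pair.
#' @param seed Seed for all search randomness.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 20, generations = 50,
                      subset_size_for_selection = 5,
                      per_gene_mutation_prob = 1 / 100,
                      elitism = 1, crossover = TRUE, seed = 1L) {
  if (population_size < 2) abort("population_size must be at least 2")
  if (per_gene_mutation_prob < 0 || per_gene_mutation_prob > 1) {
    abort("per_gene_mutation_prob must be in [0, 1]")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      generations = as.integer(generations),
      subset_size_for_selection = as.integer(subset_size_for_selection),
      per_gene_mutation_prob = per_gene_mutation_prob,
      elitism = as.integer(elitism),
      crossover = isTRUE(crossover),
      seed = as.integer(seed)
    ),
    class = "ga_config"
  )
}

#' Initialize a population of subset masks
#'
#' Each chromosome's bits are drawn uniformly and repaired to non-empty
#' (one random bit forced on if all-zero), so every individual is a valid
#' feature subset.
#'
#' @param n_features Chromosome length.
#' @param population_size Number of chromosomes.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside [run_ga()]).
#' @return List of 0/1 integer vectors.
#' @export
init_population <- function(n_features, population_size, seed = NULL) {
  if (n_features < 1) abort("n_features must be positive")
  draw <- function() {
    replicate(population_size, repair_mask(
      sample(c(0L, 1L), n_features, replace = TRUE)
    ), simplify = FALSE)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Fitness-proportional parent selection from a random subset
#'
#' Draws `min(subset_size, population)` distinct individuals uniformly, then
#' samples one of them with probability proportional to fitness. If every
#' fitness in the subset is zero the choice is uniform, with a warning.
#'
#' @param population List of masks.
#' @param fitnesses Numeric vector of fitness values, one per individual.
#' @param subset_size Subset size (default 5).
#' @param seed Optional seed, see [init_population()].
#' @return One mask from `population`.
#' @export
select_parent <- function(population, fitnesses, subset_size = 5, seed = NULL) {
  if (length(population) == 0) abort("population is empty")
  if (length(fitnesses) != length(population)) {
    abort("one fitness per individual required")
  }
  draw <- function() {
    idx <- sample.int(length(population), min(subset_size, length(population)))
    w <- fitnesses[idx]
    if (all(w == 0)) {
      warn("all subset fitnesses are zero; selecting uniformly")
      w <- rep(1, length(idx))
    }
    population[[idx[sample.int(length(idx), 1, prob = w)]]]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Single-point crossover of two chromosomes
#'
#' A cut point is drawn uniformly in `1..len-1`; the children swap tails
#' after the cut and are repaired to non-empty.
#'
#' @param parent1,parent2 Equal-length 0/1 vectors, length at least 2.
#' @param seed Optional seed.
#' @param cut Fixed cut point (bits `1..cut` stay with their parent);
#'   drawn uniformly when `NULL`.
#' @return List of two child masks.
#' @export
crossover_single_point <- function(parent1, parent2, seed = NULL, cut = NULL) {
  len <- length(parent1)
  if (len != length(parent2)) abort("parents must have equal length")
  if (len < 2) abort("chromosomes must have at least 2 genes")
  run <- function() {
    pos <- if (is.null(cut)) sample.int(len - 1, 1) else cut
    c1 <- c(parent1[1:pos], parent2[(pos + 1):len])
    c2 <- c(parent2[1:pos], parent1[(pos + 1):len])
    list(repair_mask(c1), repair_mask(c2))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Bit-flip mutation
#'
#' Flips each gene independently with probability `per_gene_prob`, then
#' repairs the mask to non-empty.
#'
#' @param mask 0/1 vector.
#' @param per_gene_prob Flip probability in `[0, 1]`.
#' @param seed Optional seed.
#' @return Mutated mask.
#' @export
mutate_mask <- function(mask, per_gene_prob, seed = NULL) {
  if (per_gene_prob < 0 || per_gene_prob > 1) {
    abort("per_gene_prob must be in [0, 1]")
  }
  run <- function() {
    flip <- runif(length(mask)) < per_gene_prob
    repair_mask(as.integer(xor(mask == 1, flip)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Genetic-algorithm feature-subset search
#'
#' Evolves a population of subset masks for a fixed number of generations:
#' subset-based fitness-proportional selection, single-point crossover on
#' every pair, per-gene mutation, and elitism carrying the best individuals
#' forward unchanged. Fitness is the wrapper fitness `1/(1 + g)` with g the
#' wrapped random-forest error, see [wrapper_fitness()].
#'
#' @param data Data frame of predictors (a `target` column is ignored).
#' @param labels Binary 0/1 outcome vector.
#' @param config A [ga_config()].
#' @param fitness Optional memoised fitness closure from
#'   [fitness_function()]; built from `data`/`labels` when `NULL`.
#' @param num_trees Trees for the default wrapper objective.
#' @return An `optimization_result`: best mask, best fitness, per-generation
#'   best-fitness trace, evaluation count and seed.
#' @export
run_ga <- function(data, labels, config = ga_config(), fitness = NULL,
                   num_trees = 100) {
  x <- predictor_frame(data)
  feats <- names(x)
  if (is.null(fitness)) {
    fitness <- fitness_function(
      x, labels, num_trees = num_trees, seed = child_seed(config$seed, 0)
    )
  }
  evals <- 0L
  score <- function(mask) {
    evals <<- evals + 1L
    fitness(mask)
  }
  with_seed(config$seed, {
    pop <- init_population(length(feats), config$population_size)
    vals <- lapply(pop, score)
    fit <- vapply(vals, `[[`, numeric(1), "fitness")
    best_i <- which.max(fit)
    best <- list(mask = pop[[best_i]], val = vals[[best_i]])
    trace <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[head(ord, config$elitism)]
      nxt <- elite
      while (length(nxt) < config$population_size) {
        p1 <- select_parent(pop, fit, config$subset_size_for_selection)
        p2 <- select_parent(pop, fit, config$subset_size_for_selection)
        kids <- if (config$crossover && length(feats) >= 2) {
          crossover_single_point(p1, p2)
        } else {
          list(p1, p2)
        }
        kids <- lapply(kids, mutate_mask, per_gene_prob = config$per_gene_mutation_prob)
        nxt <- c(nxt, kids)
      }
      pop <- nxt[seq_len(config$population_size)]
      vals <- lapply(pop, score)
      fit <- vapply(vals, `[[`, numeric(1), "fitness")
      gen_best <- which.max(fit)
      if (fit[gen_best] > best$val$fitness) {
        best <- list(mask = pop[[gen_best]], val = vals[[gen_best]])
      }
      trace[gen] <- max(fit)
    }
    new_optimization_result(
      method = "ga",
      best_mask = best$mask,
      best_fitness = best$val$fitness,
      best_objective = best$val$objective,
      trace = trace,
      evaluations = evals,
      seed = config$seed,
      features = feats
    )
  })
}
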