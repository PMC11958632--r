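#' Ant-colony search configuration
#'
#' Defaults follow the reference setup: pheromone influence `alpha = 1`,
#' heuristic (visibility) influence `beta = 2`, evaporation `rho = 0.5`,
#' 5 ants, 100 iterations. Each feature is a node; an ant builds a subset of
#' `n_select` distinct features by repeated roulette-wheel draws. When
#' `n_select` is `NULL` it is drawn once per run uniformly between half the
#' feature count (rounded up) and one less than the full count.
#'
#' @param alpha Pheromone exponent.
#' @param beta Heuristic exponent.
#' @param evaporation Trail decay factor `rho` in (0, 1].
#' @param n_ants Ants per iteration.
#' @param iterations Number of colony iterations.
#' @param n_select Features per ant subset, or `NULL` to draw per run.
#' @param deposit `"all"` deposits pheromone from every ant,
#'   `"iteration_best"` only from the iteration's best ant.
#' @param pheromone_floor Lower bound keeping every trail positive.
#' @param heuristic_floor Lower bound on the normalized heuristic so no
#'   feature has identically zero selection probability.
#' @param seed Seed for all search randomness.
#' @return An `aco_config` list.
#' @export
aco_config <- function(alpha = 1, beta = 2, evaporation = 0.5, n_ants = 5,
                       iterations = 100, n_select = NULL,
                       deposit = c("all", "iteration_best"),
                       pheromone_floor = 1e-6, heuristic_floor = 0.01,
                       seed = 1L) {
  if (alpha < 0 || beta < 0) abort("alpha and beta must be nonnegative")
  if (evaporation <= 0 || evaporation > 1) abort("evaporation must be in (0, 1]")
  structure(
    list(
      alpha = alpha, beta = beta, evaporation = evaporation,
      n_ants = as.integer(n_ants), iterations = as.integer(iterations),
      n_select = if (is.null(n_select)) NULL else as.integer(n_select),
      deposit = match.arg(deposit),
      pheromone_floor = pheromone_floor,
      heuristic_floor = heuristic_floor,
      seed = as.integer(seed)
    ),
    class = "aco_config"
  )
}

#' Ant selection probabilities over candidate features
#'
#' \eqn{P(i) = \tau(i)^\alpha \eta(i)^\beta / \sum_l \tau(l)^\alpha
#' \eta(l)^\beta} over the candidate set. If every numerator is zero the
#' distribution falls back to uniform with a warning.
#'
#' @param tau Positive pheromone trail per candidate.
#' @param eta Nonnegative heuristic desirability per candidate.
#' @param alpha,beta Exponents.
#' @return Probability vector summing to 1 over the candidates.
#' @export
#' @examples
#' selection_probabilities(c(1, 1), c(2, 1), alpha = 1, beta = 2)
selection_probabilities <- function(tau, eta, alpha = 1, beta = 2) {
  if (length(tau) == 0) abort("candidate set is empty")
  if (length(eta) != length(tau)) abort("tau and eta must share a length")
  num <- tau^alpha * eta^beta
  if (all(num == 0)) {
    warn("all selection numerators are zero; using uniform probabilities")
    num <- rep(1, length(tau))
  }
  num / sum(num)
}

#' Roulette-wheel draw
#'
#' Samples one index with probability proportional to the given weights.
#'
#' @param probs Nonnegative probability vector.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return One index in `1..length(probs)`.
#' @export
roulette_select <- function(probs, seed = NULL) {
  if (any(probs < 0)) abort("probabilities must be nonnegative")
  run <- function() sample.int(length(probs), 1, prob = probs)
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Construct one ant's feature subset
#'
#' Chooses `n_select` distinct features by repeated roulette draws without
#' replacement, renormalizing the selection probabilities over the remaining
#' candidates after every draw.
#'
#' @param tau,eta Full-length trail and heuristic vectors.
#' @param n_select Number of features to pick.
#' @param alpha,beta Exponents.
#' @param seed Optional seed.
#' @return 0/1 mask with exactly `n_select` bits set.
#' @export
construct_ant_subset <- function(tau, eta, n_select, alpha = 1, beta = 2,
                                 seed = NULL) {
  d <- length(tau)
  if (n_select < 1 || n_select > d) abort(sprintf("n_select must be in 1..%d", d))
  run <- function() {
    mask <- integer(d)
    candidates <- seq_len(d)
    for (step in seq_len(n_select)) {
      probs <- selection_probabilities(
        tau[candidates], eta[candidates], alpha, beta
      )
      pick <- candidates[roulette_select(probs)]
      mask[pick] <- 1L
      candidates <- candidates[candidates != pick]
    }
    mask
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Global pheromone update
#'
#' \eqn{\tau(i) \leftarrow \rho\,\tau(i) + \sum_k \Delta\tau_k(i)} where ant
#' `k` deposits its fitness on every feature in its subset and nothing
#' elsewhere; a floor keeps every trail positive.
#'
#' @param tau Current trail vector.
#' @param ant_masks List of 0/1 masks, one per depositing ant.
#' @param ant_fitnesses Fitness per depositing ant (nonnegative).
#' @param evaporation Decay factor `rho`.
#' @param floor Minimum trail value.
#' @return Updated trail vector.
#' @export
#' @examples
#' update_pheromone(1, list(1L), 0.3, evaporation = 0.5)
update_pheromone <- function(tau, ant_masks, ant_fitnesses, evaporation = 0.5,
                             floor = 1e-6) {
  if (any(ant_fitnesses < 0)) abort("fitnesses must be nonnegative")
  deposits <- numeric(length(tau))
  for (k in seq_along(ant_masks)) {
    deposits <- deposits + ant_fitnesses[k] * (ant_masks[[k]] == 1)
  }
  pmax(evaporation * tau + deposits, floor)
}

#' Ant-colony feature-subset search
#'
#' Features are independent nodes. Per iteration each ant builds an
#' `n_select`-feature subset by roulette draws driven by pheromone and a
#' static heuristic, every subset is scored with the shared wrapper fitness,
#' and the trail evaporates and receives fitness-proportional deposits. The
#' heuristic is the min-max-normalized ANOVA F score of each feature
#' (floored so every feature stays reachable). The trace records best-so-far
#' fitness.
#'
#' @inheritParams run_ga
#' @param config An [aco_config()].
#' @param heuristic Optional per-feature desirability; computed from
#'   [anova_f_scores()] when `NULL`.
#' @return An `optimization_result` with the final trail in `$pheromone`.
#' @export
run_aco <- function(data, labels, config = aco_config(), fitness = NULL,
                    heuristic = NULL, num_trees = 100) {
  x <- predictor_frame(data)
  feats <- names(x)
  d <- length(feats)
  if (is.null(fitness)) {
    fitness <- fitness_function(
      x, labels, num_trees = num_trees, seed = child_seed(config$seed, 0)
    )
  }
  if (is.null(heuristic)) {
    f <- anova_f_scores(x, labels)$score
    f[!is.finite(f)] <- max(f[is.finite(f)], 1)
    rng <- range(f)
    heuristic <- if (diff(rng) == 0) rep(1, d) else (f - rng[1]) / diff(rng)
  }
  eta <- pmax(heuristic, config$heuristic_floor)
  evals <- 0L
  score <- function(mask) {
    evals <<- evals + 1L
    fitness(mask)
  }
  with_seed(config$seed, {
    n_select <- config$n_select %||%
      sample(seq(ceiling(d / 2), d - 1), 1)
    tau <- rep(1, d)
    best <- NULL
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      masks <- replicate(
        config$n_ants,
        construct_ant_subset(tau, eta, n_select, config$alpha, config$beta),
        simplify = FALSE
      )
      vals <- lapply(masks, score)
      fit <- vapply(vals, `[[`, numeric(1), "fitness")
      it_best <- which.max(fit)
      if (is.null(best) || fit[it_best] > best$val$fitness) {
        best <- list(mask = masks[[it_best]], val = vals[[it_best]])
      }
      if (config$deposit == "all") {
        tau <- update_pheromone(
          tau, masks, fit, config$evaporation, config$pheromone_floor
        )
      } else {
        tau <- update_pheromone(
          tau, masks[it_best], fit[it_best], config$evaporation,
          config$pheromone_floor
        )
      }
      trace[it] <- best$val$fitness
    }
    out <- new_optimization_result(
      method = "aco",
      best_mask = best$mask,
      best_fitness = best$val$fitness,
      best_objective = best$val$objective,
      trace = trace,
      evaluations = evals,
      seed = config$seed,
      features = feats
    )
    out$pheromone <- setNames(tau, feats)
    out$n_select <- n_select
    out
  })
}
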