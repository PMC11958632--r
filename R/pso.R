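#' Particle-swarm search configuration
#'
#' Defaults follow the reference setup: inertia weight `w = 0.9`, cognitive
#' and social factors `c1 = c2 = 0.5`, a k-nearest-neighbour topology of
#' `k = 30` under the Minkowski `p = 2` norm, and 1000 iterations. Swarm
#' size defaults to 40 so the 30-neighbour topology is meaningful.
#' Velocities (and positions) are clamped to plus or minus
#' `velocity_clamp = 6`, the range over which the sigmoid transfer is
#' effectively saturated, so no bit ever freezes completely.
#'
#' @param inertia,cognitive,social Update coefficients `w`, `c1`, `c2`.
#' @param neighbors Neighbourhood size `k` (clamped to the swarm size).
#' @param minkowski_p Norm order for the neighbour topology.
#' @param iterations Number of swarm updates.
#' @param swarm_size Number of particles.
#' @param velocity_clamp Symmetric bound on each velocity component.
#' @param seed Seed for all search randomness.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(inertia = 0.9, cognitive = 0.5, social = 0.5,
                         neighbors = 30, minkowski_p = 2, iterations = 1000,
                         swarm_size = 40, velocity_clamp = 6, seed = 1L) {
  if (inertia < 0 || cognitive < 0 || social < 0) {
    abort("inertia, cognitive and social coefficients must be nonnegative")
  }
  if (iterations < 1) abort("iterations must be at least 1")
  structure(
    list(
      inertia = inertia, cognitive = cognitive, social = social,
      neighbors = as.integer(neighbors), minkowski_p = minkowski_p,
      iterations = as.integer(iterations), swarm_size = as.integer(swarm_size),
      velocity_clamp = velocity_clamp, seed = as.integer(seed)
    ),
    class = "swarm_config"
  )
}

#' Particle velocity update
#'
#' Componentwise update
#' \eqn{v' = w v + c_1 r_1 (p - x) + c_2 r_2 (p_n - x)} with independent
#' uniform(0,1) draws `r1`, `r2` per component per term, where `p` is the
#' particle's personal-best position and `p_n` its neighbourhood-best
#' position. The result is clamped to plus or minus `velocity_clamp`.
#'
#' @param velocity,position Current velocity and position vectors.
#' @param pbest,nbest Personal-best and neighbourhood-best positions.
#' @param config A [swarm_config()].
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param rand_fn Override for the stochastic draws: a function `n ->
#'   numeric(n)`. Supplying `function(n) rep(1, n)` makes the update
#'   deterministic, which is how the arithmetic is unit-checked.
#' @return New velocity vector.
#' @export
#' @examples
#' cfg <- swarm_config()
#' update_velocity(0.1, 0, 1, 1, cfg, rand_fn = function(n) rep(1, n))
update_velocity <- function(velocity, position, pbest, nbest,
                            config = swarm_config(), seed = NULL,
                            rand_fn = NULL) {
  len <- length(velocity)
  if (length(position) != len || length(pbest) != len || length(nbest) != len) {
    abort("velocity, position and best vectors must share a length")
  }
  run <- function() {
    r <- if (is.null(rand_fn)) runif else rand_fn
    v <- config$inertia * velocity +
      config$cognitive * r(len) * (pbest - position) +
      config$social * r(len) * (nbest - position)
    pmin(pmax(v, -config$velocity_clamp), config$velocity_clamp)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Sigmoid transfer from a real component to a bit
#'
#' The binary-swarm transfer rule: each real component maps to a bit that is
#' 1 with probability \eqn{S(v) = 1/(1 + e^{-v})}.
#'
#' @param component Real vector (position or velocity components).
#' @param seed Optional seed.
#' @return 0/1 integer vector of the same length.
#' @export
binarize_position <- function(component, seed = NULL) {
  if (any(!is.finite(component))) abort("components must be finite")
  run <- function() as.integer(runif(length(component)) < plogis(component))
  if (is.null(seed)) run() else with_seed(seed, run())
}

minkowski_dist <- function(positions, p) {
  n <- nrow(positions)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- (rowSums(abs(sweep(positions, 2, positions[i, ], "-"))^p))^(1 / p)
    d[i, ] <- di
  }
  d
}

#' Neighbourhood best under a k-nearest-neighbour topology
#'
#' Each particle's neighbourhood is its `k` nearest particles (itself
#' included) under the Minkowski `p`-norm on positions; its neighbourhood
#' best is the member with the highest personal-best fitness.
#'
#' @param positions Matrix of particle positions (particles in rows).
#' @param pbest_fitness Personal-best fitness per particle.
#' @param k Neighbourhood size; values above the swarm size are clamped
#'   with a warning.
#' @param p Minkowski norm order.
#' @return Integer vector: for each particle, the index of its
#'   neighbourhood-best particle.
#' @export
neighborhood_best <- function(positions, pbest_fitness, k, p = 2) {
  n <- nrow(positions)
  if (k < 1) abort("k must be at least 1")
  if (k > n) {
    warn(sprintf("k = %d exceeds swarm size %d; clamped", k, n))
    k <- n
  }
  d <- minkowski_dist(positions, p)
  vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    nb[which.max(pbest_fitness[nb])]
  }, integer(1))
}

#' Particle-swarm feature-subset search
#'
#' Binary particle swarm over subset masks: continuous positions and
#' velocities per feature dimension, the velocity update of
#' [update_velocity()], position update `x <- x + v` (clamped like the
#' velocity), mask sampling through the sigmoid transfer of
#' [binarize_position()], and personal/neighbourhood bests under the kNN
#' topology of [neighborhood_best()]. The trace records the best-so-far
#' fitness per iteration and is therefore non-decreasing.
#'
#' @inheritParams run_ga
#' @param config A [swarm_config()].
#' @return An `optimization_result`.
#' @export
run_pso <- function(data, labels, config = swarm_config(), fitness = NULL,
                    num_trees = 100) {
  x <- predictor_frame(data)
  feats <- names(x)
  d <- length(feats)
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
    ns <- config$swarm_size
    pos <- matrix(runif(ns * d, -1, 1), ns, d)
    vel <- matrix(runif(ns * d, -1, 1), ns, d)
    pbest_pos <- pos
    pbest_mask <- vector("list", ns)
    pbest_fit <- numeric(ns)
    pbest_obj <- numeric(ns)
    for (i in seq_len(ns)) {
      m <- repair_mask(binarize_position(pos[i, ]))
      v <- score(m)
      pbest_mask[[i]] <- m
      pbest_fit[i] <- v$fitness
      pbest_obj[i] <- v$objective
    }
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      nb <- neighborhood_best(pos, pbest_fit, config$neighbors, config$minkowski_p)
      for (i in seq_len(ns)) {
        vel[i, ] <- update_velocity(
          vel[i, ], pos[i, ], pbest_pos[i, ], pbest_pos[nb[i], ], config
        )
        pos[i, ] <- pmin(pmax(pos[i, ] + vel[i, ], -config$velocity_clamp),
                         config$velocity_clamp)
        m <- repair_mask(binarize_position(pos[i, ]))
        v <- score(m)
        if (v$fitness > pbest_fit[i]) {
          pbest_fit[i] <- v$fitness
          pbest_obj[i] <- v$objective
          pbest_mask[[i]] <- m
          pbest_pos[i, ] <- pos[i, ]
        }
      }
      trace[it] <- max(pbest_fit)
    }
    best_i <- which.max(pbest_fit)
    new_optimization_result(
      method = "pso",
      best_mask = pbest_mask[[best_i]],
      best_fitness = pbest_fit[best_i],
      best_objective = pbest_obj[best_i],
      trace = trace,
      evaluations = evals,
      seed = config$seed,
      features = feats
    )
  })
}
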