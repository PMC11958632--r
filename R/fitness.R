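#' Wrapper fitness of a feature subset
#'
#' The quantity all three metaheuristics maximize: \eqn{f = 1/(1 + g)} where
#' \eqn{g \ge 0} is a wrapped model's error on the masked feature set. The
#' default objective is the out-of-bag root-mean-squared error of a
#' random-forest regressor predicting the 0/1 label, so \eqn{f \in (0, 1]}
#' and \eqn{f = 1} exactly when the error is zero.
#'
#' @param data Data frame of predictors (a `target` column is ignored).
#' @param labels Binary 0/1 outcome vector.
#' @param mask 0/1 inclusion vector over the predictors; must select at
#'   least one feature.
#' @param objective Either `"rf_rmse"` (default) or a function
#'   `(data_masked, labels) -> g` returning a nonnegative error.
#' @param num_trees Trees in the wrapped forest.
#' @param seed Seed for the wrapped model; with a fixed seed the fitness of
#'   a mask is deterministic.
#' @return List with elements `fitness` (in (0, 1]) and `objective` (the
#'   error g it was derived from).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 120, seed = 7))
#' mask <- rep(1L, 13)
#' wrapper_fitness(cohort$data, cohort$labels, mask, num_trees = 50)
wrapper_fitness <- function(data, labels, mask, objective = "rf_rmse",
                            num_trees = 100, seed = 1L) {
  x <- predictor_frame(data)
  check_labels(labels, nrow(x))
  mask <- check_mask(mask, ncol(x))
  g <- if (is.function(objective)) {
    objective(x[, mask == 1, drop = FALSE], labels)
  } else {
    rf_rmse(x[, mask == 1, drop = FALSE], labels, num_trees, seed)
  }
  if (is.na(g) || g < 0) abort("objective must be a nonnegative error")
  list(fitness = 1 / (1 + g), objective = g)
}

rf_rmse <- function(x, labels, num_trees, seed) {
  dat <- cbind(x, .y = as.numeric(labels))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = num_trees, num.threads = 1, seed = as.integer(seed),
    verbose = FALSE
  )
  sqrt(fit$prediction.error)
}

#' Build a memoised fitness function over subset masks
#'
#' Returns a closure `f(mask) -> list(fitness, objective)` bound to one
#' dataset and one objective seed. Because the default objective is a
#' deterministic function of the mask given its seed, results are cached per
#' mask: repeated visits to the same subset (frequent late in any search,
#' and across repeated runs) cost nothing. All three optimizers accept such
#' a closure via their `fitness` argument.
#'
#' @inheritParams wrapper_fitness
#' @return A memoising function of one mask argument.
#' @export
fitness_function <- function(data, labels, objective = "rf_rmse",
                             num_trees = 100, seed = 1L) {
  x <- predictor_frame(data)
  check_labels(labels, nrow(x))
  cache <- new.env(parent = emptyenv())
  force(objective); force(num_trees); force(seed)
  function(mask) {
    mask <- check_mask(mask, ncol(x))
    key <- paste(mask, collapse = "")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    val <- wrapper_fitness(
      x, labels, mask,
      objective = objective, num_trees = num_trees, seed = seed
    )
    assign(key, val, envir = cache)
    val
  }
}
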