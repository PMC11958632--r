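# Run code under a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# Derive a 31-bit child seed from a base seed and a stream index.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629 + 1
}

check_labels <- function(labels, n) {
  if (length(labels) != n) {
    abort(sprintf("labels length %d does not match %d rows", length(labels), n))
  }
  if (any(is.na(labels)) || !all(labels %in% c(0, 1))) {
    abort("labels must be 0/1 with no missing values")
  }
  invisible(labels)
}

check_mask <- function(mask, n_features = NULL) {
  if (!is.null(n_features) && length(mask) != n_features) {
    abort(sprintf(
      "mask length %d does not match %d features", length(mask), n_features
    ))
  }
  if (any(is.na(mask)) || !all(mask %in% c(0, 1))) {
    abort("subset mask must be a 0/1 vector")
  }
  if (sum(mask) == 0) abort("subset mask is empty: at least one feature must be selected")
  invisible(as.integer(mask))
}

# Force one uniformly chosen bit on when a mask has gone all-zero.
repair_mask <- function(mask) {
  if (sum(mask) == 0) mask[sample.int(length(mask), 1)] <- 1L
  as.integer(mask)
}

new_optimization_result <- function(method, best_mask, best_fitness,
                                    best_objective, trace, evaluations,
                                    seed, features) {
  names(best_mask) <- features
  structure(
    list(
      method = method,
      best_mask = as.integer(best_mask),
      best_fitness = best_fitness,
      best_objective = best_objective,
      trace = as.numeric(trace),
      evaluations = as.integer(evaluations),
      seed = as.integer(seed),
      features = features
    ),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result: %s>\n  %d/%d features selected, fitness %.4f (objective %.4f)\n  %d iterations, %d fitness evaluations, seed %d\n",
    x$method, sum(x$best_mask), length(x$best_mask), x$best_fitness,
    x$best_objective, length(x$trace), x$evaluations, x$seed
  ))
  cat("  selected:", paste(x$features[x$best_mask == 1], collapse = ", "), "\n")
  invisible(x)
}
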