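# Shared fixtures, built in code.

toy_cleveland_lines <- function() {
  c(
    "63,1,1,145,233,1,2,150,0,2.3,3,0,6,0",
    "67,1,4,160,286,0,2,108,1,1.5,2,3,3,2"
  )
}

# Deterministic, cheap wrapper objective for search-logic tests: RMSE of an
# ordinary least-squares probe on the masked features.
lm_objective <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, as.matrix(x)), y)
  sqrt(mean(fit$residuals^2))
}

# Small cohort + memoised cheap fitness shared across search-logic tests.
tiny_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) {
      co <<- generate_cohort(cohort_config(n_patients = 150, seed = 2024))
    }
    co
  }
})

tiny_fitness <- local({
  fn <- NULL
  function() {
    if (is.null(fn)) {
      co <- tiny_cohort()
      fn <<- fitness_function(co$data, co$labels, objective = lm_objective)
    }
    fn
  }
})

# Independent brute-force filter-score oracles (re-derived from the score
# definitions, sharing no code with the implementation).
oracle_chi_square <- function(x, y) {
  classes <- sort(unique(y))
  total <- sum(x)
  stat <- 0
  for (cl in classes) {
    obs <- sum(x[y == cl])
    expd <- total * sum(y == cl) / length(y)
    stat <- stat + (obs - expd)^2 / expd
  }
  stat
}

oracle_f_stat <- function(x, y) {
  unname(summary(stats::aov(x ~ factor(y)))[[1]]$`F value`[1])
}

oracle_discrete_mi <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (xv in unique(x)) {
    for (yv in unique(y)) {
      pxy <- mean(x == xv & y == yv)
      if (pxy > 0) {
        mi <- mi + pxy * log(pxy / (mean(x == xv) * mean(y == yv)))
      }
    }
  }
  mi
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

make_scores <- function(features, method, values) {
  tibble::tibble(feature = features, method = method, score = values)
}

reference_score_columns <- function() {
  ref <- cleveland_reference_scores()
  list(
    ref = ref,
    chi = make_scores(ref$feature, "chi_square", ref$chi_square),
    mi = make_scores(ref$feature, "mutual_information", ref$mutual_information),
    f = make_scores(ref$feature, "f_statistic", ref$f_statistic)
  )
}
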