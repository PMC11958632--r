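test_that("confusion counts tally the 2x2 outcomes", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cc), c(tp = 1, fp = 1, fn = 1, tn = 1))
  same <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(same$fp + same$fn, 0)
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0 or 1")
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "share a length")
})

test_that("the hand-worked metric example is reproduced", {
  m <- classification_metrics(tibble::tibble(tp = 50, fp = 10, fn = 5, tn = 35))
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$specificity, 35 / 45)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f_score, 2 * (50 / 60) * (50 / 55) / (50 / 60 + 50 / 55))
  expect_equal(m$classification_error_percent, 15)

  perfect <- classification_metrics(tibble::tibble(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(all(unlist(perfect[1:5]) == 1))
  expect_equal(perfect$classification_error_percent, 0)

  # an accuracy of 0.8525 pairs with a 14.75% error rate
  acc <- classification_metrics(tibble::tibble(tp = 5213, fp = 0, fn = 1475, tn = 3312))
  expect_equal(acc$accuracy, 0.8525)
  expect_equal(acc$classification_error_percent, 14.75)
})

test_that("metric identities hold against outcome counting on random confusion tables", {
  set.seed(500)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    p <- rbinom(n, 1, runif(1, 0.2, 0.8))
    cc <- confusion_counts(y, p)
    # brute-force outcome counting
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (j in seq_len(n)) {
      if (y[j] == 1 && p[j] == 1) tp <- tp + 1
      if (y[j] == 0 && p[j] == 1) fp <- fp + 1
      if (y[j] == 1 && p[j] == 0) fn <- fn + 1
      if (y[j] == 0 && p[j] == 0) tn <- tn + 1
    }
    expect_equal(unlist(cc), c(tp = tp, fp = fp, fn = fn, tn = tn))
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, n)
    m <- suppressWarnings(classification_metrics(cc))
    expect_equal(m$accuracy * 100 + m$classification_error_percent, 100)
    expect_equal(m$accuracy, (tp + tn) / n)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    if (m$precision + m$recall > 0) {
      expect_equal(
        m$f_score, 2 * m$precision * m$recall / (m$precision + m$recall)
      )
    }
  }
})

test_that("rank-based AUC matches the exhaustive pairwise oracle", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(auc_rank(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # ties likely
    expect_equal(auc_rank(s, y), oracle_auc(s, y))
  }
  expect_error(auc_rank(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  set.seed(7)
  y <- rbinom(100, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- rnorm(100) + y
  expect_equal(
    auc_rank(s, y),
    as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  )
})

test_that("stratified folds partition the cohort and keep class balance", {
  co <- tiny_cohort()
  rep1 <- evaluate_subset(co$data, co$labels, classifier = "DT",
                          protocol = eval_protocol(folds = 5, seed = 3))
  expect_equal(rep1$tp + rep1$fp + rep1$fn + rep1$tn, nrow(co$data))
  rep2 <- evaluate_subset(co$data, co$labels, classifier = "DT",
                          protocol = eval_protocol(folds = 5, seed = 3))
  expect_equal(rep1, rep2)
})

test_that("every registered classifier evaluates a separable cohort well", {
  set.seed(90)
  n <- 160
  y <- rep(c(0, 1), each = n / 2)
  df <- data.frame(
    a = rnorm(n, mean = 5 * y), b = rnorm(n, mean = -4 * y), c = rnorm(n)
  )
  for (cl in classifier_registry()) {
    rep <- evaluate_subset(df, y, classifier = cl,
                           protocol = eval_protocol(folds = 3, seed = 5),
                           seed = 11)
    expect_gte(rep$accuracy, 0.85)
    expect_gte(rep$auc, 0.9)
  }
  rf <- evaluate_subset(df, y, classifier = "RF",
                        protocol = eval_protocol(folds = 3, seed = 5),
                        seed = 11)
  expect_gte(rf$accuracy, 0.95)
  expect_error(
    evaluate_subset(df, y, classifier = "MLP"),
    "registered"
  )
  expect_error(
    evaluate_subset(df, y, mask = rep(0L, 3), classifier = "RF"), "empty"
  )
})

test_that("the comparison runner produces one row per method and classifier", {
  co <- tiny_cohort()
  comp <- compare_methods(
    co$data, co$labels,
    methods = c("all_features", "filter"),
    classifiers = c("LR", "DT", "NB"),
    filter_k = 5,
    protocol = eval_protocol(folds = 3, seed = 2),
    seed = 8
  )
  expect_equal(nrow(comp), 6)
  expect_setequal(unique(comp$method), c("all_features", "filter"))
  expect_true(all(comp$n_selected[comp$method == "filter"] == 5))
  expect_true(all(comp$n_selected[comp$method == "all_features"] == 13))
  expect_true(all(comp$accuracy >= 0 & comp$accuracy <= 1))
  # selected feature lists are recorded
  expect_true(all(nzchar(comp$selected)))

  comp2 <- compare_methods(
    co$data, co$labels,
    methods = c("all_features", "filter"),
    classifiers = c("LR", "DT", "NB"),
    filter_k = 5,
    protocol = eval_protocol(folds = 3, seed = 2),
    seed = 8
  )
  expect_equal(comp, comp2)
})
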