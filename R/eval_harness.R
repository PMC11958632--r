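#' Confusion counts for binary predictions
#'
#' Standard 2x2 tally with class 1 (disease) as positive.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return Tibble with one row: `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("vectors must share a length")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    abort("entries must be 0 or 1")
  }
  tibble(
    tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == 0),
    tn = sum(y_true == 0 & y_pred == 0)
  )
}

safe_ratio <- function(num, den, name) {
  if (den == 0) {
    warn(sprintf("%s undefined (zero denominator); reported as 0", name))
    return(0)
  }
  num / den
}

#' Confusion-derived classification metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' accuracy `(TP+TN)/total`, F-score (harmonic mean of precision and
#' recall), and the classification error rate `100 - 100 * accuracy` in
#' percent. Ratios with a zero denominator are reported as 0 with a warning.
#'
#' @param counts One-row tibble (or named list) with `tp`, `fp`, `fn`, `tn`.
#' @return One-row tibble with columns `precision`, `recall`,
#'   `specificity`, `accuracy`, `f_score`, `classification_error_percent`.
#' @export
#' @examples
#' classification_metrics(tibble::tibble(tp = 50, fp = 10, fn = 5, tn = 35))
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total <= 0) abort("confusion counts are empty")
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  specificity <- safe_ratio(tn, tn + fp, "specificity")
  accuracy <- (tp + tn) / total
  f_score <- if (precision + recall == 0) {
    warn("f_score undefined (zero precision and recall); reported as 0")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble(
    precision = precision, recall = recall, specificity = specificity,
    accuracy = accuracy, f_score = f_score,
    classification_error_percent = 100 - 100 * accuracy
  )
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen positive case receives a higher
#' score than a randomly chosen negative case, with ties counted half; the
#' Mann-Whitney form of the area under the ROC curve.
#'
#' @param scores Real-valued per-sample scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_rank(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
auc_rank <- function(scores, labels) {
  check_labels(labels, length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluation protocol
#'
#' Stratified k-fold cross-validation (default 5 folds) or a stratified
#' holdout split. Metrics are aggregated by pooling confusion counts (and
#' scores, for AUC) over the evaluated samples rather than averaging
#' per-fold metrics, so no fold can contribute an undefined ratio.
#'
#' @param scheme `"stratified_kfold"` or `"holdout"`.
#' @param folds Number of folds (k-fold scheme).
#' @param test_fraction Test proportion (holdout scheme), in (0, 1).
#' @param seed Seed for fold assignment / the split.
#' @return An `eval_protocol` list.
#' @export
eval_protocol <- function(scheme = c("stratified_kfold", "holdout"),
                          folds = 5, test_fraction = 0.25, seed = 42L) {
  scheme <- match.arg(scheme)
  if (scheme == "stratified_kfold" && folds < 2) abort("folds must be >= 2")
  if (scheme == "holdout" && (test_fraction <= 0 || test_fraction >= 1)) {
    abort("test_fraction must be in (0, 1)")
  }
  structure(
    list(
      scheme = scheme, folds = as.integer(folds),
      test_fraction = test_fraction, seed = as.integer(seed)
    ),
    class = "eval_protocol"
  )
}

# Stratified fold ids: within each class, shuffled samples are dealt
# round-robin across folds.
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    id <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
}

#' Names of the registered classifiers
#'
#' The adapter registry behind [evaluate_subset()]: logistic regression
#' (LR), k-nearest neighbours (KNN), support vector machine (SVM), naive
#' Bayes (NB), random forest (RF), random forest with grid search (RFGS),
#' gradient boosting (XGB), decision tree (DT), and a single-hidden-layer
#' neural network (NN). Each delegates to an established implementation.
#'
#' @return Character vector of registry names.
#' @export
classifier_registry <- function() {
  c("LR", "KNN", "SVM", "NB", "RF", "RFGS", "XGB", "DT", "NN")
}

scale_by_train <- function(train, test) {
  mu <- vapply(train, mean, numeric(1))
  sg <- vapply(train, sd, numeric(1))
  sg[sg == 0 | is.na(sg)] <- 1
  list(
    train = sweep(sweep(as.matrix(train), 2, mu), 2, sg, "/"),
    test = sweep(sweep(as.matrix(test), 2, mu), 2, sg, "/")
  )
}

# Each adapter fits on (train_x, train_y) and returns, for test_x, a score
# in [0, 1] for class 1; predictions threshold the score at 0.5.
fit_predict_score <- function(name, train_x, train_y, test_x, hyper, seed) {
  yf <- factor(train_y, levels = c(0, 1))
  with_seed(seed, switch(
    name,
    LR = {
      dat <- cbind(train_x, .y = train_y)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
      as.numeric(suppressWarnings(predict(fit, test_x, type = "response")))
    },
    KNN = {
      s <- scale_by_train(train_x, test_x)
      k <- hyper$k %||% 5
      pr <- class::knn(s$train, s$test, cl = yf, k = k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    SVM = {
      fit <- e1071::svm(
        x = as.matrix(train_x), y = yf, kernel = hyper$kernel %||% "radial",
        cost = hyper$cost %||% 1, probability = TRUE, scale = TRUE
      )
      pr <- predict(fit, as.matrix(test_x), probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    NB = {
      fit <- e1071::naiveBayes(x = train_x, y = yf)
      predict(fit, test_x, type = "raw")[, "1"]
    },
    RF = {
      fit <- randomForest::randomForest(
        x = train_x, y = yf, ntree = hyper$ntree %||% 200
      )
      predict(fit, test_x, type = "prob")[, "1"]
    },
    RFGS = rfgs_score(train_x, yf, test_x, hyper),
    XGB = {
      fit <- xgboost::xgboost(
        as.matrix(train_x), factor(train_y, levels = c(0, 1)),
        nrounds = hyper$nrounds %||% 50,
        max_depth = hyper$max_depth %||% 3,
        learning_rate = hyper$eta %||% 0.3,
        nthreads = 1, verbosity = 0
      )
      # response = probability of the second factor level ("1")
      as.numeric(predict(fit, as.matrix(test_x), type = "response"))
    },
    DT = {
      dat <- cbind(train_x, .y = yf)
      fit <- rpart::rpart(.y ~ ., data = dat, method = "class")
      predict(fit, test_x, type = "prob")[, "1"]
    },
    NN = {
      s <- scale_by_train(train_x, test_x)
      fit <- nnet::nnet(
        x = s$train, y = train_y, size = hyper$size %||% 8,
        decay = hyper$decay %||% 0.01, maxit = hyper$maxit %||% 200,
        trace = FALSE, entropy = TRUE
      )
      as.numeric(predict(fit, s$test))
    },
    abort(sprintf(
      "unknown classifier '%s'; registered: %s",
      name, paste(classifier_registry(), collapse = ", ")
    ))
  ))
}

# Grid-searched random forest: trees x max depth x min leaf, chosen by
# internal 3-fold CV accuracy on the training split, then refit on all of it.
rfgs_score <- function(train_x, yf, test_x, hyper) {
  grid <- expand.grid(
    num.trees = hyper$trees %||% c(100, 200, 500),
    max.depth = hyper$max_depth %||% c(3, 5, 0),
    min.node.size = hyper$min_leaf %||% c(1, 5)
  )
  y <- as.integer(as.character(yf))
  inner <- stratified_folds(y, 3, seed = 17L)
  dat <- cbind(train_x, .y = yf)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0
    for (f in 1:3) {
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dat[inner != f, ],
        num.trees = grid$num.trees[g], max.depth = grid$max.depth[g],
        min.node.size = grid$min.node.size[g],
        num.threads = 1, seed = 17L, verbose = FALSE
      )
      pr <- predict(fit, dat[inner == f, ])$predictions
      correct <- correct + sum(pr == yf[inner == f])
    }
    correct / length(y)
  }, numeric(1))
  bst <- grid[which.max(acc), ]
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = bst$num.trees, max.depth = bst$max.depth,
    min.node.size = bst$min.node.size, probability = TRUE,
    num.threads = 1, seed = 17L, verbose = FALSE
  )
  predict(fit, test_x)$predictions[, "1"]
}

#' Evaluate a classifier on a feature subset
#'
#' Trains and evaluates one registered classifier on the masked feature set
#' under the given protocol. Confusion counts and class-1 scores are pooled
#' over all evaluated samples; the report carries the Table-style metric set
#' plus rank-based AUC.
#'
#' @param data Data frame of predictors (a `target` column is ignored).
#' @param labels Binary 0/1 outcome vector.
#' @param mask 0/1 feature-inclusion vector; `NULL` means all features.
#' @param classifier Registry name, see [classifier_registry()].
#' @param protocol An [eval_protocol()].
#' @param hyper Named list of hyperparameter overrides for the adapter.
#' @param seed Seed for the classifier fits.
#' @return One-row tibble: `classifier`, `n_features`, the metrics of
#'   [classification_metrics()], `auc`, and the pooled counts.
#' @export
evaluate_subset <- function(data, labels, mask = NULL, classifier = "RF",
                            protocol = eval_protocol(), hyper = list(),
                            seed = 1L) {
  x <- predictor_frame(data)
  check_labels(labels, nrow(x))
  if (is.null(mask)) mask <- rep(1L, ncol(x))
  mask <- check_mask(mask, ncol(x))
  if (!classifier %in% classifier_registry()) {
    abort(sprintf(
      "unknown classifier '%s'; registered: %s",
      classifier, paste(classifier_registry(), collapse = ", ")
    ))
  }
  xm <- x[, mask == 1, drop = FALSE]
  if (protocol$scheme == "stratified_kfold") {
    fold <- stratified_folds(labels, protocol$folds, protocol$seed)
    eval_sets <- lapply(seq_len(protocol$folds), function(f) {
      list(train = which(fold != f), test = which(fold == f))
    })
  } else {
    fold <- stratified_folds(
      labels, max(2L, round(1 / protocol$test_fraction)), protocol$seed
    )
    eval_sets <- list(list(train = which(fold != 1), test = which(fold == 1)))
  }
  scores <- rep(NA_real_, nrow(xm))
  for (s in eval_sets) {
    scores[s$test] <- fit_predict_score(
      classifier, xm[s$train, , drop = FALSE], labels[s$train],
      xm[s$test, , drop = FALSE], hyper, seed
    )
  }
  used <- which(!is.na(scores))
  pred <- as.integer(scores[used] > 0.5)
  counts <- confusion_counts(labels[used], pred)
  metrics <- classification_metrics(counts)
  dplyr::bind_cols(
    tibble(classifier = classifier, n_features = sum(mask)),
    metrics,
    tibble(auc = auc_rank(scores[used], labels[used])),
    counts
  )
}

#' Compare selection methods across classifiers
#'
#' Runs the before/after-selection comparison: for each requested selection
#' method (all features, filter top-k, GA, PSO, ACO) and each requested
#' classifier, evaluates the selected subset under a common protocol.
#' Selected feature names are recorded per method.
#'
#' @inheritParams evaluate_subset
#' @param methods Character vector from `all_features`, `filter`, `ga`,
#'   `pso`, `aco`.
#' @param classifiers Registry names to evaluate (default all nine).
#' @param filter_k Features kept by the filter method.
#' @param ga,pso,aco Optimizer configurations (defaults as in their
#'   constructors).
#' @param fitness Optional shared memoised fitness closure for the three
#'   optimizers.
#' @param num_trees Trees for the default wrapper objective.
#' @return Tibble with one row per method x classifier: `method`,
#'   `n_selected`, `selected` (comma-joined names), `classifier` and the
#'   metric columns of [evaluate_subset()].
#' @export
compare_methods <- function(data, labels,
                            methods = c("all_features", "filter", "ga", "pso", "aco"),
                            classifiers = classifier_registry(),
                            filter_k = 8,
                            protocol = eval_protocol(),
                            ga = ga_config(), pso = swarm_config(),
                            aco = aco_config(), fitness = NULL,
                            num_trees = 100, seed = 1L) {
  x <- predictor_frame(data)
  check_labels(labels, nrow(x))
  if (length(methods) == 0) abort("at least one method is required")
  methods <- match.arg(
    methods, c("all_features", "filter", "ga", "pso", "aco"),
    several.ok = TRUE
  )
  masks <- purrr::map(methods, function(m) {
    switch(
      m,
      all_features = setNames(rep(1L, ncol(x)), names(x)),
      filter = select_top_k(
        filter_rank(x, labels, seed = child_seed(seed, 1)), filter_k
      ),
      ga = run_ga(x, labels, ga, fitness = fitness, num_trees = num_trees)$best_mask,
      pso = run_pso(x, labels, pso, fitness = fitness, num_trees = num_trees)$best_mask,
      aco = run_aco(x, labels, aco, fitness = fitness, num_trees = num_trees)$best_mask
    )
  })
  names(masks) <- methods
  purrr::map_dfr(methods, function(m) {
    mask <- masks[[m]]
    purrr::map_dfr(classifiers, function(cl) {
      dplyr::bind_cols(
        tibble(
          method = m, n_selected = sum(mask),
          selected = paste(names(x)[mask == 1], collapse = ",")
        ),
        evaluate_subset(
          x, labels, mask, classifier = cl, protocol = protocol,
          seed = child_seed(seed, 2)
        )
      )
    })
  })
}
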