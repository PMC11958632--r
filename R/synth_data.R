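#' Synthetic cohort configuration
#'
#' Describes a Cleveland-shaped cohort: five numeric vitals (age, resting
#' blood pressure, cholesterol, maximum heart rate, ST depression analogues)
#' drawn from normals, eight nominal attributes drawn from categorical
#' distributions over the UCI codes, and a logistic outcome model in which
#' only the features named in `informative` carry signal. Features are
#' standardized inside the logistic link so coefficients are comparable
#' across numeric and coded-nominal features; everything outside
#' `informative` is independent of the label by construction.
#'
#' The default emulates the 13-column layout with three informative
#' features (`thalach`, `oldpeak`, `cp`, coefficients -1.5, 1.5, 1.0) and
#' ten noise features at n = 500.
#'
#' @param n_patients Cohort size.
#' @param numeric_specs Tibble `feature`, `mean`, `sd`.
#' @param nominal_specs Tibble `feature`, `levels` (list), `probs` (list,
#'   each summing to 1).
#' @param informative Named numeric vector of logistic coefficients
#'   `beta_j` over a subset of the features.
#' @param intercept Logistic intercept `beta_0`.
#' @param seed Generator seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 500,
                          numeric_specs = NULL, nominal_specs = NULL,
                          informative = c(thalach = -1.5, oldpeak = 1.5, cp = 1.0),
                          intercept = 0, seed = 1L) {
  numeric_specs <- numeric_specs %||% tibble::tribble(
    ~feature,   ~mean, ~sd,
    "age",      54,    9,
    "trestbps", 131,   17,
    "chol",     246,   51,
    "thalach",  150,   23,
    "oldpeak",  1.05,  1.1
  )
  nominal_specs <- nominal_specs %||% tibble::tribble(
    ~feature,  ~levels,     ~probs,
    "sex",     c(0, 1),     c(0.32, 0.68),
    "cp",      c(1, 2, 3, 4), c(0.08, 0.17, 0.28, 0.47),
    "fbs",     c(0, 1),     c(0.85, 0.15),
    "restecg", c(0, 1, 2),  c(0.50, 0.01, 0.49),
    "exang",   c(0, 1),     c(0.67, 0.33),
    "slope",   c(1, 2, 3),  c(0.47, 0.46, 0.07),
    "ca",      c(0, 1, 2, 3), c(0.58, 0.21, 0.13, 0.08),
    "thal",    c(3, 6, 7),  c(0.55, 0.06, 0.39)
  )
  feats <- c(numeric_specs$feature, nominal_specs$feature)
  if (length(feats) == 0) abort("the feature set is empty")
  bad <- setdiff(names(informative), feats)
  if (length(bad) > 0) {
    abort(sprintf(
      "informative features not in the schema: %s", paste(bad, collapse = ", ")
    ))
  }
  for (i in seq_len(nrow(nominal_specs))) {
    p <- nominal_specs$probs[[i]]
    if (abs(sum(p) - 1) > 1e-8) {
      abort(sprintf(
        "level probabilities for '%s' must sum to 1", nominal_specs$feature[i]
      ))
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      numeric_specs = numeric_specs, nominal_specs = nominal_specs,
      informative = informative, intercept = intercept,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic Cleveland-shaped cohort
#'
#' Draws the configured features, standardizes them, and samples the binary
#' label with probability
#' \eqn{\mathrm{logit}^{-1}(\beta_0 + \sum_{j \in S} \beta_j z_j)} where `S`
#' is the informative set. Identical seeds give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return List with `data` (tibble of predictors in schema order, with a
#'   `"kinds"` attribute), `labels` (0/1 integer vector) and `truth` (list:
#'   `informative` names, `coefficients`, `intercept`, realized
#'   `prevalence`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 100, seed = 3))
#' table(cohort$labels)
generate_cohort <- function(config = cohort_config()) {
  with_seed(config$seed, {
    n <- config$n_patients
    cols <- list()
    kinds <- character()
    schema <- cleveland_schema()
    for (i in seq_len(nrow(config$numeric_specs))) {
      s <- config$numeric_specs[i, ]
      v <- rnorm(n, s$mean, s$sd)
      # clamp to the declared physiological bounds where the schema has them
      b <- schema[schema$feature == s$feature, ]
      if (nrow(b) == 1) {
        if (!is.na(b$lower)) v <- pmax(v, b$lower)
        if (!is.na(b$upper)) v <- pmin(v, b$upper)
      }
      cols[[s$feature]] <- v
      kinds[s$feature] <- "numeric"
    }
    for (i in seq_len(nrow(config$nominal_specs))) {
      s <- config$nominal_specs[i, ]
      cols[[s$feature]] <- sample(s$levels[[1]], n, replace = TRUE,
                                  prob = s$probs[[1]])
      kinds[s$feature] <- "nominal"
    }
    ord <- intersect(cleveland_schema()$feature, names(cols))
    ord <- c(ord, setdiff(names(cols), ord))
    data <- as_tibble(cols)[ord]
    lin <- rep(config$intercept, n)
    for (nm in names(config$informative)) {
      v <- data[[nm]]
      z <- if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
      lin <- lin + config$informative[[nm]] * z
    }
    labels <- rbinom(n, 1, plogis(lin))
    attr(data, "kinds") <- kinds[ord]
    list(
      data = data,
      labels = as.integer(labels),
      truth = list(
        informative = names(config$informative),
        coefficients = config$informative,
        intercept = config$intercept,
        prevalence = mean(labels)
      )
    )
  })
}

#' Write a cohort in the Cleveland dialect with a ground-truth sidecar
#'
#' The cohort's predictors plus its binary label (as the raw target column)
#' go to `path` in the header-less comma-separated dialect; the ground truth
#' is written as JSON next to it.
#'
#' @param cohort Output of [generate_cohort()].
#' @param path Output CSV path; the sidecar is `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort$data
  out$target <- cohort$labels
  write_cleveland(out, path)
  jsonlite::write_json(
    cohort$truth, paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Per-feature selection frequency over repeated runs
#'
#' The fraction of optimization runs in which each feature's mask bit is
#' set; the basis of the informative-vs-noise recovery comparison.
#'
#' @param results List of `optimization_result` objects over one feature
#'   space.
#' @return Tibble `feature`, `frequency` in schema order.
#' @export
selection_frequency <- function(results) {
  if (length(results) == 0) abort("no optimization results supplied")
  feats <- results[[1]]$features
  for (r in results) {
    if (!identical(r$features, feats)) {
      abort("results must share one feature space")
    }
  }
  m <- do.call(rbind, lapply(results, `[[`, "best_mask"))
  tibble(feature = feats, frequency = colMeans(m))
}

#' Informative-vs-noise recovery margin
#'
#' Summarizes a recovery experiment: the mean selection frequency over the
#' true informative features minus the mean over the noise features. A
#' successful subset search yields a clearly positive margin.
#'
#' @param freq Tibble from [selection_frequency()].
#' @param informative Character vector of true informative feature names.
#' @return One-row tibble: `informative_mean`, `noise_mean`, `margin`.
#' @export
recovery_margin <- function(freq, informative) {
  inf_f <- freq$frequency[freq$feature %in% informative]
  noise_f <- freq$frequency[!freq$feature %in% informative]
  tibble(
    informative_mean = mean(inf_f),
    noise_mean = mean(noise_f),
    margin = mean(inf_f) - mean(noise_f)
  )
}
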