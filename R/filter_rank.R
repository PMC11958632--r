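score_tbl <- function(features, method, scores) {
  tibble(feature = features, method = method, score = as.numeric(scores))
}

#' Chi-square filter scores
#'
#' Class-sum chi-square statistic per feature, the standard top-K filter
#' convention for nonnegative tabular features: observed values are the
#' per-class sums of the feature, expected values split the total feature sum
#' in proportion to class size, and the score is \eqn{\sum_c (O_c - E_c)^2 / E_c}.
#'
#' @param data Data frame of predictors (a `target` column is ignored). All
#'   values must be nonnegative.
#' @param labels Binary 0/1 outcome vector, one per row.
#' @return Tibble with columns `feature`, `method`, `score`.
#' @export
#' @examples
#' chi_square_scores(data.frame(x = c(1, 1, 3, 3)), c(0, 0, 1, 1))
chi_square_scores <- function(data, labels) {
  x <- predictor_frame(data)
  check_labels(labels, nrow(x))
  cls <- sort(unique(labels))
  n <- length(labels)
  scores <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    if (any(v < 0)) {
      abort(sprintf(
        "feature '%s' has negative values; chi-square needs nonnegative input (shift or scale it first)",
        nm
      ))
    }
    tot <- sum(v)
    if (tot == 0) {
      warn(sprintf("feature '%s' sums to zero; chi-square score set to 0", nm))
      return(0)
    }
    obs <- vapply(cls, function(c) sum(v[labels == c]), numeric(1))
    exp <- tot * vapply(cls, function(c) mean(labels == c), numeric(1))
    sum((obs - exp)^2 / exp)
  }, numeric(1))
  score_tbl(names(x), "chi_square", scores)
}

#' ANOVA F filter scores
#'
#' One-way ANOVA F statistic of each feature against the binary outcome:
#' \eqn{F = (SSB/df_1) / (SSW/df_2)} with \eqn{df_1 = } classes \eqn{- 1} and
#' \eqn{df_2 = n - } classes. A feature with zero within-group variance but
#' separated group means is reported as `Inf` (ranked above all finite
#' scores) with a warning.
#'
#' @inheritParams chi_square_scores
#' @return Tibble with columns `feature`, `method`, `score`.
#' @export
#' @examples
#' anova_f_scores(data.frame(x = c(1, 2, 3, 4)), c(0, 0, 1, 1))
anova_f_scores <- function(data, labels) {
  x <- predictor_frame(data)
  check_labels(labels, nrow(x))
  cls <- sort(unique(labels))
  if (length(cls) < 2) abort("both classes must be present")
  n <- length(labels)
  df1 <- length(cls) - 1
  df2 <- n - length(cls)
  scores <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    gm <- mean(v)
    ssb <- sum(vapply(cls, function(c) {
      sum(labels == c) * (mean(v[labels == c]) - gm)^2
    }, numeric(1)))
    ssw <- sum(vapply(cls, function(c) {
      sum((v[labels == c] - mean(v[labels == c]))^2)
    }, numeric(1)))
    if (ssw == 0) {
      if (ssb == 0) return(0)
      warn(sprintf(
        "feature '%s' has zero within-group variance; F reported as Inf", nm
      ))
      return(Inf)
    }
    (ssb / df1) / (ssw / df2)
  }, numeric(1))
  score_tbl(names(x), "f_statistic", scores)
}

discrete_mi <- function(x, y) {
  jt <- table(x, y)
  n <- sum(jt)
  pj <- jt / n
  px <- rowSums(pj)
  py <- colSums(pj)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      p <- pj[i, j]
      if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
    }
  }
  max(mi, 0)
}

# Nearest-neighbour MI estimate between a continuous feature and a discrete
# label (Ross-style estimator): for each point, the radius is the distance to
# its k-th nearest neighbour within its own class; m counts the sample points
# strictly inside that radius. Estimates can be slightly negative and are
# clipped at zero by the caller.
knn_mi <- function(x, y, k = 3) {
  n <- length(x)
  keep <- ave(seq_along(y), y, FUN = length) > 1
  x <- x[keep]
  y <- y[keep]
  n_eff <- length(x)
  if (n_eff < 2) return(0)
  d <- abs(outer(x, x, "-"))
  k_all <- numeric(n_eff)
  radius <- numeric(n_eff)
  label_counts <- ave(seq_along(y), y, FUN = length)
  for (i in seq_len(n_eff)) {
    same <- which(y == y[i])
    same <- same[same != i]
    k_i <- min(k, length(same))
    radius[i] <- sort(d[i, same])[k_i]
    k_all[i] <- k_i
  }
  m_all <- vapply(seq_len(n_eff), function(i) sum(d[i, ] < radius[i]), numeric(1))
  m_all <- pmax(m_all, 1)
  digamma(n_eff) + mean(digamma(k_all)) -
    mean(digamma(label_counts)) - mean(digamma(m_all))
}

#' Mutual-information filter scores
#'
#' Mutual information of each feature with the binary outcome, in nats.
#' Nominal features use the plug-in estimate from the empirical contingency
#' table. Numeric features use a nearest-neighbour estimator (`k` neighbours,
#' default 3) after adding a seeded micro-jitter that breaks ties; estimates
#' are clipped at zero.
#'
#' @inheritParams chi_square_scores
#' @param k Neighbour count for the continuous estimator.
#' @param seed Integer seed for the tie-breaking jitter.
#' @return Tibble with columns `feature`, `method`, `score`.
#' @export
mutual_info_scores <- function(data, labels, k = 3, seed = 1L) {
  x <- predictor_frame(data)
  check_labels(labels, nrow(x))
  kinds <- feature_kinds(data)
  scores <- with_seed(seed, vapply(names(x), function(nm) {
    v <- x[[nm]]
    if (kinds[[nm]] == "nominal") {
      discrete_mi(v, labels)
    } else {
      jitter_sd <- 1e-10 * max(1, mean(abs(v)))
      vj <- v + rnorm(length(v), sd = jitter_sd)
      max(knn_mi(vj, labels, k = k), 0)
    }
  }, numeric(1)))
  score_tbl(names(x), "mutual_information", scores)
}

#' Aggregate the three filter scores into an overall ranking
#'
#' Per feature: each filter's rank (1 = best score, ties to the earlier
#' feature), the total (sum of the three raw scores) and the overall rank by
#' descending total. The overall ranking is what downstream top-k selection
#' consumes.
#'
#' @param chi,mi,f Score tibbles from [chi_square_scores()],
#'   [mutual_info_scores()], [anova_f_scores()] (any order of the three
#'   methods is accepted) over the same features.
#' @return A `rank_table` tibble with columns `feature`, `chi_square`,
#'   `mutual_information`, `f_statistic`, the three `*_rank` columns,
#'   `total`, `overall_rank`.
#' @export
aggregate_ranks <- function(chi, mi, f) {
  all <- dplyr::bind_rows(chi, mi, f)
  expected <- c("chi_square", "mutual_information", "f_statistic")
  if (!setequal(unique(all$method), expected)) {
    abort(sprintf(
      "need exactly the three methods %s", paste(expected, collapse = ", ")
    ))
  }
  feats <- unique(all$feature)
  by_m <- split(all, all$method)
  for (m in names(by_m)) {
    if (!setequal(by_m[[m]]$feature, feats) || nrow(by_m[[m]]) != length(feats)) {
      abort("the three score vectors must cover an identical feature set")
    }
  }
  wide <- all |>
    tidyr::pivot_wider(names_from = "method", values_from = "score") |>
    dplyr::select(dplyr::all_of(c("feature", expected)))
  wide <- wide[match(feats, wide$feature), ]
  desc_rank <- function(s) rank(-s, ties.method = "first")
  out <- wide |>
    dplyr::mutate(
      chi_square_rank = desc_rank(.data$chi_square),
      mutual_information_rank = desc_rank(.data$mutual_information),
      f_statistic_rank = desc_rank(.data$f_statistic),
      total = .data$chi_square + .data$mutual_information + .data$f_statistic,
      overall_rank = desc_rank(.data$total)
    )
  class(out) <- c("rank_table", class(out))
  out
}

#' Select the top-k features of an overall ranking
#'
#' @param ranks A `rank_table` from [aggregate_ranks()].
#' @param k Number of features to keep, `1 <= k <= n`.
#' @return A named 0/1 subset mask over the ranked features, 1 for the `k`
#'   best overall ranks.
#' @export
select_top_k <- function(ranks, k) {
  n <- nrow(ranks)
  if (k < 1 || k > n) abort(sprintf("k must be in 1..%d", n))
  mask <- as.integer(ranks$overall_rank <= k)
  names(mask) <- ranks$feature
  mask
}

#' One-call filter ranking
#'
#' Runs the three univariate filters and aggregates them; equivalent to
#' piping [chi_square_scores()], [mutual_info_scores()] and
#' [anova_f_scores()] into [aggregate_ranks()]. Because the chi-square
#' filter requires nonnegative input, any feature with negative values is
#' shifted by its minimum for that filter only (the usual convention before
#' a chi-square filter); set `shift_nonnegative = FALSE` to error instead.
#'
#' @inheritParams mutual_info_scores
#' @param shift_nonnegative Shift negative-valued features to zero minimum
#'   for the chi-square stage.
#' @return A `rank_table` tibble, see [aggregate_ranks()].
#' @export
filter_rank <- function(data, labels, k = 3, seed = 1L,
                        shift_nonnegative = TRUE) {
  x <- predictor_frame(data)
  kinds <- feature_kinds(data)
  x_chi <- x
  if (shift_nonnegative) {
    for (nm in names(x_chi)) {
      mn <- min(x_chi[[nm]])
      if (mn < 0) x_chi[[nm]] <- x_chi[[nm]] - mn
    }
  }
  attr(x, "kinds") <- kinds
  aggregate_ranks(
    chi_square_scores(x_chi, labels),
    mutual_info_scores(x, labels, k = k, seed = seed),
    anova_f_scores(x, labels)
  )
}

#' Published reference filter scores for the Cleveland table
#'
#' A published reference score table for the 13 Cleveland predictors: the
#' three per-filter scores together with the printed total and overall rank.
#' Two printed rows (`cp`, `thal`) are arithmetically inconsistent with their
#' own score columns in the source and are flagged by `consistent = FALSE`;
#' exact checks of the aggregation are meaningful only on the consistent
#' rows.
#'
#' @return Tibble with columns `feature`, `chi_square`,
#'   `mutual_information`, `f_statistic`, `published_total`,
#'   `published_rank`, `consistent`.
#' @export
cleveland_reference_scores <- function() {
  path <- system.file(
    "extdata", "cleveland_reference_scores.csv", package = "cardioselect"
  )
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(consistent = as.logical(.data$consistent))
}
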