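#' Tidy an optimization result
#'
#' @param x An `optimization_result`.
#' @param ... Unused.
#' @return Tibble `iteration`, `best_fitness` (the per-iteration trace).
#' @method tidy optimization_result
#' @export
tidy.optimization_result <- function(x, ...) {
  tibble(
    iteration = seq_along(x$trace),
    best_fitness = x$trace
  )
}

#' One-row summary of an optimization result
#'
#' @param x An `optimization_result`.
#' @param ... Unused.
#' @return Tibble `method`, `best_fitness`, `best_objective`, `n_selected`,
#'   `selected`, `iterations`, `evaluations`, `seed`.
#' @method glance optimization_result
#' @export
glance.optimization_result <- function(x, ...) {
  tibble(
    method = x$method,
    best_fitness = x$best_fitness,
    best_objective = x$best_objective,
    n_selected = sum(x$best_mask),
    selected = paste(x$features[x$best_mask == 1], collapse = ","),
    iterations = length(x$trace),
    evaluations = x$evaluations,
    seed = x$seed
  )
}

#' Convergence-trace plot
#'
#' @param object An `optimization_result`.
#' @param ... Unused.
#' @return A ggplot of best fitness against iteration.
#' @method autoplot optimization_result
#' @export
autoplot.optimization_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$iteration, .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "iteration", y = "best fitness",
      title = sprintf("%s subset search (%d/%d features selected)",
                      toupper(object$method), sum(object$best_mask),
                      length(object$best_mask))
    ) +
    ggplot2::theme_minimal()
}

#' Filter-ranking plot
#'
#' @param object A `rank_table` from [aggregate_ranks()].
#' @param ... Unused.
#' @return A ggplot of total filter score per feature, best rank on top.
#' @method autoplot rank_table
#' @export
autoplot.rank_table <- function(object, ...) {
  object |>
    dplyr::arrange(dplyr::desc(.data$overall_rank)) |>
    dplyr::mutate(feature = factor(.data$feature, levels = .data$feature)) |>
    ggplot2::ggplot(ggplot2::aes(.data$total, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "total filter score (chi-square + MI + F)", y = NULL,
      title = "Univariate filter ranking"
    ) +
    ggplot2::theme_minimal()
}

#' Selection-frequency plot
#'
#' @param freq Tibble from [selection_frequency()].
#' @param informative Optional names of the true informative features,
#'   highlighted when given.
#' @return A ggplot of per-feature selection frequency.
#' @export
plot_selection_frequency <- function(freq, informative = NULL) {
  dat <- freq |>
    dplyr::mutate(
      role = if (is.null(informative)) "feature" else
        ifelse(.data$feature %in% informative, "informative", "noise"),
      feature = factor(.data$feature, levels = rev(.data$feature))
    )
  ggplot2::ggplot(dat, ggplot2::aes(.data$frequency, .data$feature,
                                    fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "selection frequency", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Method-comparison plot
#'
#' @param comparison Tibble from [compare_methods()].
#' @param metric Metric column to display (default accuracy).
#' @return A ggplot of the metric by classifier, faceted nothing, coloured
#'   by selection method.
#' @export
plot_comparison <- function(comparison, metric = "accuracy") {
  ggplot2::ggplot(comparison, ggplot2::aes(
    .data$classifier, .data[[metric]], fill = .data$method
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric, fill = "selection") +
    ggplot2::theme_minimal()
}
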