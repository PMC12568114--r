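#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot stage-wise metrics of a retraining experiment
#'
#' One panel per metric, one line per strategy mode, across retraining
#' stages.
#'
#' @param object A `ddm_experiment`.
#' @param metrics Which report columns to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ddm_experiment
#' @export
autoplot.ddm_experiment <- function(object,
                                    metrics = c("mae", "rmse", "ndcg",
                                                "n_total"),
                                    ...) {
  long <- object$reports |>
    select(all_of(c("stage", "mode", metrics))) |>
    tidyr::pivot_longer(all_of(metrics), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$value,
                                     colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Retraining stage", y = NULL, colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot fitted feature weights
#'
#' @param object A `ddm_feature_weights`.
#' @param ... Unused.
#' @return A ggplot bar chart of weights, coloured by feature group.
#' @method autoplot ddm_feature_weights
#' @export
autoplot.ddm_feature_weights <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature, .data$weight),
                                  y = .data$weight, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Controller weight", fill = "Group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a session embedding
#'
#' Scatter of the first two principal components, coloured by sport.
#'
#' @param object A `ddm_embedding`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ddm_embedding
#' @export
autoplot.ddm_embedding <- function(object, ...) {
  d <- as_tibble(object$index)
  d$pc1 <- object$scores[, 1]
  d$pc2 <- if (ncol(object$scores) >= 2) object$scores[, 2] else 0
  evr <- object$explained_variance_ratio
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                  colour = .data$sport)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * evr[1]),
      y = if (length(evr) >= 2) sprintf("PC2 (%.0f%%)", 100 * evr[2]) else "PC2",
      colour = "Sport"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a similarity-threshold sweep
#'
#' @param sweep A [run_threshold_sweep()] result.
#' @return A ggplot of reduction rate against threshold.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$threshold,
                                      y = .data$reduction_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Cosine similarity threshold",
                  y = "Reduction rate (%)") +
    ggplot2::theme_minimal()
}
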