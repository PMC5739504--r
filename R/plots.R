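#' Plot a sensitivity/specificity sweep
#'
#' Both curves against the score threshold, with the crossover marked.
#'
#' @param object A `trna_sweep` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trna_sweep <- function(object, ...) {
  curve <- tidy(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "rate", values_to = "value")
  ggplot2::ggplot(curve, ggplot2::aes(.data$threshold, .data$value,
                                      colour = .data$rate)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = attr(object, "crossover_threshold"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "pathogenicity score threshold", y = NULL,
                  colour = NULL,
                  subtitle = sprintf("crossover %.3g (sens %.2f, spec %.2f)",
                                     attr(object, "crossover_threshold"),
                                     attr(object, "sensitivity_at_crossover"),
                                     attr(object, "specificity_at_crossover"))) +
    ggplot2::theme_minimal()
}

#' Plot a differential-evolution trace
#'
#' Best objective per generation (non-increasing under greedy selection).
#'
#' @param object A `trna_tuning` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trna_tuning <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$generation, .data$best_objective)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "generation", y = "best objective",
                  subtitle = sprintf("final objective %.4f", object$objective)) +
    ggplot2::theme_minimal()
}

#' Score distribution by labelled class
#'
#' Box plot of scores for labelled pathogenic and benign variants, the
#' usual first look at how well the scorer separates the classes.
#'
#' @param data A data frame with a score column and a label column (e.g.
#'   the output of [loo_rescore()] joined to labels).
#' @param score,label Column names.
#' @return A ggplot.
#' @export
plot_score_separation <- function(data, score = "total_score",
                                  label = "label") {
  ggplot2::ggplot(data, ggplot2::aes(.data[[label]], .data[[score]],
                                     fill = .data[[label]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "pathogenicity score") +
    ggplot2::theme_minimal()
}
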