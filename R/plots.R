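#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_abline geom_col coord_flip labs theme_minimal
#' @export
ggplot2::autoplot

#' ROC curve of a hold-out evaluation
#'
#' Plots the receiver operating characteristic traced by thresholding the
#' forest's vote fractions on the held-out subjects.
#'
#' @param object A `cc_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cc_evaluation
#' @export
autoplot.cc_evaluation <- function(object, ...) {
  ord <- order(object$scores, decreasing = TRUE)
  lab <- object$labels[ord]
  df <- tibble(
    tpr = c(0, cumsum(lab) / max(sum(lab), 1)),
    fpr = c(0, cumsum(!lab) / max(sum(!lab), 1))
  )
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %s)",
                         ifelse(is.na(object$auc), "NA",
                                sprintf("%.2f", object$auc)))) +
    theme_minimal()
}

#' Feature-importance bar chart of a model evaluation
#'
#' @param object A `cc_evaluation`.
#' @param top_n Number of top features to show.
#' @return A ggplot.
#' @export
plot_importances <- function(object, top_n = 15) {
  df <- tidy(object) |> utils::head(top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$feature, y = .data$gini_importance)) +
    geom_col(fill = "#41ab5d") +
    coord_flip() +
    labs(x = NULL, y = "Mean decrease in Gini") +
    theme_minimal()
}

#' Accuracy profile of a recursive-feature-elimination run
#'
#' Mean inner cross-validation accuracy against candidate feature-subset
#' size, with the winning size highlighted.
#'
#' @param object A `cc_rfe`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cc_rfe
#' @export
autoplot.cc_rfe <- function(object, ...) {
  df <- object$profile
  ggplot(df, aes(x = .data$size, y = .data$mean_accuracy)) +
    geom_line(colour = "grey40") +
    geom_point() +
    geom_point(data = df[df$size == object$best_size, ],
               colour = "#d7301f", size = 3) +
    labs(x = "Feature subset size", y = "Mean inner accuracy") +
    theme_minimal()
}

#' Clustering-coefficient profile of a cohort by outcome
#'
#' Mean baseline clustering coefficient per region, split by impairment
#' outcome; predictive regions are highlighted.
#'
#' @param metrics Long tibble with `subject_id`, `region`, `clustering`.
#' @param status Tibble with `subject_id` and `outcome_label`.
#' @param highlight Regions to mark (default none).
#' @return A ggplot.
#' @export
plot_clustering_by_outcome <- function(metrics, status, highlight = NULL) {
  df <- metrics |>
    dplyr::inner_join(select(status, "subject_id", "outcome_label"),
                      by = "subject_id") |>
    group_by(.data$region, .data$outcome_label) |>
    summarise(clustering = mean(.data$clustering), .groups = "drop") |>
    mutate(highlighted = .data$region %in% (highlight %||% character(0)))
  ggplot(df, aes(x = .data$region, y = .data$clustering,
                 colour = .data$outcome_label)) +
    geom_point(aes(shape = .data$highlighted)) +
    labs(x = NULL, y = "Mean clustering coefficient", colour = "Outcome",
         shape = "Predictive region") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
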