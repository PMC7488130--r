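#' Heatmap of a module score across patients and modules
#'
#' @param scores A `module_scores` tibble from [score_all()].
#' @param metric Score column to draw: `"s_score"`, `"score_genes"` or
#'   `"score_drugs"`.
#' @return A ggplot object (patients on the y axis, modules on the x axis).
#' @export
plot_score_heatmap <- function(scores,
                               metric = c("s_score", "score_genes",
                                          "score_drugs")) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(scores)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$module),
                                        y = .data$patient,
                                        fill = .data[[metric]])) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::labs(x = "module", y = "patient", fill = metric)
  if (metric == "s_score") {
    p <- p + ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                           high = "#b2182b", midpoint = 0,
                                           limits = c(-1, 1))
  } else {
    p <- p + ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                          limits = c(0, 1))
  }
  p + ggplot2::theme_minimal()
}

#' Autoplot method for module score tables
#'
#' @param object A `module_scores` tibble.
#' @param metric Passed to [plot_score_heatmap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_scores <- function(object, metric = "s_score", ...) {
  plot_score_heatmap(object, metric = metric)
}

#' Bar chart of selection categories across the cohort
#'
#' @param selections A `module_selection` tibble from [select_active()].
#' @return A ggplot object.
#' @export
plot_selection_summary <- function(selections) {
  df <- dplyr::count(tibble::as_tibble(selections), .data$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#4d72b0") +
    ggplot2::labs(x = "selection category", y = "patients") +
    ggplot2::theme_minimal()
}
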