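# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a concordance regression
#'
#' Morphological value on x, genetic value on y (on the transformed scale
#' for the IOBS), with the fitted line and the identity line.
#'
#' @param object A `concordance_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concordance_fit <- function(object, ...) {
  lab <- if (object$metric == "iobs") "ln IOBS" else object$metric
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste(lab, "(morphological)"), y = paste(lab, "(genetic)"),
      title = sprintf("%s: R² = %.3f, slope = %.3f, n = %d",
                      object$metric, object$r_squared, object$slope,
                      object$n)) +
    ggplot2::theme_minimal()
}

#' Stacked composition plot of site communities
#'
#' @param community A site community tibble (one or more sites).
#' @param fill One of `"group"` or `"label"`.
#' @return A ggplot.
#' @export
plot_community <- function(community, fill = c("group", "label")) {
  fill <- match.arg(fill)
  ggplot2::ggplot(community,
                  ggplot2::aes(x = .data$site_id, y = .data$count,
                               fill = .data[[fill]])) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of specimens") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-site quality classes from both identification routes
#'
#' @param summary The `summary` tibble of a `study_report`.
#' @return A ggplot comparing morphological and genetic classes per site.
#' @export
plot_quality_classes <- function(summary) {
  long <- tidyr::pivot_longer(
    summary[, c("site_id", "habitat", "morph_class", "genetic_class")],
    cols = c("morph_class", "genetic_class"),
    names_to = "source", values_to = "quality_class")
  long$source <- sub("_class$", "", long$source)
  long$quality_class <- quality_factor(long$quality_class)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site_id,
                                     y = .data$quality_class,
                                     colour = .data$source,
                                     shape = .data$source)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        size = 2.5) +
    ggplot2::facet_grid(. ~ habitat, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "quality class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
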