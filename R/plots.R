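# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_vline labs theme_minimal facet_wrap scale_size_area
#' @export
ggplot2::autoplot

#' BIC trace plot
#'
#' BIC against the number of clusters, with the selected k marked.
#'
#' @param object a [select_cluster_count()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bic_trace <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$k, y = .data$bic)) +
    geom_line(colour = "grey40") +
    geom_point() +
    geom_vline(xintercept = object$selected_k, linetype = "dashed",
               colour = "firebrick") +
    labs(x = "number of clusters k", y = "BIC",
         title = sprintf("Cluster-count selection (k = %d)",
                         object$selected_k)) +
    theme_minimal()
}

#' Scree plot of a PCA summary
#'
#' @param object a [pca_summary()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pca_summary <- function(object, ...) {
  df <- tidy.pca_summary(object)
  ggplot(df, aes(x = .data$component, y = .data$variance_explained)) +
    geom_col(fill = "steelblue") +
    labs(x = "principal component", y = "% variance explained") +
    theme_minimal()
}

#' Mean temporal profile per cluster
#'
#' @param fit a [fit_gmm()] object.
#' @param profiles the profile tibble the model was fitted to.
#' @return a ggplot, one facet per cluster.
#' @export
plot_cluster_profiles <- function(fit, profiles) {
  df <- cluster_mean_profiles(fit, profiles)
  df$cell <- factor(df$cell, levels = unique(df$cell))
  ggplot(df, aes(x = .data$cell, y = .data$mean_z, group = .data$cluster)) +
    geom_line(colour = "steelblue") +
    geom_point(size = 1) +
    facet_wrap(~cluster) +
    labs(x = "(condition, day) cell", y = "mean z-score") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Degree vs betweenness hub/bottleneck plot
#'
#' @param classification tibble from [classify_hub_bottleneck()].
#' @param highlight optional character vector of node ids drawn in red
#'   (e.g. the significantly altered proteins).
#' @return a ggplot on log-scaled axes.
#' @export
plot_hub_bottleneck <- function(classification, highlight = NULL) {
  classification$highlight <- classification$node %in% (highlight %||% character(0))
  ggplot(classification,
         aes(x = .data$degree, y = .data$betweenness,
             colour = .data$highlight)) +
    geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    labs(x = "degree (hub-ness)", y = "betweenness (bottleneck-ness)") +
    theme_minimal()
}

#' Module size against query fraction
#'
#' Marker area encodes the MCODE score, mirroring the usual module-summary
#' scatter.
#'
#' @param modules an [mcode()] result with a `query_fraction` column (see
#'   [run_pipeline()]) or the columns size/score/query_fraction.
#' @return a ggplot.
#' @export
plot_module_summary <- function(modules) {
  if (!"query_fraction" %in% names(modules)) {
    abort("modules need a query_fraction column (see run_pipeline())")
  }
  ggplot(modules, aes(x = .data$size, y = .data$query_fraction,
                      size = .data$score)) +
    geom_point(alpha = 0.7, colour = "steelblue") +
    scale_size_area() +
    labs(x = "module size (nodes)", y = "fraction of module in query set",
         size = "MCODE score") +
    theme_minimal()
}
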