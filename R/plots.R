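#' Plot methods for pipeline results
#'
#' `autoplot()` methods for the main result types: ordination scatter
#' for `pcoa_result`, representation-by-factor R-squared bars for
#' `eval_grid`, a volcano plot for `da_result`, and degree/Jaccard
#' panels for `interaction_shift`. All return ggplot objects the caller
#' can restyle.
#'
#' @param object A result object.
#' @param labels Optional group label per sample (pcoa).
#' @param q_threshold DAM threshold drawn on the volcano plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name agemicro-autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname agemicro-autoplot
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, labels = NULL, ...) {
  df <- object$points
  if (!is.null(labels)) df$group <- as.character(labels)
  pct <- round(100 * object$rel_eig[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2))
  p <- if (is.null(labels)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::stat_ellipse(ggplot2::aes(colour = .data$group),
                            level = 0.95)
  }
  p + ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pct[1]),
                    y = sprintf("PCo2 (%.1f%%)", pct[2]))
}

#' @rdname agemicro-autoplot
#' @method autoplot eval_grid
#' @export
autoplot.eval_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$representation, y = .data$R2,
                               fill = .data$factor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = expression(PERMANOVA ~ R^2)) +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname agemicro-autoplot
#' @method autoplot da_result
#' @export
autoplot.da_result <- function(object, q_threshold = 0.25, ...) {
  df <- object
  df$dam <- df$q_value < q_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coefficient,
                                   y = -log10(.data$p_value),
                                   colour = .data$dam)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "log2 effect (second vs first group)",
                  y = "-log10 p", colour = sprintf("q < %.2g", q_threshold))
}

#' @rdname agemicro-autoplot
#' @method autoplot interaction_shift
#' @export
autoplot.interaction_shift <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              dplyr::all_of(valid_kingdoms),
                              names_to = "kingdom", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$n,
                                     fill = .data$kingdom)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = object$focal_taxon,
                  x = NULL, y = "in-cluster neighbors")
}

#' Density plot of within-group pairwise distances
#'
#' @param distances Output of [pairwise_distance_density()].
#' @return A ggplot object.
#' @export
plot_distance_density <- function(distances) {
  ggplot2::ggplot(distances, ggplot2::aes(x = .data$distance,
                                          colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "within-group distance", y = "density")
}
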