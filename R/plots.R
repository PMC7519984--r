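#' Bar chart of per-timepoint up/down counts
#'
#' The time-lag view: numbers of significantly up- and downregulated DE
#' miRNAs and high-confidence target genes at each treatment timepoint.
#'
#' @param counts Output of [timecourse_counts()].
#' @return A ggplot object.
#' @export
plot_timecourse_counts <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$timepoint, y = .data$n,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(ggplot2::vars(.data$side),
                        labeller = ggplot2::as_labeller(
                          c(mirna = "DE miRNAs",
                            target = "high-confidence targets"))) +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#27ae60")) +
    ggplot2::labs(x = "time after heat onset", y = "probes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of family overall directions
#'
#' @param family_profiles An `mh_family_profiles` table.
#' @return A ggplot object.
#' @export
plot_family_directions <- function(family_profiles) {
  ov <- distinct(as_tibble(family_profiles), .data$family,
                 .data$overall_direction)
  ggplot2::ggplot(ov, ggplot2::aes(x = .data$overall_direction,
                                   fill = .data$overall_direction)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#27ae60",
                                          up_down = "#f39c12")) +
    ggplot2::labs(x = "overall family direction", y = "families") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Bar chart of GO-Slim term counts per aspect
#'
#' @param counts Output of [goslim_counts()].
#' @return A ggplot object.
#' @export
plot_goslim_counts <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$term, .data$n_genes),
                               y = .data$n_genes)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$aspect), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mh_family_profiles <- function(object, ...) {
  plot_family_directions(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.mh_de <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$pvalue),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$timepoint)) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#27ae60",
                                            none = "grey70")) +
    ggplot2::labs(x = "log2 fold change vs control",
                  y = expression(-log[10](p)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the miRNA-PPI network
#'
#' Base-graphics layout of the heterogeneous network: square family
#' nodes, round gene nodes, node colour by direction, dashed edges for
#' translation inhibition and grey edges for PPI.
#'
#' @param x An `mh_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.mh_network <- function(x, ...) {
  g <- x$graph
  dir_col <- c(up = "#c0392b", down = "#27ae60", up_down = "#f39c12")
  vcol <- dir_col[igraph::V(g)$direction]
  vcol[is.na(vcol)] <- "grey80"
  ecol <- ifelse(igraph::E(g)$kind == "ppi", "grey60", "black")
  elty <- ifelse(igraph::E(g)$kind == "translation_inhibition", 2, 1)
  igraph::plot.igraph(
    g,
    vertex.shape = ifelse(igraph::V(g)$type == "family", "square", "circle"),
    vertex.color = vcol, vertex.size = 6, vertex.label.cex = 0.5,
    edge.color = ecol, edge.lty = elty, ...)
  invisible(x)
}
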