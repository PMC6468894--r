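#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot of per-dataset quantile ranks for selected genes
#'
#' One box per gene and species over the per-dataset quantile ranks, with the
#' individual dataset ranks overplotted — the display used to show that
#' canonical hedgehog target genes rank highly in both species while other
#' genes are species-specific.
#'
#' @param ranks List of tibbles from [quantile_rank()].
#' @param homolog_map Tibble from [read_homolog_map()].
#' @param genes Character vector of gene symbols (human-side casing).
#' @return A ggplot object.
#' @export
plot_rank_boxplot <- function(ranks, homolog_map, genes) {
  df <- rank_boxplot_data(ranks, homolog_map) %>%
    filter(.data$gene %in% toupper(genes))
  if (!nrow(df)) abort("none of the requested genes found in the rank vectors")
  ggplot2::ggplot(df, ggplot2::aes(.data$gene, .data$qrank,
                                   fill = .data$species)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.8), size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "quantile rank of SHH overexpression") +
    ggplot2::theme_minimal()
}

#' Beeswarm-style plot of a single gene's expression by group
#'
#' Sample-level log2 expression of a gene's max-mean probeset, jittered
#' within groups.
#'
#' @param dataset A probeset-level [expression_dataset()].
#' @param gene Gene symbol.
#' @param annotation Optional probeset-to-gene map (defaults to the
#'   dataset's).
#' @return A ggplot object.
#' @export
plot_gene_expression <- function(dataset, gene, annotation = NULL) {
  df <- select_max_mean_probe(dataset, gene, annotation)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, color = "#B2182B") +
    ggplot2::labs(x = NULL, y = "log2 expression",
                  subtitle = sprintf("%s (%s, probeset %s)", gene,
                                     dataset$dataset_id,
                                     attr(df, "probeset"))) +
    ggplot2::theme_minimal()
}
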