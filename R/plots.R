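#' Heatmap of a cross-ome correlation matrix
#'
#' Tau heatmap with lipids in rows and proteins in columns, optionally
#' ordered by the dendrogram leaf order of a cluster assignment.
#'
#' @param object A `crossome_tau` object.
#' @param clusters Optional `crossome_clusters` tibble; if given, rows and
#'   columns follow its leaf order.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crossome_tau
#' @export
autoplot.crossome_tau <- function(object, clusters = NULL, ...) {
  df <- tidy(object)
  lipid_levels <- object$lipid_ids
  protein_levels <- object$protein_ids
  if (!is.null(clusters)) {
    lo <- clusters[clusters$ome == "lipid", ]
    po <- clusters[clusters$ome == "protein", ]
    lipid_levels <- lo$feature_id[order(lo$leaf_rank)]
    protein_levels <- po$feature_id[order(po$leaf_rank)]
  }
  df$lipid_id <- factor(df$lipid_id, levels = lipid_levels)
  df$protein_id <- factor(df$protein_id, levels = protein_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protein_id, y = .data$lipid_id,
                                   fill = .data$tau)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = "protein", y = "lipid", fill = "Kendall tau-b") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Bar plot of one cluster's genotype signature
#'
#' @param signatures Tibble from [cluster_signature()].
#' @param cluster Which cluster to plot.
#' @param control_genotype Control to drop from the bars (it is 0 by
#'   construction); keep with `NULL`.
#' @return A ggplot object.
#' @export
plot_cluster_signature <- function(signatures, cluster,
                                   control_genotype = "control") {
  df <- signatures[signatures$cluster == cluster, ]
  if (nrow(df) == 0) stop("no signature rows for cluster ", cluster)
  if (!is.null(control_genotype)) df <- df[df$genotype != control_genotype, ]
  df <- df[order(df$signature), ]
  df$genotype <- factor(df$genotype, levels = df$genotype)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$signature,
                                   fill = .data$signature > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "#2166AC")) +
    ggplot2::labs(x = NULL, y = "summed cluster log2FC (KO / control)",
                  title = sprintf("cluster %s signature", cluster)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Bar plot of top-partner protein frequencies
#'
#' @param freq Tibble from [top_partner_frequency()].
#' @param max_proteins Show at most this many proteins (default 20).
#' @return A ggplot object.
#' @export
plot_partner_frequency <- function(freq, max_proteins = 20) {
  df <- utils::head(freq, max_proteins)
  df$protein_id <- factor(df$protein_id, levels = rev(df$protein_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_lipids, y = .data$protein_id)) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::labs(x = "lipids carrying the protein in their top partners",
                  y = NULL) +
    ggplot2::theme_minimal()
}
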