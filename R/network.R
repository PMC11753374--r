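#' Extract a bipartite marker-lipid network
#'
#' Collects every edge between a set of marker proteins and the lipids in
#' the named lipid clusters whose `|tau|` exceeds `edge_tau_min`. Nodes with
#' no super-threshold edge do not appear. Unknown marker ids are skipped
#' with a warning.
#'
#' @param ct A `crossome_tau` object.
#' @param marker_proteins Character vector of protein ids of interest.
#' @param lipid_clusters Cluster ids whose lipids enter the network.
#' @param clusters Cluster assignment tibble (`ome`, `feature_id`,
#'   `cluster`) from [cluster_crossome()].
#' @param edge_tau_min Absolute-tau threshold for an edge, strict
#'   inequality (default 0.4).
#' @param species Optional parsed species tibble to annotate lipid class.
#' @return An edge tibble `protein_id`, `lipid_id`, `tau`,
#'   `protein_cluster`, `lipid_cluster` (and `lipid_class` when `species`
#'   is given), sorted by decreasing `|tau|`.
#' @export
extract_network <- function(ct, marker_proteins, lipid_clusters, clusters,
                            edge_tau_min = 0.4, species = NULL) {
  stopifnot(inherits(ct, "crossome_tau"))
  unknown <- setdiff(marker_proteins, ct$protein_ids)
  if (length(unknown) > 0) {
    warning(sprintf("skipped %d unknown marker id(s): %s", length(unknown),
                    paste(utils::head(unknown, 5), collapse = ", ")))
  }
  markers <- intersect(marker_proteins, ct$protein_ids)
  lip_tbl <- clusters[clusters$ome == "lipid" & clusters$cluster %in% lipid_clusters, ]
  lips <- intersect(lip_tbl$feature_id, ct$lipid_ids)
  empty <- tibble::tibble(protein_id = character(), lipid_id = character(),
                          tau = double(), protein_cluster = integer(),
                          lipid_cluster = integer())
  if (length(markers) == 0 || length(lips) == 0) return(empty)

  sub <- ct$tau[lips, markers, drop = FALSE]
  hit <- which(!is.na(sub) & abs(sub) > edge_tau_min, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)

  pro_tbl <- clusters[clusters$ome == "protein", ]
  out <- tibble::tibble(
    protein_id = markers[hit[, 2]],
    lipid_id = lips[hit[, 1]],
    tau = sub[hit],
    protein_cluster = pro_tbl$cluster[match(markers[hit[, 2]], pro_tbl$feature_id)],
    lipid_cluster = lip_tbl$cluster[match(lips[hit[, 1]], lip_tbl$feature_id)]
  )
  if (!is.null(species)) {
    out$lipid_class <- species$lipid_class[match(out$lipid_id, species$raw_name)]
  }
  dplyr::arrange(out, dplyr::desc(abs(.data$tau)), .data$protein_id, .data$lipid_id)
}

#' Write a bipartite network as GraphML
#'
#' @param edges Edge tibble from [extract_network()].
#' @param path Output path (`.graphml`).
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(edges, path) {
  nodes <- tibble::tibble(
    name = c(unique(edges$protein_id), unique(edges$lipid_id)),
    type = c(rep("protein", length(unique(edges$protein_id))),
             rep("lipid", length(unique(edges$lipid_id))))
  )
  g <- igraph::graph_from_data_frame(
    edges[c("protein_id", "lipid_id", "tau")],
    directed = FALSE, vertices = nodes
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Lipid-class rank and chain-length summary
#'
#' Ranks lipids by log2 fold change (ascending, mid-rank ties) and
#' summarises each lipid class: median log2 FC, median percentile rank, and
#' median log2 FC split into short chains (`total_carbons < carbon_cutoff`)
#' versus long chains. Species with unknown carbon totals are excluded from
#' the chain split and counted in `n_unknown_carbons`.
#'
#' @param log2fc Tibble with columns `lipid_id` and `log2fc` (one value per
#'   lipid, e.g. one genotype's fold changes).
#' @param species Parsed species tibble from [parse_lipid_names()] covering
#'   the lipids.
#' @param carbon_cutoff Chain-length cutoff in carbons (default 20).
#' @return A tibble with one row per class present: `lipid_class`, `n`,
#'   `median_log2fc`, `median_percentile`, `median_log2fc_short`,
#'   `median_log2fc_long`, `n_short`, `n_long`, `n_unknown_carbons`.
#' @export
class_chain_summary <- function(log2fc, species, carbon_cutoff = 20) {
  stopifnot(is.data.frame(log2fc),
            all(c("lipid_id", "log2fc") %in% names(log2fc)))
  missing_sp <- setdiff(log2fc$lipid_id, species$raw_name)
  if (length(missing_sp) > 0) {
    stop("no parsed species for lipid(s), e.g. ", missing_sp[1])
  }
  df <- log2fc[!is.na(log2fc$log2fc), ]
  idx <- match(df$lipid_id, species$raw_name)
  df$lipid_class <- species$lipid_class[idx]
  df$total_carbons <- species$total_carbons[idx]
  df$percentile <- rank(df$log2fc, ties.method = "average") / nrow(df)

  df |>
    dplyr::group_by(.data$lipid_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_log2fc = stats::median(.data$log2fc),
      median_percentile = stats::median(.data$percentile),
      median_log2fc_short = stats::median(
        .data$log2fc[!is.na(.data$total_carbons) & .data$total_carbons < carbon_cutoff]),
      median_log2fc_long = stats::median(
        .data$log2fc[!is.na(.data$total_carbons) & .data$total_carbons >= carbon_cutoff]),
      n_short = sum(!is.na(.data$total_carbons) & .data$total_carbons < carbon_cutoff),
      n_long = sum(!is.na(.data$total_carbons) & .data$total_carbons >= carbon_cutoff),
      n_unknown_carbons = sum(is.na(.data$total_carbons)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$median_percentile))
}
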