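#' Cluster both omes of a filtered correlation matrix
#'
#' Each protein's profile is its tau vector over the retained lipids, and
#' vice versa; missing tau is imputed as 0 for clustering distances only
#' (absence of association). Hierarchical average-linkage clustering on
#' Euclidean distances yields the dendrogram leaf order; seeded k-means
#' (25 restarts, best inertia) yields the labels, which are renumbered by
#' the leaf-order position of each cluster's medoid so the output is
#' deterministic given the seed.
#'
#' @param ct A filtered `crossome_tau` (see [degree_filter()]).
#' @param k_protein,k_lipid Number of clusters per ome (defaults 18 and 13).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return A tibble with columns `ome`, `feature_id`, `cluster`,
#'   `leaf_rank` (position in the dendrogram leaf order), of class
#'   `crossome_clusters`.
#' @export
cluster_crossome <- function(ct, k_protein = 18, k_lipid = 13, seed = 1,
                             nstart = 25) {
  stopifnot(inherits(ct, "crossome_tau"))
  tau0 <- ct$tau
  tau0[is.na(tau0)] <- 0
  withr::with_seed(seed, {
    lip <- cluster_one_ome(tau0, k_lipid, nstart)
    pro <- cluster_one_ome(t(tau0), k_protein, nstart)
  })
  out <- dplyr::bind_rows(
    tibble::tibble(ome = "protein", feature_id = ct$protein_ids,
                   cluster = pro$labels, leaf_rank = pro$leaf_rank),
    tibble::tibble(ome = "lipid", feature_id = ct$lipid_ids,
                   cluster = lip$labels, leaf_rank = lip$leaf_rank)
  )
  class(out) <- c("crossome_clusters", class(out))
  out
}

# profiles: features x dims. Returns k-means labels renumbered by the
# leaf-order position of each cluster medoid, plus per-feature leaf rank.
cluster_one_ome <- function(profiles, k, nstart) {
  n <- nrow(profiles)
  if (k > n) stop(sprintf("k = %d exceeds the %d available features", k, n))
  hc <- stats::hclust(stats::dist(profiles), method = "average")
  leaf_rank <- match(seq_len(n), hc$order)
  if (k == 1) {
    return(list(labels = rep(1L, n), leaf_rank = leaf_rank))
  }
  km <- stats::kmeans(profiles, centers = k, nstart = nstart, iter.max = 100)
  medoid_rank <- vapply(seq_len(k), function(c) {
    members <- which(km$cluster == c)
    d2 <- rowSums((profiles[members, , drop = FALSE] -
                     matrix(km$centers[c, ], length(members), ncol(profiles),
                            byrow = TRUE))^2)
    min(leaf_rank[members[d2 == min(d2)]])
  }, numeric(1))
  relabel <- match(seq_len(k), order(medoid_rank))
  list(labels = relabel[km$cluster], leaf_rank = leaf_rank)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to score recovery of planted modules.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return The adjusted Rand index, 1 for identical partitions (up to
#'   relabeling), ~0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
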