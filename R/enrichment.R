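#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule (sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's, within relative tolerance 1e-7),
#' and the sample odds ratio `ad/bc` (`Inf` when `bc = 0` and `ad > 0`).
#'
#' @param a,b,c,d Nonnegative integer counts: in-cluster/in-term,
#'   in-cluster/out-of-term, out-of-cluster/in-term, out/out.
#' @return A one-row tibble with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (sum(counts) == 0) stop("total count must be positive")
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value
  tibble::tibble(odds_ratio = or, p_value = min(p, 1))
}

#' Annotation-term enrichment of feature clusters
#'
#' For every (cluster, term) pair, builds the 2x2 contingency table over the
#' analysis universe and applies Fisher's exact test, with
#' Benjamini-Hochberg q-values computed across all tested pairs at once.
#' Term member sets are intersected with the universe before counting;
#' terms left empty are skipped with one warning. Pairs whose overlap `a`
#' falls below `min_overlap_count` are not tested (and not part of the BH
#' family).
#'
#' @param clusters A cluster assignment tibble with columns `feature_id`
#'   and `cluster` (e.g. one ome of [cluster_crossome()] output).
#' @param terms Annotation tibble: `term_id`, `term_name`, list-column
#'   `features` (see [read_gmt()]).
#' @param universe Character vector of feature ids defining the analysis
#'   population; defaults to the clustered features. Must contain all
#'   clustered features.
#' @param min_overlap_count Minimum in-cluster in-term count `a` for a pair
#'   to be tested (default 2).
#' @return A tibble with one row per tested pair: `cluster`, `term_id`,
#'   `term_name`, counts `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `q_value`.
#' @export
enrich_clusters <- function(clusters, terms, universe = NULL,
                            min_overlap_count = 2) {
  stopifnot(is.data.frame(clusters),
            all(c("feature_id", "cluster") %in% names(clusters)))
  feats <- unique(clusters$feature_id)
  if (is.null(universe)) universe <- feats
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  outside <- setdiff(feats, universe)
  if (length(outside) > 0) {
    stop("universe must contain all clustered features; missing e.g. ", outside[1])
  }
  n_universe <- length(universe)

  term_sets <- purrr::map(terms$features, intersect, y = universe)
  empty <- lengths(term_sets) == 0
  if (any(empty)) {
    warning(sprintf("skipped %d term(s) disjoint from the universe: %s",
                    sum(empty), paste(utils::head(terms$term_id[empty], 5), collapse = ", ")))
  }
  keep_terms <- which(!empty)
  cluster_ids <- sort(unique(clusters$cluster))
  cluster_sets <- purrr::map(cluster_ids,
                             ~ unique(clusters$feature_id[clusters$cluster == .x]))

  rows <- purrr::map(keep_terms, function(t) {
    term_set <- term_sets[[t]]
    purrr::map(seq_along(cluster_ids), function(ci) {
      cset <- cluster_sets[[ci]]
      a <- length(intersect(cset, term_set))
      if (a < min_overlap_count) return(NULL)
      b <- length(cset) - a
      cc <- length(term_set) - a
      d <- n_universe - a - b - cc
      ft <- fisher_exact_2x2(a, b, cc, d)
      tibble::tibble(cluster = cluster_ids[ci],
                     term_id = terms$term_id[t], term_name = terms$term_name[t],
                     a = a, b = b, c = cc, d = d,
                     odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    return(tibble::tibble(cluster = integer(), term_id = character(),
                          term_name = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), odds_ratio = double(),
                          p_value = double(), q_value = double()))
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value)
}

#' Lipid-class enrichment of lipid clusters
#'
#' Treats each parsed lipid class as an annotation term and tests every
#' (cluster, class) pair exactly as [enrich_clusters()] does.
#'
#' @param clusters Lipid cluster assignment tibble (`feature_id`, `cluster`).
#' @param species Parsed species tibble from [parse_lipid_names()]; its
#'   `raw_name` must cover the clustered lipids.
#' @param universe Lipid universe (default: clustered lipids).
#' @param min_overlap_count Minimum overlap to test a pair (default 2).
#' @return As [enrich_clusters()], with lipid classes as `term_id`.
#' @export
enrich_lipid_classes <- function(clusters, species, universe = NULL,
                                 min_overlap_count = 2) {
  stopifnot(all(c("raw_name", "lipid_class") %in% names(species)))
  missing_sp <- setdiff(unique(clusters$feature_id), species$raw_name)
  if (length(missing_sp) > 0) {
    stop("no parsed species for clustered lipid(s), e.g. ", missing_sp[1])
  }
  by_class <- split(species$raw_name, species$lipid_class)
  terms <- tibble::tibble(term_id = names(by_class),
                          term_name = names(by_class),
                          features = unname(purrr::map(by_class, unique)))
  enrich_clusters(clusters, terms, universe = universe,
                  min_overlap_count = min_overlap_count)
}

#' Top correlated proteins per lipid
#'
#' For each lipid, ranks proteins by `|tau|` (missing excluded; ties broken
#' lexicographically by protein id) and keeps the top `n`. Lipids whose tau
#' row is entirely missing are excluded with a warning.
#'
#' @param ct A `crossome_tau` object (typically degree-filtered).
#' @param lipids Lipid ids to rank (default: all lipids in `ct`).
#' @param n Partners kept per lipid (default 10).
#' @return A tibble `lipid_id`, `rank`, `protein_id`, `tau`.
#' @export
top_partners <- function(ct, lipids = NULL, n = 10) {
  stopifnot(inherits(ct, "crossome_tau"), n >= 1)
  if (is.null(lipids)) lipids <- ct$lipid_ids
  unknown <- setdiff(lipids, ct$lipid_ids)
  if (length(unknown) > 0) stop("unknown lipid id(s), e.g. ", unknown[1])

  rows <- purrr::map(lipids, function(l) {
    tau <- ct$tau[l, ]
    ok <- which(!is.na(tau))
    if (length(ok) == 0) return(NULL)
    ord <- ok[order(-abs(tau[ok]), ct$protein_ids[ok])]
    top <- utils::head(ord, n)
    tibble::tibble(lipid_id = l, rank = seq_along(top),
                   protein_id = ct$protein_ids[top], tau = unname(tau[top]))
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning(sprintf("excluded %d lipid(s) with all-missing tau", sum(dropped)))
  }
  dplyr::bind_rows(rows)
}

#' Frequency of proteins among per-lipid top partners
#'
#' Counts, over a set of lipids, how many lipids carry each protein in
#' their top-`n` partner list (see [top_partners()]).
#'
#' @inheritParams top_partners
#' @return A tibble `protein_id`, `n_lipids`, sorted by decreasing count
#'   then protein id.
#' @export
top_partner_frequency <- function(ct, lipids = NULL, n = 10) {
  partners <- top_partners(ct, lipids = lipids, n = n)
  out <- dplyr::count(partners, .data$protein_id, name = "n_lipids")
  dplyr::arrange(out, dplyr::desc(.data$n_lipids), .data$protein_id)
}
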