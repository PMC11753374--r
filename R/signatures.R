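#' Per-genotype summed cluster signatures
#'
#' For every cluster and genotype, de-logs each feature's within-genotype
#' replicate mean (geometric mean on the intensity scale), sums over the
#' cluster's features, and reports the log2 ratio of that sum to the same
#' sum in the control genotype. Features whose mean is missing in either the
#' genotype or the control are dropped pairwise; `n_features` records the
#' count actually used. The control against itself is exactly 0.
#'
#' @param abund Abundance tibble (log2 scale; see [read_abundance()]).
#' @param clusters Cluster assignment tibble with `feature_id` and
#'   `cluster`, e.g. one ome of [cluster_crossome()] output.
#' @param meta Sample metadata tibble (see [read_sample_meta()]).
#' @param control_genotype Name of the control genotype in `meta`.
#' @return A tibble `cluster`, `genotype`, `signature` (log2 FC vs control),
#'   `n_features`. Clusters with no usable feature in a genotype get a
#'   missing signature with a warning.
#' @export
cluster_signature <- function(abund, clusters, meta, control_genotype) {
  m <- abundance_matrix(abund)
  meta <- meta[meta$sample_id %in% colnames(m), ]
  if (!control_genotype %in% meta$genotype) {
    stop("control genotype '", control_genotype, "' not present in meta")
  }
  gm <- genotype_mean_matrix(m, meta)  # features x genotypes, log2 scale
  genotypes <- colnames(gm)
  ctl <- gm[, control_genotype]

  clusters <- clusters[clusters$feature_id %in% rownames(gm), ]
  cluster_ids <- sort(unique(clusters$cluster))
  rows <- purrr::map(cluster_ids, function(cl) {
    feats <- clusters$feature_id[clusters$cluster == cl]
    purrr::map(genotypes, function(g) {
      usable <- feats[!is.na(gm[feats, g]) & !is.na(ctl[feats])]
      if (length(usable) == 0) {
        return(tibble::tibble(cluster = cl, genotype = g,
                              signature = NA_real_, n_features = 0L))
      }
      sig <- log2(sum(2^gm[usable, g]) / sum(2^ctl[usable]))
      tibble::tibble(cluster = cl, genotype = g,
                     signature = sig, n_features = length(usable))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (any(is.na(out$signature))) {
    warning(sprintf("%d cluster x genotype combination(s) had no usable features",
                    sum(is.na(out$signature))))
  }
  out
}

#' Per-genotype log2 fold change against a control
#'
#' Within-genotype replicate means of the log2 values, minus the control
#' genotype's mean, per feature.
#'
#' @inheritParams cluster_signature
#' @return A tibble `genotype`, `feature_id`, `log2fc` (control rows are 0
#'   wherever the control mean is defined).
#' @export
genotype_log2fc <- function(abund, meta, control_genotype) {
  m <- abundance_matrix(abund)
  meta <- meta[meta$sample_id %in% colnames(m), ]
  if (!control_genotype %in% meta$genotype) {
    stop("control genotype '", control_genotype, "' not present in meta")
  }
  gm <- genotype_mean_matrix(m, meta)
  fc <- gm - gm[, control_genotype]
  tibble::tibble(
    genotype = rep(colnames(fc), each = nrow(fc)),
    feature_id = rep(rownames(fc), times = ncol(fc)),
    log2fc = as.vector(fc)
  )
}

#' K-means fingerprinting on a curated annotation panel
#'
#' Restricts a genotype-by-feature log2 fold-change matrix to a curated
#' panel of annotated features (e.g. organelle marker sets), computes the
#' per-genotype mean log2 FC of every annotation group, and k-means
#' clusters both the genotypes and the panel features with a fixed seed.
#' Cluster ids are renumbered by first appearance in input order so output
#' is deterministic given the seed.
#'
#' @param log2fc Tibble from [genotype_log2fc()] (columns `genotype`,
#'   `feature_id`, `log2fc`), or a genotype-by-feature numeric matrix.
#' @param panel Annotation tibble (`term_id`, `term_name`, list-column
#'   `features`); groups define the panel and the group means.
#' @param k_genotype,k_feature Cluster counts for genotypes and features.
#' @param seed Integer seed.
#' @param nstart k-means restarts (default 25).
#' @return A list: `genotype_clusters` (tibble `genotype`, `cluster`),
#'   `feature_clusters` (tibble `feature_id`, `cluster`), and `group_means`
#'   (tibble, one row per genotype, one column per annotation group).
#' @export
organelle_panel_kmeans <- function(log2fc, panel, k_genotype, k_feature,
                                   seed = 1, nstart = 25) {
  m <- l2fc_matrix(log2fc)  # genotypes x features
  panel_feats <- intersect(unique(unlist(panel$features)), colnames(m))
  if (length(panel_feats) == 0) stop("no panel features present in the matrix")
  m <- m[, panel_feats, drop = FALSE]
  if (k_genotype > nrow(m)) stop("k_genotype exceeds the number of genotypes")
  if (k_feature > ncol(m)) stop("k_feature exceeds the number of panel features")

  means <- vapply(panel$features, function(f) {
    f <- intersect(f, colnames(m))
    if (length(f) == 0) return(rep(NA_real_, nrow(m)))
    rowMeans(m[, f, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  colnames(means) <- panel$term_id
  group_means <- dplyr::bind_cols(tibble::tibble(genotype = rownames(m)),
                                  tibble::as_tibble(means))

  m0 <- m
  m0[is.na(m0)] <- 0
  withr::with_seed(seed, {
    gk <- stats::kmeans(m0, centers = k_genotype, nstart = nstart, iter.max = 100)
    fk <- stats::kmeans(t(m0), centers = k_feature, nstart = nstart, iter.max = 100)
  })
  list(
    genotype_clusters = tibble::tibble(genotype = rownames(m),
                                       cluster = relabel_by_first(gk$cluster)),
    feature_clusters = tibble::tibble(feature_id = colnames(m),
                                      cluster = relabel_by_first(fk$cluster)),
    group_means = group_means
  )
}

l2fc_matrix <- function(log2fc) {
  if (is.matrix(log2fc)) {
    stopifnot(!is.null(rownames(log2fc)), !is.null(colnames(log2fc)))
    return(log2fc)
  }
  stopifnot(all(c("genotype", "feature_id", "log2fc") %in% names(log2fc)))
  wide <- tidyr::pivot_wider(log2fc, names_from = "feature_id",
                             values_from = "log2fc")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$genotype
  m
}

relabel_by_first <- function(labels) {
  match(labels, unique(labels))
}

#' Robust-z outlier detection across genotypes
#'
#' For each feature's per-genotype summary values, computes the robust
#' z-score `(value - median) / (1.4826 * MAD)` across all genotypes and
#' flags `|z| >= z_threshold`. A MAD of zero is floored at `mad_floor`
#' (with a warning), so constant vectors give z = 0 everywhere.
#'
#' @param values Tibble with columns `genotype` and `value`, optionally
#'   `feature_id` to process many features at once.
#' @param z_threshold Outlier threshold on `|robust_z|` (default 2.5).
#' @param mad_floor Lower bound on the scaled MAD (default 1e-9).
#' @return A tibble `feature_id` (if given), `genotype`, `value`,
#'   `robust_z`, `is_outlier`.
#' @export
detect_outliers <- function(values, z_threshold = 2.5, mad_floor = 1e-9) {
  stopifnot(is.data.frame(values),
            all(c("genotype", "value") %in% names(values)))
  has_feature <- "feature_id" %in% names(values)
  groups <- if (has_feature) split(values, values$feature_id) else list(values)

  floored <- 0L
  rows <- purrr::map(groups, function(g) {
    v <- g$value
    ok <- !is.na(v)
    if (sum(ok) < 5) {
      stop("need at least 5 genotypes with non-missing summaries")
    }
    med <- stats::median(v[ok])
    s <- stats::mad(v[ok])  # 1.4826 * median absolute deviation
    if (s < mad_floor) {
      floored <<- floored + 1L
      s <- mad_floor
    }
    z <- (v - med) / s
    out <- tibble::tibble(genotype = g$genotype, value = v,
                          robust_z = z, is_outlier = abs(z) >= z_threshold)
    if (has_feature) out <- dplyr::bind_cols(tibble::tibble(feature_id = g$feature_id), out)
    out
  })
  if (floored > 0) {
    warning(sprintf("MAD below %g for %d feature(s); floored", mad_floor, floored))
  }
  dplyr::bind_rows(rows)
}
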