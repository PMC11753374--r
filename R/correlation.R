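#' Kendall tau-b rank correlation
#'
#' Tie-corrected Kendall correlation between two numeric vectors:
#' `tau = (C - D) / sqrt((n0 - n1) (n0 - n2))` with `C`/`D` the concordant
#' and discordant pair counts, `n0 = n(n-1)/2`, and `n1`, `n2` the tie-pair
#' counts in each vector. Positions missing in either vector are dropped
#' first; the result is `NA` when fewer than `min_overlap` complete pairs
#' remain or when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length (before missing-value drop).
#' @param min_overlap Minimum number of complete pairs required.
#' @return A single tau value in `[-1, 1]`, or `NA`.
#' @examples
#' kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 2/3
#' @export
kendall_tau_b <- function(x, y, min_overlap = 2) {
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: x has %d values, y has %d", length(x), length(y)))
  }
  if (min_overlap < 2) min_overlap <- 2
  res <- tau_matrix_cpp(matrix(as.double(x), nrow = 1),
                        matrix(as.double(y), nrow = 1),
                        as.integer(min_overlap))
  res$tau[1, 1]
}

#' All-pairs lipid-protein Kendall correlation
#'
#' Computes the Kendall tau-b between every lipid and every protein across
#' the samples the two tables share, pairwise-complete per feature pair.
#' With `aggregate = "genotype_mean"` the per-genotype means of the log2
#' values replace the replicate-level columns before correlating.
#'
#' @param lipids,proteins Abundance tibbles (see [read_abundance()]).
#' @param min_overlap Minimum complete sample pairs for a defined tau
#'   (default 8; below it tau is reported missing).
#' @param aggregate `"replicate"` (default) correlates replicate-level
#'   columns; `"genotype_mean"` first averages within genotype (requires
#'   `meta`).
#' @param meta Sample metadata tibble, required for `"genotype_mean"`.
#' @return A `crossome_tau` object: list with `tau` (lipid x protein matrix),
#'   `n_pairs` (complete-pair counts), `lipid_ids`, `protein_ids`,
#'   `min_overlap`. Use [tidy()] for a long tibble.
#' @export
cross_correlation <- function(lipids, proteins, min_overlap = 8,
                              aggregate = c("replicate", "genotype_mean"),
                              meta = NULL) {
  aggregate <- match.arg(aggregate)
  L <- abundance_matrix(lipids)
  P <- abundance_matrix(proteins)
  shared <- intersect(colnames(L), colnames(P))
  if (length(shared) == 0) stop("lipid and protein tables share no sample ids")
  L <- L[, shared, drop = FALSE]
  P <- P[, shared, drop = FALSE]

  if (aggregate == "genotype_mean") {
    if (is.null(meta)) stop("meta is required for aggregate = 'genotype_mean'")
    L <- genotype_mean_matrix(L, meta)
    P <- genotype_mean_matrix(P, meta)
  }
  if (ncol(L) < min_overlap) {
    warning(sprintf("only %d shared samples; all tau below min_overlap = %d will be missing",
                    ncol(L), min_overlap))
  }
  res <- tau_matrix_cpp(L, P, as.integer(min_overlap))
  dimnames(res$tau) <- list(rownames(L), rownames(P))
  dimnames(res$n_pairs) <- dimnames(res$tau)
  new_crossome_tau(res$tau, res$n_pairs, min_overlap)
}

new_crossome_tau <- function(tau, n_pairs, min_overlap) {
  structure(
    list(tau = tau, n_pairs = n_pairs,
         lipid_ids = rownames(tau), protein_ids = colnames(tau),
         min_overlap = min_overlap),
    class = "crossome_tau"
  )
}

genotype_mean_matrix <- function(m, meta) {
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (any(is.na(meta$sample_id))) stop("meta is missing sample ids present in the data")
  groups <- split(seq_len(ncol(m)), meta$genotype)
  out <- vapply(groups, function(idx) {
    rowMeans(m[, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  out[is.nan(out)] <- NA_real_
  out
}

#' @export
print.crossome_tau <- function(x, ...) {
  cat(sprintf("<crossome_tau> %d lipids x %d proteins; %d/%d tau defined (min_overlap = %d)\n",
              length(x$lipid_ids), length(x$protein_ids),
              sum(!is.na(x$tau)), length(x$tau), x$min_overlap))
  invisible(x)
}

#' Tidy a cross-ome correlation matrix
#'
#' @param x A `crossome_tau` object.
#' @param ... Unused.
#' @return A long tibble with `lipid_id`, `protein_id`, `tau`, `n_pairs`.
#' @method tidy crossome_tau
#' @export
tidy.crossome_tau <- function(x, ...) {
  tibble::tibble(
    lipid_id = rep(x$lipid_ids, times = length(x$protein_ids)),
    protein_id = rep(x$protein_ids, each = length(x$lipid_ids)),
    tau = as.vector(x$tau),
    n_pairs = as.vector(x$n_pairs)
  )
}

#' One-row summary of a cross-ome correlation matrix
#'
#' @param x A `crossome_tau` object.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, defined fraction, median |tau|.
#' @method glance crossome_tau
#' @export
glance.crossome_tau <- function(x, ...) {
  tibble::tibble(
    n_lipids = length(x$lipid_ids),
    n_proteins = length(x$protein_ids),
    n_defined = sum(!is.na(x$tau)),
    frac_defined = mean(!is.na(x$tau)),
    median_abs_tau = stats::median(abs(x$tau), na.rm = TRUE),
    min_overlap = x$min_overlap
  )
}

#' Cross-ome degree filter
#'
#' Retains a lipid only if at least `min_partners` proteins correlate with
#' it at `|tau| > tau_min` in the full matrix, and symmetrically for
#' proteins. Both criteria are evaluated on the full matrix and applied
#' simultaneously in a single pass; there is no iterative re-filtering.
#'
#' @param ct A `crossome_tau` object.
#' @param tau_min Absolute-tau threshold, strict inequality (default 0.4).
#' @param min_partners Minimum super-threshold partners (default 2).
#' @return A filtered `crossome_tau` with attributes `retained_lipids` and
#'   `retained_proteins`. An empty retained set on either ome gives a
#'   structured empty result with a warning.
#' @export
degree_filter <- function(ct, tau_min = 0.4, min_partners = 2) {
  stopifnot(inherits(ct, "crossome_tau"))
  if (!(tau_min > 0 && tau_min < 1)) stop("tau_min must be in (0, 1)")
  if (min_partners < 1) stop("min_partners must be >= 1")
  hits <- !is.na(ct$tau) & abs(ct$tau) > tau_min
  keep_l <- rowSums(hits) >= min_partners
  keep_p <- colSums(hits) >= min_partners
  if (!any(keep_l) || !any(keep_p)) {
    warning("degree filter retained no features on at least one ome")
  }
  out <- new_crossome_tau(ct$tau[keep_l, keep_p, drop = FALSE],
                          ct$n_pairs[keep_l, keep_p, drop = FALSE],
                          ct$min_overlap)
  attr(out, "retained_lipids") <- ct$lipid_ids[keep_l]
  attr(out, "retained_proteins") <- ct$protein_ids[keep_p]
  attr(out, "tau_min") <- tau_min
  attr(out, "min_partners") <- min_partners
  out
}
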