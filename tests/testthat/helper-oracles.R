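# Independent brute-force oracles used to check the implementation.

# Kendall tau-b by explicit enumeration of all pairs
tau_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  conc <- disc <- tx <- ty <- 0
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      dx <- x[a] - x[b]
      dy <- y[a] - y[b]
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
      if (dx != 0 && dy != 0) {
        if (sign(dx) == sign(dy)) conc <- conc + 1 else disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt(n0 - tx) * sqrt(n0 - ty)
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

# two-sided Fisher p by summing hypergeometric probabilities (via choose,
# independent of stats::fisher.test / dhyper) over all tables with the
# observed margins whose probability <= observed (relative tolerance 1e-7)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p0 <- pr[xs == a]
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up, written directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# degree filter by explicit row/column enumeration
degree_filter_oracle <- function(tau, tau_min, min_partners) {
  keep_l <- logical(nrow(tau))
  for (i in seq_len(nrow(tau))) {
    hits <- 0
    for (j in seq_len(ncol(tau))) {
      if (!is.na(tau[i, j]) && abs(tau[i, j]) > tau_min) hits <- hits + 1
    }
    keep_l[i] <- hits >= min_partners
  }
  keep_p <- logical(ncol(tau))
  for (j in seq_len(ncol(tau))) {
    hits <- 0
    for (i in seq_len(nrow(tau))) {
      if (!is.na(tau[i, j]) && abs(tau[i, j]) > tau_min) hits <- hits + 1
    }
    keep_p[j] <- hits >= min_partners
  }
  list(lipids = rownames(tau)[keep_l], proteins = colnames(tau)[keep_p])
}

# wrap a bare tau matrix as the package's container
as_tau_object <- function(tau, min_overlap = 2) {
  n_pairs <- matrix(10L, nrow(tau), ncol(tau), dimnames = dimnames(tau))
  structure(
    list(tau = tau, n_pairs = n_pairs,
         lipid_ids = rownames(tau), protein_ids = colnames(tau),
         min_overlap = min_overlap),
    class = "crossome_tau"
  )
}

# scaled-down simulation preset used across tests
small_sim <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_genotypes = 8, n_replicates = 3, n_proteins = 120, n_lipids = 60,
         n_modules = 3, module_size_protein = 12, module_size_lipid = 6,
         seed = seed),
    list(...)
  )
  do.call(simulate_crossome, args)
}
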