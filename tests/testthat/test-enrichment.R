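test_that("degenerate 2x2 margins force p = 1 and extreme tables match the oracle", {
  expect_equal(fisher_exact_2x2(0, 7, 0, 5)$p_value, 1)
  res <- fisher_exact_2x2(5, 0, 0, 5)
  expect_identical(res$odds_ratio, Inf)
  expect_equal(res$p_value, fisher_oracle(5, 0, 0, 5), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "positive")
})

test_that("two-sided p matches the hypergeometric tail-sum oracle on random tables", {
  withr::local_seed(20)
  for (i in 1:100) {
    tab <- as.integer(sample(0:12, 4, replace = TRUE))
    if (sum(tab) == 0) tab[1] <- 1L
    got <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])$p_value
    expect_equal(got, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
  }
})

test_that("Fisher p is symmetric under transpose and row/column swaps", {
  withr::local_seed(21)
  for (i in 1:20) {
    t <- sample(0:10, 4, replace = TRUE)
    p <- fisher_exact_2x2(t[1], t[2], t[3], t[4])$p_value
    expect_equal(fisher_exact_2x2(t[1], t[3], t[2], t[4])$p_value, p)  # transpose
    expect_equal(fisher_exact_2x2(t[4], t[3], t[2], t[1])$p_value, p)  # both swaps
  }
})

test_that("sample odds ratio is ad/bc with the documented edge cases", {
  expect_equal(fisher_exact_2x2(4, 2, 1, 3)$odds_ratio, 6)
  expect_equal(fisher_exact_2x2(0, 2, 3, 4)$odds_ratio, 0)
  expect_true(is.nan(fisher_exact_2x2(0, 0, 3, 4)$odds_ratio))
})

test_that("BH q-values equal the step-up definition", {
  withr::local_seed(22)
  p <- runif(40)^2
  clusters <- tibble::tibble(feature_id = sprintf("F%02d", 1:40),
                             cluster = rep(1:4, each = 10))
  terms <- tibble::tibble(
    term_id = sprintf("T%02d", 1:12), term_name = sprintf("T%02d", 1:12),
    features = purrr::map(1:12, ~ sample(clusters$feature_id, 12))
  )
  res <- enrich_clusters(clusters, terms, min_overlap_count = 1)
  expect_equal(res$q_value, bh_oracle(res$p_value), tolerance = 1e-12)
  # step-up property: q is nondecreasing in ranked p
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
})

test_that("cluster-term counts honour the margin identities", {
  clusters <- tibble::tibble(feature_id = sprintf("F%02d", 1:30),
                             cluster = rep(1:3, each = 10))
  terms <- tibble::tibble(term_id = c("A", "B"), term_name = c("A", "B"),
                          features = list(sprintf("F%02d", 1:10),
                                          sprintf("F%02d", 8:20)))
  universe <- sprintf("F%02d", 1:40)
  res <- enrich_clusters(clusters, terms, universe = universe,
                         min_overlap_count = 1)
  expect_true(all(res$a + res$b + res$c + res$d == 40))
  expect_true(all(res$a + res$b == 10))  # cluster size
  # a cluster identical to a term: a = cluster size, b = 0, smallest p
  row <- res[res$cluster == 1 & res$term_id == "A", ]
  expect_equal(row$a, 10L)
  expect_equal(row$b, 0L)
  expect_equal(min(res$p_value), row$p_value)
})

test_that("terms outside the universe are skipped and bad input is an error", {
  clusters <- tibble::tibble(feature_id = c("F1", "F2"), cluster = c(1L, 1L))
  terms <- tibble::tibble(term_id = c("in", "out"), term_name = c("in", "out"),
                          features = list(c("F1", "F2"), c("X1", "X2")))
  expect_warning(res <- enrich_clusters(clusters, terms, min_overlap_count = 1),
                 "disjoint")
  expect_setequal(res$term_id, "in")
  expect_error(enrich_clusters(clusters, terms, universe = character(0)), "empty universe")
  expect_error(enrich_clusters(clusters, terms, universe = "F1"), "must contain")
})

test_that("lipid-class enrichment treats classes as terms", {
  species <- parse_lipid_names(c(sprintf("LPC %d:1", 14:23), sprintf("TG 5%d:2", 0:9)))
  clusters <- tibble::tibble(feature_id = species$raw_name,
                             cluster = rep(1:2, each = 10))
  res <- enrich_lipid_classes(clusters, species, min_overlap_count = 1)
  expect_true(all(res$a + res$b + res$c + res$d == 20))
  lpc <- res[res$cluster == 1 & res$term_id == "LPC", ]
  expect_equal(lpc$a, 10L)
  expect_equal(lpc$b, 0L)
  # a single-member class is only tested when the overlap floor allows it
  sp2 <- parse_lipid_names(c(sprintf("LPC %d:1", 14:18), "CE 16:0"))
  cl2 <- tibble::tibble(feature_id = sp2$raw_name, cluster = rep(1:2, c(5, 1)))
  res_floor2 <- enrich_lipid_classes(cl2, sp2, min_overlap_count = 2)
  expect_false("CE" %in% res_floor2$term_id)
  res_floor1 <- enrich_lipid_classes(cl2, sp2, min_overlap_count = 1)
  expect_true("CE" %in% res_floor1$term_id)
})

test_that("top partners are the largest-|tau| proteins with deterministic ties", {
  tau <- matrix(c(0.9, -0.8, 0.1, 0.5, 0.5, NA), 1, 6,
                dimnames = list("L1", paste0("P", 1:6)))
  ct <- as_tau_object(tau)
  top <- top_partners(ct, n = 3)
  expect_equal(top$protein_id, c("P1", "P2", "P4"))  # P4 before P5 on the tie
  expect_equal(top$rank, 1:3)
  expect_equal(top$tau, c(0.9, -0.8, 0.5))
})

test_that("top-partner ranking equals a brute-force sort on random matrices", {
  withr::local_seed(23)
  tau <- matrix(runif(15 * 30, -1, 1), 15, 30,
                dimnames = list(paste0("L", 1:15), paste0("P", 1:30)))
  tau[sample(length(tau), 40)] <- NA
  ct <- as_tau_object(tau)
  top <- top_partners(ct, n = 5)
  for (l in rownames(tau)) {
    row <- tau[l, !is.na(tau[l, ])]
    want <- names(row)[order(-abs(row), names(row))][1:5]
    expect_equal(top$protein_id[top$lipid_id == l], want)
  }
  # frequency totals: |lipids| x n minus exclusions (none here)
  freq <- top_partner_frequency(ct, n = 5)
  expect_equal(sum(freq$n_lipids), 15L * 5L)
})

test_that("lipids with all-missing tau are excluded with a warning", {
  tau <- matrix(c(0.5, 0.2, NA, NA), 2, 2, byrow = TRUE,
                dimnames = list(c("L1", "L2"), c("P1", "P2")))
  expect_warning(top <- top_partners(as_tau_object(tau), n = 2), "all-missing")
  expect_setequal(top$lipid_id, "L1")
  expect_error(top_partners(as_tau_object(tau), lipids = "nope"), "unknown lipid")
})

test_that("permuted labels keep the q < 0.05 call rate at the nominal level", {
  # small permutation null: planted structure destroyed by relabeling
  withr::local_seed(24)
  feats <- sprintf("F%03d", 1:150)
  terms <- tibble::tibble(
    term_id = sprintf("T%02d", 1:10), term_name = sprintf("T%02d", 1:10),
    features = purrr::map(1:10, ~ sample(feats, 20))
  )
  frac <- replicate(50, {
    cl <- tibble::tibble(feature_id = feats,
                         cluster = sample(rep(1:5, each = 30)))
    res <- enrich_clusters(cl, terms)
    if (nrow(res) == 0) 0 else mean(res$q_value < 0.05)
  })
  expect_lte(mean(frac), 0.05)
})
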