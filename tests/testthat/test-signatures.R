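toy_abundance <- function() {
  # 4 features x (2 genotypes x 2 replicates), log2 scale
  m <- matrix(10, 4, 4,
              dimnames = list(paste0("F", 1:4),
                              c("ctl_r1", "ctl_r2", "ko_r1", "ko_r2")))
  m[1:2, 3:4] <- 11  # cluster 1 features doubled in KO
  as_abundance(m, "protein")
}

toy_meta <- function() {
  tibble::tibble(sample_id = c("ctl_r1", "ctl_r2", "ko_r1", "ko_r2"),
                 genotype = rep(c("control", "KO"), each = 2),
                 condition = "fed", replicate = rep(1:2, 2))
}

toy_clusters <- function() {
  tibble::tibble(feature_id = paste0("F", 1:4), cluster = rep(1:2, each = 2))
}

test_that("control vs itself is exactly 0 and doubling gives signature 1", {
  sig <- cluster_signature(toy_abundance(), toy_clusters(), toy_meta(), "control")
  ctl <- sig[sig$genotype == "control", ]
  expect_true(all(ctl$signature == 0))
  expect_equal(sig$signature[sig$cluster == 1 & sig$genotype == "KO"], 1)
  expect_equal(sig$signature[sig$cluster == 2 & sig$genotype == "KO"], 0)
  expect_true(all(sig$n_features == 2L))
})

test_that("features missing in either genotype are dropped pairwise", {
  ab <- toy_abundance()
  m <- abundance_matrix(ab)
  m["F1", c("ko_r1", "ko_r2")] <- NA  # F1 unusable for KO
  sig <- cluster_signature(as_abundance(m, "protein"), toy_clusters(),
                           toy_meta(), "control")
  ko1 <- sig[sig$cluster == 1 & sig$genotype == "KO", ]
  expect_equal(ko1$n_features, 1L)
  expect_equal(ko1$signature, 1)
  # a cluster with no usable features gives a missing signature + warning
  m2 <- abundance_matrix(toy_abundance())
  m2[3:4, 3:4] <- NA
  expect_warning(
    sig2 <- cluster_signature(as_abundance(m2, "protein"), toy_clusters(),
                              toy_meta(), "control"),
    "no usable"
  )
  expect_true(is.na(sig2$signature[sig2$cluster == 2 & sig2$genotype == "KO"]))
})

test_that("signatures ignore feature order and global intensity scaling", {
  ab <- toy_abundance()
  sig <- cluster_signature(ab, toy_clusters(), toy_meta(), "control")
  perm <- toy_clusters()[c(3, 1, 4, 2), ]
  sig_perm <- cluster_signature(ab, perm, toy_meta(), "control")
  expect_equal(sig, sig_perm)
  scaled <- as_abundance(abundance_matrix(ab) + log2(7), "protein")
  sig_scaled <- cluster_signature(scaled, toy_clusters(), toy_meta(), "control")
  expect_equal(sig$signature, sig_scaled$signature)
  expect_error(cluster_signature(ab, toy_clusters(), toy_meta(), "absent"),
               "not present")
})

test_that("a planted module effect is recovered by the summed signature", {
  sim <- small_sim(seed = 41, n_genotypes = 10, missing_rate = 0)
  truth <- sim$truth$features
  clusters <- truth[truth$ome == "protein" & truth$module > 0,
                    c("feature_id", "module")]
  names(clusters)[2] <- "cluster"
  sig <- cluster_signature(sim$proteins, clusters, sim$meta, "control")
  hits <- purrr::imap(sim$truth$affected_map, function(gts, m) {
    sig$signature[sig$cluster == as.integer(m) & sig$genotype %in% gts]
  })
  expect_equal(mean(unlist(hits)), 1, tolerance = 0.5)
})

test_that("genotype log2 fold changes difference the genotype means", {
  fc <- genotype_log2fc(toy_abundance(), toy_meta(), "control")
  expect_equal(fc$log2fc[fc$genotype == "KO" & fc$feature_id == "F1"], 1)
  expect_equal(fc$log2fc[fc$genotype == "KO" & fc$feature_id == "F3"], 0)
  expect_true(all(fc$log2fc[fc$genotype == "control"] == 0))
})

test_that("panel k-means splits opposite genotype groups perfectly", {
  genotypes <- sprintf("G%02d", 1:8)
  feats <- sprintf("F%02d", 1:12)
  # first genotype half up, second half down, with per-feature magnitudes
  # so feature profiles are distinct
  m <- outer(c(rep(2, 4), rep(-2, 4)), seq(0.5, 1.6, length.out = 12))
  dimnames(m) <- list(genotypes, feats)
  panel <- tibble::tibble(term_id = c("grpA", "grpB"),
                          term_name = c("grpA", "grpB"),
                          features = list(feats[1:6], feats[7:12]))
  res <- organelle_panel_kmeans(m, panel, k_genotype = 2, k_feature = 2, seed = 3)
  expect_equal(adjusted_rand_index(res$genotype_clusters$cluster,
                                   rep(1:2, each = 4)), 1)
  expect_equal(dim(res$group_means), c(8L, 3L))
  expect_equal(res$group_means$grpA, unname(rowMeans(m[, 1:6])))
  expect_setequal(res$feature_clusters$cluster, 1:2)
  # one annotation group -> one mean column
  res1 <- organelle_panel_kmeans(m, panel[1, ], k_genotype = 2, k_feature = 2,
                                 seed = 3)
  expect_equal(names(res1$group_means), c("genotype", "grpA"))
  expect_error(organelle_panel_kmeans(m, panel, k_genotype = 9, k_feature = 2,
                                      seed = 3), "k_genotype")
})

test_that("robust z flags planted outliers and guards constant vectors", {
  vals <- tibble::tibble(genotype = sprintf("G%02d", 1:11),
                         value = c(seq(-0.5, 0.5, length.out = 10), 10))
  out <- detect_outliers(vals, z_threshold = 2.5)
  expect_warning(detect_outliers(tibble::tibble(genotype = sprintf("G%d", 1:6),
                                                value = rep(1, 6))),
                 "floored")
  expect_true(out$is_outlier[out$genotype == "G11"])
  expect_false(any(out$is_outlier[out$genotype != "G11"]))
  constant <- suppressWarnings(
    detect_outliers(tibble::tibble(genotype = sprintf("G%d", 1:6), value = rep(1, 6)))
  )
  expect_true(all(constant$robust_z == 0))
  expect_false(any(constant$is_outlier))
  expect_error(detect_outliers(tibble::tibble(genotype = c("a", "b"), value = 1:2)),
               "at least 5")
})

test_that("robust z is equivariant under constant shifts and grouped by feature", {
  withr::local_seed(51)
  v <- rnorm(12)
  base <- detect_outliers(tibble::tibble(genotype = sprintf("G%02d", 1:12), value = v))
  shifted <- detect_outliers(tibble::tibble(genotype = sprintf("G%02d", 1:12),
                                            value = v + 100))
  expect_equal(base$robust_z, shifted$robust_z, tolerance = 1e-12)
  two <- tibble::tibble(feature_id = rep(c("A", "B"), each = 12),
                        genotype = rep(sprintf("G%02d", 1:12), 2),
                        value = c(v, v * 3 + 5))
  res <- detect_outliers(two)
  expect_equal(res$robust_z[res$feature_id == "A"],
               res$robust_z[res$feature_id == "B"], tolerance = 1e-12)
})

test_that("network extraction matches a brute-force scan and honours thresholds", {
  withr::local_seed(52)
  tau <- matrix(runif(8 * 10, -1, 1), 8, 10,
                dimnames = list(paste0("L", 1:8), paste0("P", 1:10)))
  tau[sample(length(tau), 10)] <- NA
  ct <- as_tau_object(tau)
  clusters <- dplyr::bind_rows(
    tibble::tibble(ome = "protein", feature_id = paste0("P", 1:10),
                   cluster = rep(1:2, 5), leaf_rank = 1:10),
    tibble::tibble(ome = "lipid", feature_id = paste0("L", 1:8),
                   cluster = rep(1:2, 4), leaf_rank = 1:8)
  )
  markers <- c("P1", "P2", "P3")
  net <- extract_network(ct, markers, lipid_clusters = 1, clusters,
                         edge_tau_min = 0.3)
  lips <- paste0("L", seq(1, 8, by = 2))
  want <- 0L
  for (p in markers) for (l in lips) {
    t <- tau[l, p]
    if (!is.na(t) && abs(t) > 0.3) {
      want <- want + 1L
      expect_true(any(net$protein_id == p & net$lipid_id == l))
    }
  }
  expect_equal(nrow(net), want)
  # threshold 0: every defined entry of the submatrix is an edge
  net0 <- extract_network(ct, markers, 1, clusters, edge_tau_min = 0)
  expect_equal(nrow(net0), sum(!is.na(tau[lips, markers]) & tau[lips, markers] != 0))
  expect_warning(extract_network(ct, c("P1", "NOPE"), 1, clusters), "unknown marker")
})

test_that("network edges live inside the degree-filtered support", {
  sim <- small_sim(seed = 53)
  ct <- cross_correlation(sim$lipids, sim$proteins)
  f <- degree_filter(ct, tau_min = 0.4, min_partners = 2)
  cl <- cluster_crossome(f, k_protein = 3, k_lipid = 3, seed = 2)
  net <- extract_network(f, attr(f, "retained_proteins"), 1:3, cl,
                         edge_tau_min = 0.5)
  if (nrow(net) > 0) {
    expect_true(all(net$protein_id %in% attr(f, "retained_proteins")))
    expect_true(all(net$lipid_id %in% attr(f, "retained_lipids")))
    expect_true(all(abs(net$tau) > 0.5))
  }
  path <- withr::local_tempfile(fileext = ".graphml")
  top <- extract_network(f, attr(f, "retained_proteins"), 1:3, cl, 0.4)
  write_network_graphml(top, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(top))
})

test_that("class summaries rank classes and split chains at the carbon cutoff", {
  species <- parse_lipid_names(c(sprintf("CE %d:0", 14:18),
                                 sprintf("CE %d:0", 20:24),
                                 sprintf("PC %d:1", 21:110)))
  # 10 CE species occupy the top 10% of 100 ranks; short CE above long CE
  fc <- tibble::tibble(
    lipid_id = species$raw_name,
    log2fc = c(seq(3, 4, length.out = 5),    # short-chain CE, highest
               seq(2, 2.8, length.out = 5),  # long-chain CE
               seq(-1, 0.8, length.out = 90))
  )
  res <- class_chain_summary(fc, species, carbon_cutoff = 20)
  ce <- res[res$lipid_class == "CE", ]
  expect_gte(ce$median_percentile, 0.9)
  expect_gt(ce$median_log2fc_short, ce$median_log2fc_long)
  expect_equal(ce$n_short, 5L)
  expect_equal(ce$n_long, 5L)

  # all-zero fold changes: every class sits at the mid-rank
  fc0 <- tibble::tibble(lipid_id = species$raw_name, log2fc = 0)
  res0 <- class_chain_summary(fc0, species)
  expect_true(all(abs(res0$median_percentile - 0.5) < 0.05))
})

test_that("species with unknown carbons are excluded from the chain split", {
  species <- suppressWarnings(
    parse_lipid_names(c("CE 16:0", "CE 24:0", "CholesterylWeird"))
  )
  fc <- tibble::tibble(lipid_id = species$raw_name, log2fc = c(1, 2, 3))
  res <- class_chain_summary(fc, species, carbon_cutoff = 20)
  ce <- res[res$lipid_class == "CE", ]
  expect_equal(ce$n_unknown_carbons, 0L)
  other <- res[res$lipid_class == "CholesterylWeird", ]
  expect_equal(other$n_unknown_carbons, 1L)
  expect_equal(other$n_short + other$n_long, 0L)
})
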