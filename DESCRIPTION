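Package: crossome
Title: Cross-Ome Lipid-Protein Correlation Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fingerprinting panels of mutant cell lines by
    correlating lipidomes against proteomes. Computes all-pairs Kendall
    tau-b association matrices across shared samples with pairwise-complete
    handling of missing intensities, applies a cross-ome degree filter,
    clusters both omes (hierarchical leaf ordering plus seeded k-means),
    tests protein clusters for annotation-term enrichment and lipid
    clusters for lipid-class enrichment with Fisher's exact test and
    Benjamini-Hochberg control, derives per-genotype summed-cluster
    log2 fold-change signatures against a control line, extracts bipartite
    marker networks, flags outlier genotypes with robust z-scores, and
    summarises lipid classes by chain length. Ships a seeded synthetic
    multi-omics generator with planted cross-ome modules that provides
    ground truth for every pipeline stage, plus lipid shorthand name
    parsing and readers/writers for delimited abundance matrices, sample
    metadata, and GMT annotation files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
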