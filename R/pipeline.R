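#' Default pipeline configuration
#'
#' Thresholds mirror the analysis defaults: `|tau| > 0.4` with at least 2
#' cross-ome partners, 8 complete pairs per defined tau, 18 protein and 13
#' lipid clusters, robust-z threshold 2.5, chain-length cutoff 20 carbons,
#' BH alpha 0.05, top-10 partners.
#'
#' @return A named list of defaults, ready to edit and pass to
#'   [run_pipeline()].
#' @export
pipeline_config <- function() {
  list(
    seed = 17,
    tau_min = 0.4, min_partners = 2, min_overlap = 8,
    k_protein = 18, k_lipid = 13,
    control_genotype = "control",
    z_threshold = 2.5, carbon_cutoff = 20, alpha = 0.05, top_n = 10,
    aggregate = "replicate",
    simulate = NULL,  # list of simulate_crossome() args, or NULL
    inputs = NULL     # list(lipids=, proteins=, meta=, gmt=) of file paths
  )
}

#' Read / write a pipeline configuration
#'
#' YAML round trip: unspecified fields take [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config()`, a full config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(user)
  validate_config(cfg)
  cfg
}

# modifyList drops NULL-valued entries; keep the optional input slots
merge_config <- function(user) {
  cfg <- utils::modifyList(pipeline_config(), user)
  for (k in c("simulate", "inputs")) {
    if (!k %in% names(cfg)) cfg[k] <- list(NULL)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param cfg A config list.
#' @return For `write_pipeline_config()`, `path` invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(cfg$tau_min > 0, cfg$tau_min < 1,
            cfg$min_partners >= 1, cfg$min_overlap >= 2,
            cfg$k_protein >= 1, cfg$k_lipid >= 1,
            cfg$z_threshold > 0, cfg$carbon_cutoff > 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$top_n >= 1)
  invisible(cfg)
}

#' Run the full cross-ome fingerprinting pipeline
#'
#' Loads (or simulates) the paired abundance tables, computes the
#' lipid-protein Kendall matrix, applies the degree filter, clusters both
#' omes, runs annotation-term and lipid-class enrichment, derives summed
#' cluster signatures for both omes, ranks top partners, flags outlier
#' genotypes per retained lipid, and writes every stage's table plus a
#' run manifest to `out_dir`. Any stage failure aborts with the stage name.
#'
#' @param cfg Config list (see [pipeline_config()]) or path to a YAML file.
#'   Exactly one of `cfg$simulate` (arguments to [simulate_crossome()]) or
#'   `cfg$inputs` (paths: `lipids`, `proteins`, `meta`, `gmt`) must be set.
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest list, invisibly: stages with feature counts, input
#'   hashes, output paths, package version, and seed.
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  cfg <- merge_config(cfg)
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  manifest <- list(package = "crossome",
                   version = as.character(utils::packageVersion("crossome")),
                   seed = cfg$seed, config = cfg[setdiff(names(cfg), c("simulate", "inputs"))],
                   stages = list(), outputs = character(), input_hashes = list())
  out <- function(name) file.path(out_dir, name)
  emit <- function(tbl, name) {
    readr::write_tsv(tbl, out(name))
    manifest$outputs <<- c(manifest$outputs, out(name))
  }

  # -- load or simulate ------------------------------------------------
  dat <- stage("load", {
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      if (is.null(args$seed)) args$seed <- cfg$seed
      do.call(simulate_crossome, args)
    } else if (!is.null(cfg$inputs)) {
      paths <- cfg$inputs
      need <- c("lipids", "proteins", "meta")
      missing_in <- setdiff(need, names(paths))
      if (length(missing_in) > 0) stop("inputs must name: ", paste(missing_in, collapse = ", "))
      absent <- unlist(paths)[!file.exists(unlist(paths))]
      if (length(absent) > 0) stop("missing input file: ", absent[1])
      manifest$input_hashes <- as.list(tools::md5sum(unlist(paths)))
      lipids <- read_abundance(paths$lipids, ome = "lipid")
      list(lipids = lipids,
           proteins = read_abundance(paths$proteins, ome = "protein"),
           meta = read_sample_meta(paths$meta),
           terms = if (!is.null(paths$gmt)) read_gmt(paths$gmt) else NULL,
           species = parse_lipid_names(lipids$feature_id))
    } else {
      stop("config must set either 'simulate' or 'inputs'")
    }
  })
  if (!"raw_name" %in% names(dat$species)) {
    dat$species <- dplyr::rename(dat$species, raw_name = "name")
  }
  n_prot <- nrow(dat$proteins); n_lip <- nrow(dat$lipids)
  say("loaded: %d proteins, %d lipids, %d samples", n_prot, n_lip, nrow(dat$meta))
  manifest$stages$load <- list(n_proteins = n_prot, n_lipids = n_lip,
                               n_samples = nrow(dat$meta))

  # -- correlate -------------------------------------------------------
  ct <- stage("correlate", cross_correlation(
    dat$lipids, dat$proteins, min_overlap = cfg$min_overlap,
    aggregate = cfg$aggregate, meta = dat$meta))
  say("correlated: %d x %d tau matrix", n_lip, n_prot)
  manifest$stages$correlate <- as.list(glance(ct))

  # -- filter ----------------------------------------------------------
  fct <- stage("filter", degree_filter(ct, tau_min = cfg$tau_min,
                                       min_partners = cfg$min_partners))
  ret_l <- attr(fct, "retained_lipids"); ret_p <- attr(fct, "retained_proteins")
  say("retained: %d lipids, %d proteins (|tau| > %g, >= %d partners)",
      length(ret_l), length(ret_p), cfg$tau_min, cfg$min_partners)
  manifest$stages$filter <- list(n_lipids = length(ret_l), n_proteins = length(ret_p))
  emit(tidy(fct), "tau_filtered.tsv")
  writeLines(ret_l, out("retained_lipids.txt"))
  writeLines(ret_p, out("retained_proteins.txt"))
  manifest$outputs <- c(manifest$outputs, out("retained_lipids.txt"),
                        out("retained_proteins.txt"))

  # -- cluster ---------------------------------------------------------
  clusters <- stage("cluster", cluster_crossome(
    fct, k_protein = cfg$k_protein, k_lipid = cfg$k_lipid, seed = cfg$seed))
  emit(clusters, "clusters.tsv")
  manifest$stages$cluster <- list(k_protein = cfg$k_protein, k_lipid = cfg$k_lipid)

  prot_clusters <- clusters[clusters$ome == "protein", ]
  lip_clusters <- clusters[clusters$ome == "lipid", ]

  # -- enrich ----------------------------------------------------------
  if (!is.null(dat$terms)) {
    enr_p <- stage("enrich_protein", enrich_clusters(
      prot_clusters, dat$terms, universe = ret_p))
    emit(enr_p, "enrichment_protein.tsv")
    manifest$stages$enrich_protein <- list(
      n_tested = nrow(enr_p), n_significant = sum(enr_p$q_value < cfg$alpha))
  }
  enr_l <- stage("enrich_lipid_class", enrich_lipid_classes(
    lip_clusters, dat$species, universe = ret_l))
  emit(enr_l, "enrichment_lipid_class.tsv")
  manifest$stages$enrich_lipid_class <- list(
    n_tested = nrow(enr_l), n_significant = sum(enr_l$q_value < cfg$alpha))

  # -- signatures ------------------------------------------------------
  sig_p <- stage("signature_protein", cluster_signature(
    dat$proteins, prot_clusters, dat$meta, cfg$control_genotype))
  emit(sig_p, "signatures_protein.tsv")
  sig_l <- stage("signature_lipid", cluster_signature(
    dat$lipids, lip_clusters, dat$meta, cfg$control_genotype))
  emit(sig_l, "signatures_lipid.tsv")

  # -- top partners ----------------------------------------------------
  partners <- stage("top_partners", top_partners(fct, n = cfg$top_n))
  emit(partners, "top_partners.tsv")
  freq <- stage("top_partners", top_partner_frequency(fct, n = cfg$top_n))
  emit(freq, "partner_frequency.tsv")

  # -- outliers --------------------------------------------------------
  outliers <- stage("outliers", {
    fc <- genotype_log2fc(dat$lipids, dat$meta, cfg$control_genotype)
    fc <- fc[fc$feature_id %in% ret_l, ]
    vals <- dplyr::rename(fc, value = "log2fc")
    detect_outliers(vals, z_threshold = cfg$z_threshold)
  })
  emit(outliers, "outliers_lipid.tsv")
  manifest$stages$outliers <- list(n_flagged = sum(outliers$is_outlier))

  # -- class / chain summary -------------------------------------------
  summaries <- stage("class_chain_summary", {
    fc <- genotype_log2fc(dat$lipids, dat$meta, cfg$control_genotype)
    fc <- fc[fc$genotype != cfg$control_genotype, ]
    fc |>
      dplyr::group_by(.data$genotype) |>
      dplyr::group_modify(~ class_chain_summary(
        dplyr::rename(.x, lipid_id = "feature_id"), dat$species,
        carbon_cutoff = cfg$carbon_cutoff)) |>
      dplyr::ungroup()
  })
  emit(summaries, "class_chain_summary.tsv")

  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  say("wrote %d outputs to %s", length(manifest$outputs) + 1, out_dir)
  invisible(manifest)
}
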