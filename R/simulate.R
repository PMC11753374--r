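#' Generate parseable lipid shorthand names
#'
#' Draws unique names in the grammar accepted by [parse_lipid_names()].
#' Lyso classes and CE get single-chain names (`"LPC 18:1"`); all other
#' classes get two-chain molecular-species names (`"PC 16:0_18:1"`) so sum
#' compositions never collide. Ground-truth class and totals are returned
#' alongside each name.
#'
#' @param classes Character vector of class tokens, one per name to draw
#'   (recycled against `counts` when `counts` is given).
#' @param counts Optional integer vector: how many names per class.
#' @param chain_range Length-2 integer range of carbons per chain.
#' @param db_range Length-2 integer range of double bonds per chain.
#' @param seed Integer seed.
#' @return A tibble `name`, `lipid_class`, `total_carbons`,
#'   `total_double_bonds`.
#' @export
generate_lipid_names <- function(classes, counts = NULL,
                                 chain_range = c(14, 24), db_range = c(0, 4),
                                 seed = 1) {
  stopifnot(length(chain_range) == 2, length(db_range) == 2,
            chain_range[1] <= chain_range[2], db_range[1] <= db_range[2])
  if (!is.null(counts)) {
    stopifnot(length(counts) == length(classes), all(counts >= 0))
    classes <- rep(classes, times = counts)
  }
  n <- length(classes)
  if (n == 0) {
    return(tibble::tibble(name = character(), lipid_class = character(),
                          total_carbons = integer(), total_double_bonds = integer()))
  }
  single_chain <- c(LYSO_CLASSES, "CE")
  withr::with_seed(seed, {
    out <- vector("list", n)
    seen <- character(0)
    for (i in seq_len(n)) {
      cls <- classes[i]
      k <- if (cls %in% single_chain) 1L else 2L
      # rejection-sample until the name is unique
      attempts <- 0L
      repeat {
        attempts <- attempts + 1L
        if (attempts > 1000L) {
          stop("cannot draw enough unique names for class ", cls,
               "; widen chain_range/db_range")
        }
        carbons <- sample_range(chain_range, k)
        dbs <- sample_range(db_range, k)
        chain_txt <- paste(sprintf("%d:%d", carbons, dbs), collapse = "_")
        name <- paste(cls, chain_txt)
        if (!name %in% seen) break
      }
      seen <- c(seen, name)
      out[[i]] <- tibble::tibble(name = name, lipid_class = cls,
                                 total_carbons = sum(carbons),
                                 total_double_bonds = sum(dbs))
    }
  })
  dplyr::bind_rows(out)
}

# draw k values uniformly from an inclusive integer range (safe when the
# range collapses to a single value, unlike sample())
sample_range <- function(range, k) {
  vals <- range[1]:range[2]
  vals[sample.int(length(vals), k, replace = TRUE)]
}

#' Simulate a paired protein/lipid dataset with planted cross-ome modules
#'
#' Emulates a mutant-panel multi-omics design: `n_genotypes` cell lines
#' (the first is the control) measured in `n_replicates` replicate cultures,
#' with log2-scale intensities for `n_proteins` proteins and `n_lipids`
#' lipids. `n_modules` latent drivers each couple a disjoint block of
#' proteins and lipids across both omes: per sample `s` and module `m`, the
#' latent activity is
#' `z[m, s] = genotype_effect * 1[genotype(s) affected by m] + N(0, latent_sd)`,
#' and each module feature takes `base + loading * z[m, s] + N(0, noise_sd)`
#' with positive loadings, so within-module features co-vary monotonically.
#' Background features are independent noise around their baseline. Entries
#' are then masked completely at random at `missing_rate`. Module lipids are
#' drawn with a per-module class bias (so class enrichment is recoverable)
#' and module proteins define annotation terms alongside decoy terms.
#'
#' @param n_genotypes Number of genotypes including the control (default 33).
#' @param n_replicates Replicates per genotype (default 4).
#' @param n_proteins,n_lipids Features per ome (defaults 2000 and 600).
#' @param n_modules Number of planted cross-ome modules (default 5).
#' @param module_size_protein,module_size_lipid Features per module and ome
#'   (defaults 40 and 15).
#' @param latent_sd Spread of the latent module activity across samples
#'   (log2 units, default 0.5): large enough that within-module pairs stay
#'   strongly rank-correlated, small enough that a 1 log2 genotype shift is
#'   identifiable from quadruplicate replicate means.
#' @param noise_sd Log2 measurement noise (default 0.3).
#' @param genotype_effect Log2 shift of a module's latent activity in its
#'   affected genotypes (default 1).
#' @param affected_map Optional named list, module (`"1"`, `"2"`, ...) to
#'   character vector of affected genotypes. Default: 3 disjoint non-control
#'   genotypes per module, assigned round-robin. The control is never
#'   affected.
#' @param missing_rate Fraction of entries masked at random (default 0.05).
#' @param chain_range,db_range Per-chain carbon and double-bond ranges for
#'   the generated lipid names (defaults 12-26 and 0-6).
#' @param n_decoy_terms Random annotation terms added beside the module
#'   terms (default 10).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the arguments and the seed.
#' @return A list: `proteins` and `lipids` (abundance tibbles), `meta`
#'   (sample metadata), `truth` (list: `features` tibble with `ome`,
#'   `feature_id`, `module` where 0 is background; `affected_map`;
#'   `latent` module x sample activity matrix), `terms` (annotation tibble
#'   for the protein ome), `species` (ground-truth lipid name tibble from
#'   [generate_lipid_names()]).
#' @export
simulate_crossome <- function(n_genotypes = 33, n_replicates = 4,
                              n_proteins = 2000, n_lipids = 600,
                              n_modules = 5,
                              module_size_protein = 40, module_size_lipid = 15,
                              latent_sd = 0.5, noise_sd = 0.3,
                              genotype_effect = 1,
                              affected_map = NULL,
                              missing_rate = 0.05,
                              chain_range = c(12, 26), db_range = c(0, 6),
                              n_decoy_terms = 10,
                              seed = 1) {
  stopifnot(n_genotypes >= 2, n_replicates >= 1, n_modules >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (n_modules * module_size_protein > n_proteins) {
    stop("module proteins exceed n_proteins")
  }
  if (n_modules * module_size_lipid > n_lipids) {
    stop("module lipids exceed n_lipids")
  }
  genotypes <- c("control", sprintf("GT%02d_KO", seq_len(n_genotypes - 1)))
  if (is.null(affected_map)) {
    per_module <- max(1, min(3, (n_genotypes - 1) %/% n_modules))
    affected_map <- purrr::map(seq_len(n_modules), function(m) {
      idx <- ((m - 1) * per_module + 1):(m * per_module)
      genotypes[-1][((idx - 1) %% (n_genotypes - 1)) + 1]
    })
    names(affected_map) <- as.character(seq_len(n_modules))
  }
  stopifnot(all(unlist(affected_map) %in% genotypes[-1]))

  meta <- tidyr::expand_grid(genotype = genotypes,
                             replicate = seq_len(n_replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_r%d", .data$genotype, .data$replicate),
                  condition = "fed") |>
    dplyr::select("sample_id", "genotype", "condition", "replicate")
  n_samples <- nrow(meta)

  protein_ids <- sprintf("PROT%04d", seq_len(n_proteins))
  prot_module <- rep(0L, n_proteins)
  prot_module[seq_len(n_modules * module_size_protein)] <-
    rep(seq_len(n_modules), each = module_size_protein)

  lipid_module <- rep(0L, n_lipids)
  lipid_module[seq_len(n_modules * module_size_lipid)] <-
    rep(seq_len(n_modules), each = module_size_lipid)

  class_pool <- c("PC", "PE", "PI", "PS", "TG", "DG", "SM", "Cer[NS]",
                  "GM3", "CE", "LPC", "LPE")
  module_class <- class_pool[((seq_len(n_modules) - 1) %% length(class_pool)) + 1]

  withr::with_seed(seed, {
    # lipid identities: 70% of a module's lipids take its signature class
    lipid_classes <- character(n_lipids)
    for (i in seq_len(n_lipids)) {
      m <- lipid_module[i]
      lipid_classes[i] <- if (m > 0 && stats::runif(1) < 0.7) module_class[m]
                          else sample(class_pool, 1)
    }
    name_seed <- sample.int(.Machine$integer.max, 1)
  })
  species <- generate_lipid_names(lipid_classes, chain_range = chain_range,
                                  db_range = db_range, seed = name_seed)
  lipid_ids <- species$name

  withr::with_seed(seed + 1L, {
    latent <- matrix(stats::rnorm(n_modules * n_samples, sd = latent_sd),
                     n_modules, n_samples,
                     dimnames = list(as.character(seq_len(n_modules)),
                                     meta$sample_id))
    for (m in seq_len(n_modules)) {
      affected <- meta$genotype %in% affected_map[[as.character(m)]]
      latent[m, affected] <- latent[m, affected] + genotype_effect
    }

    P <- simulate_ome(n_proteins, n_samples, prot_module, latent,
                      noise_sd, base_mean = 25)
    L <- simulate_ome(n_lipids, n_samples, lipid_module, latent,
                      noise_sd, base_mean = 20)
    dimnames(P) <- list(protein_ids, meta$sample_id)
    dimnames(L) <- list(lipid_ids, meta$sample_id)

    if (missing_rate > 0) {
      P[stats::runif(length(P)) < missing_rate] <- NA_real_
      L[stats::runif(length(L)) < missing_rate] <- NA_real_
    }

    terms <- module_terms(protein_ids, prot_module, n_modules, n_decoy_terms)
  })

  truth <- list(
    features = dplyr::bind_rows(
      tibble::tibble(ome = "protein", feature_id = protein_ids, module = prot_module),
      tibble::tibble(ome = "lipid", feature_id = lipid_ids, module = lipid_module)
    ),
    affected_map = affected_map,
    latent = latent
  )
  list(proteins = as_abundance(P, "protein"),
       lipids = as_abundance(L, "lipid"),
       meta = meta, truth = truth, terms = terms, species = species)
}

# one ome's log2 intensity matrix: baseline + positive loading x latent
# module activity + measurement noise
simulate_ome <- function(n_features, n_samples, module, latent, noise_sd,
                         base_mean) {
  base <- stats::rnorm(n_features, mean = base_mean, sd = 2)
  loading <- stats::runif(n_features, 0.5, 1.5)
  vals <- matrix(stats::rnorm(n_features * n_samples, sd = noise_sd),
                 n_features, n_samples)
  vals <- vals + base
  planted <- which(module > 0)
  if (length(planted) > 0) {
    vals[planted, ] <- vals[planted, ] +
      loading[planted] * latent[module[planted], , drop = FALSE]
  }
  vals
}

# module-aligned annotation terms plus random decoys over all proteins
module_terms <- function(protein_ids, prot_module, n_modules, n_decoy_terms) {
  module_rows <- tibble::tibble(
    term_id = sprintf("SYN:%04d", seq_len(n_modules)),
    term_name = sprintf("module_%d", seq_len(n_modules)),
    features = purrr::map(seq_len(n_modules),
                          ~ protein_ids[prot_module == .x])
  )
  if (n_decoy_terms == 0) return(module_rows)
  decoy_rows <- tibble::tibble(
    term_id = sprintf("SYN:%04d", n_modules + seq_len(n_decoy_terms)),
    term_name = sprintf("decoy_%d", seq_len(n_decoy_terms)),
    features = purrr::map(seq_len(n_decoy_terms), function(i) {
      sample(protein_ids, size = max(5, round(length(protein_ids) * 0.02)))
    })
  )
  dplyr::bind_rows(module_rows, decoy_rows)
}
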