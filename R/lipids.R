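#' Parse lipid shorthand names
#'
#' Parses names in the common shorthand grammar
#' `CLASS [O-|P-] C:D [ _C:D | /C:D ]*`, with optional class decorations in
#' square brackets (e.g. `"Cer[NS] 18:1_24:0"`) and prose-style prefixes
#' (`"Lyso-PC 18:1"`, `"plasmanyl-PC 34:1"`, `"alkenyl-DG 36:2"`). Chain
#' separators `"_"` and `"/"` are treated identically: only the totals are
#' used downstream. Sum-composition names (a single C:D) leave `sn_chains`
#' empty; molecular-species names record each chain and the totals are their
#' sums. Names outside the grammar are kept with `lipid_class` set to the raw
#' token and unknown totals, with one warning listing them; surrounding
#' whitespace is ignored and class tokens are case-preserved.
#'
#' @param names Character vector of lipid names. Empty strings are an error.
#' @return A tibble with one row per name: `raw_name`, `lipid_class`,
#'   `total_carbons`, `total_double_bonds` (integers, `NA` when unknown),
#'   `is_lyso`, `is_ether`, and a list-column `sn_chains` of two-column
#'   matrices (carbons, double_bonds) for resolved molecular species.
#' @examples
#' parse_lipid_names(c("LPC 18:1", "PC 16:0_18:1", "CE 16:0"))
#' @export
parse_lipid_names <- function(names) {
  stopifnot(is.character(names))
  if (length(names) == 0) {
    return(tibble::tibble(raw_name = character(), lipid_class = character(),
                          total_carbons = integer(), total_double_bonds = integer(),
                          is_lyso = logical(), is_ether = logical(),
                          sn_chains = list()))
  }
  trimmed <- stringr::str_trim(names)
  if (any(!nzchar(trimmed))) stop("empty lipid name at position ", which(!nzchar(trimmed))[1])

  rows <- purrr::map(trimmed, parse_one_lipid)
  out <- dplyr::bind_rows(rows)
  out$raw_name <- names
  bad <- !out$parsed
  if (any(bad)) {
    warning(sprintf("%d lipid name(s) outside the shorthand grammar kept unparsed: %s",
                    sum(bad), paste(utils::head(out$raw_name[bad], 5), collapse = ", ")))
  }
  out$parsed <- NULL
  out[c("raw_name", "lipid_class", "total_carbons", "total_double_bonds",
        "is_lyso", "is_ether", "sn_chains")]
}

# lyso classes written with a leading L in shorthand
LYSO_CLASSES <- c("LPC", "LPE", "LPG", "LPI", "LPS", "LPA")

parse_one_lipid <- function(name) {
  unparsed <- tibble::tibble(
    raw_name = name, lipid_class = name,
    total_carbons = NA_integer_, total_double_bonds = NA_integer_,
    is_lyso = FALSE, is_ether = FALSE, sn_chains = list(NULL), parsed = FALSE
  )

  # CLASS token = everything before the first space; chains follow
  m <- stringr::str_match(
    name,
    "^(\\S+)\\s+((?:O-|P-)?\\d+:\\d+(?:[_/]\\d+:\\d+)*)$"
  )
  if (is.na(m[1, 1])) return(unparsed)
  cls <- m[1, 2]
  chains <- m[1, 3]

  is_lyso <- FALSE
  is_ether <- FALSE

  # prose-style class prefixes
  if (stringr::str_detect(cls, stringr::regex("^lyso-", ignore_case = TRUE))) {
    is_lyso <- TRUE
    cls <- stringr::str_remove(cls, stringr::regex("^lyso-", ignore_case = TRUE))
  }
  if (stringr::str_detect(cls, stringr::regex("^(plasmanyl|plasmenyl|alkenyl)-", ignore_case = TRUE))) {
    is_ether <- TRUE
    cls <- stringr::str_remove(cls, stringr::regex("^(plasmanyl|plasmenyl|alkenyl)-", ignore_case = TRUE))
  }
  if (!nzchar(cls)) return(unparsed)
  if (toupper(cls) %in% LYSO_CLASSES) is_lyso <- TRUE

  if (stringr::str_detect(chains, "^[OP]-")) {
    is_ether <- TRUE
    chains <- stringr::str_sub(chains, 3)
  }

  pieces <- stringr::str_split(chains, "[_/]")[[1]]
  cd <- stringr::str_match(pieces, "^(\\d+):(\\d+)$")
  carbons <- as.integer(cd[, 2])
  dbs <- as.integer(cd[, 3])

  sn <- NULL
  if (length(pieces) > 1) {
    sn <- cbind(carbons = carbons, double_bonds = dbs)
  }
  tibble::tibble(
    raw_name = name, lipid_class = cls,
    total_carbons = sum(carbons), total_double_bonds = sum(dbs),
    is_lyso = is_lyso, is_ether = is_ether,
    sn_chains = list(sn), parsed = TRUE
  )
}
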