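#' Read a feature-by-sample abundance table
#'
#' Reads a delimited text matrix of log2-scale intensities into a tidy
#' abundance table: a tibble whose first column is `feature_id` and whose
#' remaining columns are samples. Values are taken as already log-scale;
#' set `transform = "log2_plus1"` for raw intensities.
#'
#' @param path Path to a delimited text file with one id column/row of
#'   feature ids and one header row/column of sample ids.
#' @param ome Which ome the table measures: `"protein"` or `"lipid"`.
#' @param orientation `"features_in_rows"` (default) if rows are features,
#'   `"features_in_columns"` if the table is transposed.
#' @param delim Field delimiter. Defaults to `","` for `.csv` files and
#'   tab otherwise.
#' @param na Strings treated as missing values.
#' @param transform `"none"` (values are already log2) or `"log2_plus1"`
#'   to apply `log2(x + 1)` to raw intensities.
#' @return A tibble with a `feature_id` column and one numeric column per
#'   sample, carrying an `"ome"` attribute.
#' @export
read_abundance <- function(path, ome = c("protein", "lipid"),
                           orientation = c("features_in_rows", "features_in_columns"),
                           delim = NULL, na = c("", "NA"),
                           transform = c("none", "log2_plus1")) {
  ome <- match.arg(ome)
  orientation <- match.arg(orientation)
  transform <- match.arg(transform)
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

  raw <- readr::read_delim(path, delim = delim, na = na,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) stop("abundance table needs an id column plus at least one value column")
  ids <- raw[[1]]
  body <- raw[-1]

  # convert cell by column, reporting the first offending coordinate
  num <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_along(body)) {
    col <- body[[j]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   col[bad[1]], bad[1], names(body)[j], path))
    }
    num[, j] <- v
  }
  dimnames(num) <- list(ids, names(body))
  if (orientation == "features_in_columns") num <- t(num)
  if (transform == "log2_plus1") num <- log2(num + 1)

  check_unique(rownames(num), "feature id")
  check_unique(colnames(num), "sample id")
  if (any(is.infinite(num))) stop("abundance table contains non-finite values")
  as_abundance(num, ome)
}

#' Write an abundance table
#'
#' Writes the tidy abundance table back to delimited text (features in
#' rows), with empty cells for missing values. `read_abundance()` on the
#' result reproduces ids, values and missingness exactly.
#'
#' @param x An abundance tibble as returned by [read_abundance()].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path, delim = "\t") {
  stopifnot(is.data.frame(x), names(x)[1] == "feature_id")
  readr::write_delim(x, path, delim = delim, na = "")
  invisible(path)
}

#' Build an abundance tibble from a matrix
#'
#' @param mat Numeric feature-by-sample matrix with row and column names.
#' @param ome `"protein"` or `"lipid"`.
#' @return A tidy abundance tibble (see [read_abundance()]).
#' @export
as_abundance <- function(mat, ome = c("protein", "lipid")) {
  ome <- match.arg(ome)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  check_unique(rownames(mat), "feature id")
  check_unique(colnames(mat), "sample id")
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(mat)), out)
  attr(out, "ome") <- ome
  out
}

#' Extract the numeric matrix from an abundance tibble
#'
#' @param x An abundance tibble.
#' @return A numeric matrix, features in rows.
#' @export
abundance_matrix <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1] == "feature_id")
  m <- as.matrix(x[-1])
  storage.mode(m) <- "double"
  rownames(m) <- x$feature_id
  m
}

#' Which ome an abundance table measures
#' @param x An abundance tibble.
#' @return `"protein"`, `"lipid"`, or `NA` if unannotated.
#' @export
abundance_ome <- function(x) {
  ome <- attr(x, "ome", exact = TRUE)
  if (is.null(ome)) NA_character_ else ome
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `genotype`, `condition`,
#'   `replicate`.
#' @return A tibble with those columns; `replicate` is a positive integer.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "genotype", "condition", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    stop("sample metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  check_unique(meta$sample_id, "sample id")
  meta$replicate <- as.integer(meta$replicate)
  if (any(is.na(meta$replicate)) || any(meta$replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  tibble::as_tibble(meta[need])
}

#' Write a sample metadata table
#' @param meta Metadata tibble (see [read_sample_meta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

#' Read a GMT annotation file
#'
#' One term per line, tab-separated: term id, term name/description, then
#' member feature ids. Terms whose member list is empty are dropped with a
#' warning; lines with fewer than three fields are an error.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `term_name`, and a list-column
#'   `features` of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1]))
  }
  rows <- purrr::map(parts, function(p) {
    members <- p[-(1:2)]
    members <- members[nzchar(members)]
    tibble::tibble(term_id = p[1], term_name = p[2], features = list(unique(members)))
  })
  out <- dplyr::bind_rows(rows)
  empty <- lengths(out$features) == 0
  if (any(empty)) {
    warning(sprintf("dropped %d GMT term(s) with no members: %s",
                    sum(empty), paste(out$term_id[empty], collapse = ", ")))
    out <- out[!empty, ]
  }
  out
}

#' Write a GMT annotation file
#' @param terms Tibble with `term_id`, `term_name`, list-column `features`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- purrr::pmap_chr(terms[c("term_id", "term_name", "features")],
                           function(term_id, term_name, features) {
                             paste(c(term_id, term_name, features), collapse = "\t")
                           })
  writeLines(lines, path)
  invisible(path)
}

# shared validation: duplicate ids are a hard error naming the duplicate
check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s: %s", what, paste(dup, collapse = ", ")))
  }
  invisible(ids)
}
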