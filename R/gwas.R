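#' GWAS Catalog association filtering
#'
#' The filtering cascade applied to GWAS Catalog association rows:
#' genome-wide significance, per-study deduplication to the smallest
#' p-value, restriction to variants uniquely mapped to a single gene,
#' restriction to high/moderate functional impact, and removal of
#' non-specific parent trait categories (including the highly polygenic
#' body-measurement traits).
#'
#' @name gwas
NULL

GWAS_EXCLUDED_CATEGORIES <- c("Other trait", "Other disease", "NR",
                              "Other measurement", "Body measurement")

#' Read a GWAS Catalog associations file
#'
#' Honors the catalog's native column headers (`SNPS`, `MAPPED_GENE`,
#' `MAPPED_TRAIT`, `P-VALUE`, `STUDY ACCESSION`, plus an impact column) and
#' optionally joins a two-column EFO trait-to-parent mapping table.
#'
#' @param path associations TSV.
#' @param trait_map optional path to a two-column TSV mapping `trait` to
#'   `parent_category`.
#' @param column_map named character vector mapping internal names
#'   (`variant`, `mapped_genes`, `mapped_trait`, `p`, `study`, `impact`,
#'   `parent_category`) to file headers; unspecified entries use the native
#'   catalog headers.
#' @param sep field separator.
#' @return tibble with internal column names; `mapped_genes` is a list-column
#'   of gene symbol sets.
#' @export
read_gwas_catalog <- function(path, trait_map = NULL, column_map = character(),
                              sep = "\t") {
  defaults <- c(variant = "SNPS", mapped_genes = "MAPPED_GENE",
                mapped_trait = "MAPPED_TRAIT", p = "P-VALUE",
                study = "STUDY ACCESSION", impact = "IMPACT",
                parent_category = "PARENT_CATEGORY")
  cm <- defaults
  cm[names(column_map)] <- column_map
  df <- read_table_file(path, sep)
  need <- cm[c("variant", "mapped_genes", "mapped_trait", "p")]
  require_columns(df, unname(need), "GWAS Catalog table")
  pick <- function(key, default = NA_character_) {
    if (cm[[key]] %in% names(df)) df[[cm[[key]]]] else rep(default, nrow(df))
  }
  out <- tibble::tibble(
    variant = as.character(df[[cm[["variant"]]]]),
    mapped_genes = split_mapped_genes(df[[cm[["mapped_genes"]]]]),
    mapped_trait = as.character(df[[cm[["mapped_trait"]]]]),
    p = as.numeric(df[[cm[["p"]]]]),
    impact = trimws(tolower(pick("impact"))),
    study = as.character(pick("study")),
    parent_category = as.character(pick("parent_category"))
  )
  if (!is.null(trait_map)) {
    tm <- read_table_file(trait_map, sep)
    if (ncol(tm) < 2) stop_schema("trait mapping file needs two columns")
    out$parent_category <- as.character(tm[[2]])[match(out$mapped_trait, tm[[1]])]
  }
  out
}

# "A - B" (intergenic) and "A; B" (multiple) conventions both split to a set
split_mapped_genes <- function(x) {
  lapply(strsplit(as.character(x), ";|,| - "), function(g) {
    g <- canon_symbol(g)
    sort(unique(g[nzchar(g) & !is.na(g)]))
  })
}

#' Apply the GWAS Catalog filtering cascade
#'
#' Stages, in order: (1) keep `p <= alpha`; (2) per (mapped gene set,
#' variant, trait) keep the minimum-p row across studies (ties broken by
#' study accession); (3) keep rows whose variant maps to exactly one gene;
#' (4) keep rows with functional impact in `keep_impacts`; (5) drop rows
#' whose parent category is missing or excluded. The per-stage survivor
#' counts are attached as `attr(result, "stage_log")`.
#'
#' @param rows tibble as returned by [read_gwas_catalog()] (columns
#'   `variant`, `mapped_genes` list-column, `mapped_trait`, `p`, `impact`,
#'   `study`, `parent_category`).
#' @param alpha significance threshold, inclusive (default `5e-8`).
#' @param excluded_categories parent categories to drop.
#' @param keep_impacts impact classes to keep.
#' @return the filtered tibble with a `stage_log` attribute (integer vector
#'   of survivor counts after each of the five stages).
#' @export
gwas_filter_pipeline <- function(rows, alpha = 5e-8,
                                 excluded_categories = GWAS_EXCLUDED_CATEGORIES,
                                 keep_impacts = c("high", "moderate")) {
  rows <- tibble::as_tibble(rows)
  require_columns(rows, c("variant", "mapped_genes", "mapped_trait", "p",
                          "impact", "study", "parent_category"),
                  "GWAS rows")
  if (!is.list(rows$mapped_genes)) {
    rows$mapped_genes <- split_mapped_genes(rows$mapped_genes)
  }
  log <- integer(5)

  # 1: genome-wide significance
  rows <- rows[!is.na(rows$p) & rows$p <= alpha, , drop = FALSE]
  log[1] <- nrow(rows)

  # 2: min-p per (gene set, variant, trait) across studies
  if (nrow(rows) > 0) {
    gene_key <- vapply(rows$mapped_genes, paste, character(1), collapse = "|")
    key <- paste(gene_key, rows$variant, rows$mapped_trait, sep = "\r")
    ord <- order(key, rows$p, rows$study)
    rows <- rows[ord, , drop = FALSE]
    rows <- rows[!duplicated(key[ord]), , drop = FALSE]
  }
  log[2] <- nrow(rows)

  # 3: variants uniquely assigned to a single gene
  rows <- rows[lengths(rows$mapped_genes) == 1, , drop = FALSE]
  log[3] <- nrow(rows)

  # 4: functional impact classes
  rows <- rows[!is.na(rows$impact) & rows$impact %in% tolower(keep_impacts),
               , drop = FALSE]
  log[4] <- nrow(rows)

  # 5: informative parent categories only
  rows <- rows[!is.na(rows$parent_category) &
                 !rows$parent_category %in% excluded_categories, , drop = FALSE]
  log[5] <- nrow(rows)

  message(sprintf("gwas_filter_pipeline survivors: [%s]",
                  paste(log, collapse = ", ")))
  attr(rows, "stage_log") <- log
  rows
}
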