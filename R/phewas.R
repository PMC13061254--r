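#' PheWAS summary-statistics processing
#'
#' Variant-level phenome-wide association records carry a p-value and an
#' effect (odds ratio for binary phenotypes, beta for continuous ones) under
#' one of four genetic models. The summarisation procedure keeps significant
#' associations, collapses multi-model duplicates to the smallest p-value,
#' and averages effects per gene within each phenotype category.
#'
#' @name phewas
NULL

PHEWAS_MODELS <- c("genotypic_additive", "allelic", "dominant", "recessive")

#' Validate a table of variant-phenotype association records
#'
#' @param records data frame with columns `variant`, `gene`, `phenotype`,
#'   `category`, `model`, `p`, `effect`, `type`.
#' @return the validated tibble.
#' @export
validate_phewas <- function(records) {
  records <- tibble::as_tibble(records)
  require_columns(records,
                  c("variant", "gene", "phenotype", "category", "model",
                    "p", "effect", "type"),
                  "PheWAS table")
  records$model <- trimws(tolower(records$model))
  bad <- which(!records$model %in% PHEWAS_MODELS)
  if (length(bad) > 0) {
    stop_value(sprintf("PheWAS row %d: model '%s' is not one of {%s}",
                       bad[1], records$model[bad[1]],
                       paste(PHEWAS_MODELS, collapse = ", ")))
  }
  records$type <- trimws(tolower(records$type))
  bad <- which(!records$type %in% c("binary", "continuous"))
  if (length(bad) > 0) {
    stop_value(sprintf("PheWAS row %d: type must be binary or continuous", bad[1]))
  }
  bad <- which(!(records$p > 0 & records$p <= 1))
  if (length(bad) > 0) {
    stop_value(sprintf("PheWAS row %d: p-value outside (0, 1]", bad[1]))
  }
  bad <- which(records$type == "binary" & records$effect <= 0)
  if (length(bad) > 0) {
    stop_value(sprintf("PheWAS row %d: odds ratio must be positive", bad[1]))
  }
  records$gene <- canon_symbol(records$gene)
  records
}

#' Keep genome-wide significant PheWAS associations
#'
#' @param records validated PheWAS tibble.
#' @param alpha significance threshold, inclusive (default `1e-8`).
#' @return the subset with `p <= alpha`.
#' @export
phewas_filter_significant <- function(records, alpha = 1e-8) {
  records <- tibble::as_tibble(records)
  records[records$p <= alpha, , drop = FALSE]
}

#' Collapse multi-model duplicates to the smallest p-value
#'
#' A variant-phenotype association tested under several genetic models is
#' represented once, by its minimum-p record. Exact p ties are broken by a
#' fixed model priority (genotypic/additive, allelic, dominant, recessive),
#' then lexicographically.
#'
#' @param records validated PheWAS tibble.
#' @return deduplicated tibble (idempotent).
#' @export
phewas_dedup_models <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) return(records)
  key <- paste(records$variant, records$phenotype, sep = "\r")
  ord <- order(key, records$p, match(records$model, PHEWAS_MODELS),
               records$gene, records$effect)
  records <- records[ord, , drop = FALSE]
  records[!duplicated(key[ord]), , drop = FALSE]
}

#' Mean association effect per gene and phenotype category
#'
#' For binary phenotypes the arithmetic mean of the odds ratios; for
#' continuous phenotypes the arithmetic mean of absolute effect sizes.
#' Binary and continuous phenotypes are summarised separately and never
#' averaged together. With `fold_protective = TRUE`, protective odds ratios
#' (< 1) are folded to `1/OR` before averaging.
#'
#' @param records PheWAS tibble, already filtered and deduplicated.
#' @param fold_protective fold ORs below 1 onto the risk scale first.
#' @return tibble with columns `gene`, `category`, `type`, `mean_effect`,
#'   `n_associations`.
#' @export
phewas_gene_category_summary <- function(records, fold_protective = FALSE) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(gene = character(), category = character(),
                          type = character(), mean_effect = numeric(),
                          n_associations = integer()))
  }
  eff <- ifelse(records$type == "binary",
                if (fold_protective) pmax(records$effect, 1 / records$effect)
                else records$effect,
                abs(records$effect))
  key <- interaction(records$gene, records$category, records$type, drop = TRUE)
  agg <- tapply(eff, key, mean)
  n <- tapply(eff, key, length)
  first <- !duplicated(key)
  out <- tibble::tibble(gene = records$gene[first],
                        category = as.character(records$category[first]),
                        type = records$type[first],
                        mean_effect = as.numeric(agg[as.character(key[first])]),
                        n_associations = as.integer(n[as.character(key[first])]))
  out[order(out$gene, out$category, out$type), , drop = FALSE]
}
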