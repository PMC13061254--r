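#' Reproducible pipeline runs
#'
#' Thin orchestration over the curation, association, enrichment and
#' expression modules: each `run_*` function reads its inputs, executes the
#' corresponding stage, writes deterministic TSV/CSV/JSON outputs and a run
#' report (parameter echo, seed, stage record counts, input file digests).
#'
#' @name cli_pipeline
NULL

run_report <- function(stage_counts, params, seed = NA_integer_,
                       inputs = character()) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  list(version = as.character(utils::packageVersion("e3ome")),
       seed = seed,
       parameters = params,
       stage_counts = stage_counts,
       input_digests = digests)
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the curation stage: score, rank, classify, tally
#'
#' @param gene_table,vote_table,evidence_tables ledger input files (see
#'   [load_ledger()]).
#' @param out_dir output directory; writes `ranked_genes.tsv`,
#'   `family_tallies.json` and `report.json`.
#' @param rules_file optional YAML rule file (defaults to the shipped one).
#' @param weights a [score_weights()] object.
#' @param sep input field separator.
#' @return invisibly, a list with `ranked`, `tallies` and `report`.
#' @export
run_curate <- function(gene_table, vote_table = NULL,
                       evidence_tables = character(), out_dir,
                       rules_file = NULL, weights = score_weights(),
                       sep = "\t") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rules <- load_family_rules(rules_file)
  ledger <- load_ledger(gene_table, vote_table, evidence_tables, sep = sep)
  ranked <- score_ledger(ledger, weights = weights)
  assignments <- do.call(rbind, lapply(ledger$genes$symbol, classify_family,
                                       ledger = ledger, rules = rules))
  fam_col <- vapply(ranked$gene, function(g) {
    paste(sort(assignments$family[assignments$gene == g]), collapse = ";")
  }, character(1))
  ranked_out <- ranked
  ranked_out$families <- fam_col
  tallies <- enumerate_families(ledger, rules)

  write_tsv_file(ranked_out, file.path(out_dir, "ranked_genes.tsv"))
  tally_list <- stats::setNames(lapply(seq_len(nrow(tallies)), function(i) {
    list(input = tallies$input[i], high = tallies$high[i],
         low = tallies$low[i],
         claim_counts = as.list(tallies$claim_counts[[i]]))
  }), tallies$family)
  jsonlite::write_json(tally_list, file.path(out_dir, "family_tallies.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- run_report(
    stage_counts = list(genes = nrow(ledger$genes),
                        votes = nrow(ledger$votes),
                        evidence = nrow(ledger$evidence),
                        rejected_rows = nrow(ledger$rejected),
                        ranked = nrow(ranked),
                        category1 = sum(ranked$category == 1),
                        category2 = sum(ranked$category == 2),
                        category3 = sum(ranked$category == 3)),
    params = list(w_yes = weights$w_yes, w_no = weights$w_no,
                  w_evidence = weights$w_evidence),
    inputs = c(gene_table, vote_table, evidence_tables))
  write_report(report, file.path(out_dir, "report.json"))
  invisible(list(ranked = ranked_out, tallies = tallies, report = report))
}

#' Run the association stage: PheWAS summarisation and GWAS filtering
#'
#' @param phewas_table PheWAS-style TSV (see [validate_phewas()] schema);
#'   optional.
#' @param gwas_table GWAS Catalog associations TSV; optional.
#' @param trait_map optional EFO trait-to-parent mapping TSV.
#' @param out_dir output directory; writes `gene_category_effects.tsv`,
#'   `gwas_filtered.tsv` and `report.json`.
#' @param phewas_alpha,gwas_alpha inclusive significance thresholds.
#' @param column_map passed to [read_gwas_catalog()].
#' @param sep input field separator.
#' @return invisibly, a list with `summary`, `gwas` and `report`.
#' @export
run_associations <- function(phewas_table = NULL, gwas_table = NULL,
                             trait_map = NULL, out_dir,
                             phewas_alpha = 1e-8, gwas_alpha = 5e-8,
                             column_map = character(), sep = "\t") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  summary_tbl <- NULL
  gwas_out <- NULL
  if (!is.null(phewas_table)) {
    rec <- validate_phewas(read_table_file(phewas_table, sep))
    counts$phewas_input <- nrow(rec)
    rec <- phewas_filter_significant(rec, alpha = phewas_alpha)
    counts$phewas_significant <- nrow(rec)
    rec <- phewas_dedup_models(rec)
    counts$phewas_deduplicated <- nrow(rec)
    summary_tbl <- phewas_gene_category_summary(rec)
    counts$phewas_summaries <- nrow(summary_tbl)
    write_tsv_file(summary_tbl, file.path(out_dir, "gene_category_effects.tsv"))
  }
  if (!is.null(gwas_table)) {
    rows <- read_gwas_catalog(gwas_table, trait_map = trait_map,
                              column_map = column_map, sep = sep)
    counts$gwas_input <- nrow(rows)
    gwas_out <- gwas_filter_pipeline(rows, alpha = gwas_alpha)
    counts$gwas_stage_log <- attr(gwas_out, "stage_log")
    flat <- gwas_out
    flat$mapped_genes <- vapply(flat$mapped_genes, paste, character(1),
                                collapse = ";")
    write_tsv_file(flat, file.path(out_dir, "gwas_filtered.tsv"))
  }
  report <- run_report(counts,
                       params = list(phewas_alpha = phewas_alpha,
                                     gwas_alpha = gwas_alpha),
                       inputs = c(phewas_table, gwas_table, trait_map))
  write_report(report, file.path(out_dir, "report.json"))
  invisible(list(summary = summary_tbl, gwas = gwas_out, report = report))
}

#' Run the phenotype-term enrichment stage
#'
#' @param obo_file ontology in OBO format.
#' @param annotation_table gene-term TSV (columns `gene`, `term`).
#' @param family_table TSV with columns `family`, `gene`.
#' @param universe_file one gene symbol per line.
#' @param out_dir output directory; writes `enrichment.tsv` and
#'   `report.json`.
#' @param min_genes minimum family genes per tested term (default 3).
#' @param propagate propagate annotations to ancestors first.
#' @return invisibly, a list with `enrichment` and `report`.
#' @export
run_enrich <- function(obo_file, annotation_table, family_table,
                       universe_file, out_dir, min_genes = 3,
                       propagate = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ontology <- read_obo(obo_file)
  direct <- read_annotations(annotation_table)
  universe <- canon_symbol(readLines(universe_file))
  universe <- universe[nzchar(universe)]
  annotations <- propagate_annotations(ontology, direct, universe,
                                       propagate = propagate)
  fam_df <- read_table_file(family_table)
  require_columns(fam_df, c("family", "gene"), "family table")
  family_sets <- split(canon_symbol(fam_df$gene), fam_df$family)
  enrichment <- enrich_families(family_sets, annotations,
                                min_genes = min_genes)
  write_tsv_file(enrichment, file.path(out_dir, "enrichment.tsv"))
  report <- run_report(
    list(terms = nrow(ontology$terms), families = length(family_sets),
         universe = annotations$universe_size, tested = nrow(enrichment),
         significant = sum(enrichment$p_adj < 0.05)),
    params = list(min_genes = min_genes, propagate = propagate),
    inputs = c(obo_file, annotation_table, family_table, universe_file))
  write_report(report, file.path(out_dir, "report.json"))
  invisible(list(enrichment = enrichment, report = report))
}

#' Run the single-cell marker stage
#'
#' Normalises raw counts to CP10K, filters small classes and runs the
#' one-vs-rest Wilcoxon harness.
#'
#' @param counts_file matrix file (`.mtx` with sidecars, or dense CSV).
#' @param labels_file CSV with columns `cell`, `broad_cell_class`.
#' @param out_dir output directory; writes `markers.tsv`, `zscores.csv` and
#'   `report.json`.
#' @param row_names,col_names MTX sidecar files.
#' @param min_cells class-size floor (default 20).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return invisibly, a list with `markers` and `report`.
#' @export
run_markers <- function(counts_file, labels_file, out_dir,
                        row_names = NULL, col_names = NULL,
                        min_cells = 20, alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- read_counts(counts_file, row_names = row_names,
                        col_names = col_names, layer = "raw")
  lab_df <- utils::read.csv(labels_file, stringsAsFactors = FALSE)
  require_columns(lab_df, c("cell", "broad_cell_class"), "cell labels")
  labels <- stats::setNames(as.character(lab_df$broad_cell_class),
                            as.character(lab_df$cell))
  norm <- cp10k_normalize(counts)
  markers <- wilcoxon_ovr(norm, labels, alpha = alpha, min_cells = min_cells)
  write_tsv_file(markers, file.path(out_dir, "markers.tsv"))
  lfc <- stats::reshape(
    as.data.frame(markers[, c("gene", "group", "log2fc")]),
    idvar = "gene", timevar = "group", direction = "wide")
  rownames(lfc) <- lfc$gene
  lfc$gene <- NULL
  names(lfc) <- sub("^log2fc\\.", "", names(lfc))
  if (ncol(lfc) >= 2) {
    z <- rowwise_zscore(as.matrix(lfc))
    utils::write.csv(round(z, 9), file.path(out_dir, "zscores.csv"))
  }
  report <- run_report(
    list(genes = nrow(counts$values), cells = ncol(counts$values),
         classes = length(unique(markers$group)),
         significant = sum(markers$significant)),
    params = list(min_cells = min_cells, alpha = alpha),
    inputs = c(counts_file, labels_file))
  write_report(report, file.path(out_dir, "report.json"))
  invisible(list(markers = markers, report = report))
}
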