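#' Phenotype-term enrichment for E3 families
#'
#' Per-family term enrichment against a fixed protein-coding gene universe:
#' gene annotations are propagated up the ontology (true-path rule), a
#' 2x2 table is built for every term annotated to at least `min_genes`
#' family members, enrichment is assessed with a one-sided (upper-tail)
#' Fisher exact test, p-values are Benjamini-Hochberg adjusted within the
#' family, and odds ratios use the Haldane-Anscombe 0.5 pseudocount so they
#' stay finite with zero cells.
#'
#' @name hpo_enrichment
NULL

#' Propagate gene annotations to ancestor terms
#'
#' Implements the true-path rule: after propagation each term's gene set is
#' the union of its own direct annotations and those of all its descendants.
#' Genes outside the universe are dropped.
#'
#' @param ontology an `e3_ontology`.
#' @param direct named list mapping term id to a character vector of genes.
#' @param universe character vector of universe gene symbols.
#' @param propagate set to `FALSE` to keep direct annotations only.
#' @return an `annotation_map`: list with `term_genes` (named list),
#'   `universe` and `universe_size`.
#' @export
propagate_annotations <- function(ontology, direct, universe,
                                  propagate = TRUE) {
  stopifnot(inherits(ontology, "e3_ontology"))
  universe <- unique(canon_symbol(universe))
  direct <- lapply(direct, function(g) intersect(unique(canon_symbol(g)), universe))
  ord <- topo_order(ontology)  # errors on cycles
  sets <- stats::setNames(vector("list", length(ord)), ord)
  for (id in ord) sets[[id]] <- direct[[id]] %||% character()
  if (propagate) {
    parent_of <- split(ontology$edges$parent, ontology$edges$child)
    # children before parents: reverse topological order
    for (id in rev(ord)) {
      for (p in parent_of[[id]] %||% character()) {
        sets[[p]] <- union(sets[[p]], sets[[id]])
      }
    }
  }
  sets <- lapply(sets, sort)
  structure(list(term_genes = sets, universe = sort(universe),
                 universe_size = length(universe)),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d terms over a universe of %d genes\n",
              length(x$term_genes), x$universe_size))
  invisible(x)
}

#' Build the 2x2 table for a family-term pair
#'
#' `a` = family genes with the term, `b` = family genes without it, `c` =
#' non-family genes with the term, `d` = the remaining universe.
#'
#' @param family_genes character vector (subset of the universe).
#' @param term_genes character vector (subset of the universe).
#' @param universe_size universe size (positive integer).
#' @return named integer vector `c(a, b, c, d)`.
#' @export
build_table <- function(family_genes, term_genes, universe_size) {
  family_genes <- unique(family_genes)
  term_genes <- unique(term_genes)
  a <- length(intersect(family_genes, term_genes))
  b <- length(family_genes) - a
  cc <- length(term_genes) - a
  d <- universe_size - a - b - cc
  if (d < 0) stop_value("universe smaller than the union of family and term genes")
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided (enrichment) Fisher exact test p-value
#'
#' Exact upper-tail hypergeometric probability `P(X >= a)` with the table's
#' margins fixed, accumulated from log-factorials (no normal approximation).
#'
#' @param table named integer vector `c(a, b, c, d)` from [build_table()].
#' @return p-value in (0, 1].
#' @export
fisher_one_sided <- function(table) {
  a <- table[["a"]]; b <- table[["b"]]; cc <- table[["c"]]; d <- table[["d"]]
  if (min(a, b, cc, d) < 0) stop_value("contingency table has a negative cell")
  n_family <- a + b          # draws
  n_term <- a + cc           # successes in the urn
  n_total <- a + b + cc + d
  hi <- min(n_family, n_term)
  if (a > hi) return(0)
  k <- a:hi
  # log hypergeometric pmf via log-binomials
  logp <- lchoose(n_term, k) + lchoose(n_total - n_term, n_family - k) -
    lchoose(n_total, n_family)
  min(1, sum(exp(logp)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts ascending, computes `p * m / i`, enforces monotonicity with a
#' running minimum from the largest rank, caps at 1, and returns the values
#' in the original input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_value("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  adj <- p_values[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Haldane-Anscombe corrected odds ratio
#'
#' `(a + 0.5)(d + 0.5) / ((b + 0.5)(c + 0.5))`: the 0.5 pseudocount keeps
#' the odds ratio finite and positive even when a cell is zero.
#'
#' @param table named integer vector `c(a, b, c, d)`.
#' @return positive odds ratio.
#' @export
haldane_anscombe_or <- function(table) {
  a <- table[["a"]]; b <- table[["b"]]; cc <- table[["c"]]; d <- table[["d"]]
  if (min(a, b, cc, d) < 0) stop_value("contingency table has a negative cell")
  (a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5))
}

#' Term enrichment for one E3 family
#'
#' Tests every term annotated to at least `min_genes` family members:
#' builds the 2x2 table against the universe, computes the one-sided Fisher
#' p, adjusts across exactly the tested terms with Benjamini-Hochberg (the
#' adjustment is per family, never global) and reports the
#' Haldane-Anscombe odds ratio.
#'
#' @param family family name (carried into the output).
#' @param family_genes character vector of family gene symbols (subset of
#'   the universe).
#' @param annotations an `annotation_map` from [propagate_annotations()].
#' @param min_genes minimum family genes annotated with a term for the term
#'   to be tested (default 3).
#' @return tibble with columns `family`, `term`, `a`, `b`, `c`, `d`, `p`,
#'   `p_adj`, `odds_ratio`, ordered by `p`.
#' @export
enrich_family <- function(family, family_genes, annotations, min_genes = 3) {
  stopifnot(inherits(annotations, "annotation_map"))
  family_genes <- unique(canon_symbol(family_genes))
  if (length(family_genes) == 0) stop_value("family gene set is empty")
  family_genes <- intersect(family_genes, annotations$universe)
  terms <- names(annotations$term_genes)
  rows <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    tg <- annotations$term_genes[[i]]
    a <- length(intersect(family_genes, tg))
    if (a < min_genes) next
    tab <- build_table(family_genes, tg, annotations$universe_size)
    rows[[i]] <- tibble::tibble(
      family = family, term = terms[i],
      a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
      p = fisher_one_sided(tab), odds_ratio = haldane_anscombe_or(tab))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble::tibble(family = character(), term = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), p = numeric(), p_adj = numeric(),
                          odds_ratio = numeric()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), c("family", "term", "a", "b", "c", "d",
                                       "p", "p_adj", "odds_ratio")]
  out
}

#' Term enrichment for several families at once
#'
#' Runs [enrich_family()] per family; the BH adjustment is computed within
#' each family over its own tested terms.
#'
#' @param family_sets named list mapping family name to its gene set.
#' @inheritParams enrich_family
#' @return row-bound tibble of per-family results.
#' @export
enrich_families <- function(family_sets, annotations, min_genes = 3) {
  out <- lapply(names(family_sets), function(f) {
    enrich_family(f, family_sets[[f]], annotations, min_genes = min_genes)
  })
  do.call(rbind, out)
}

#' Read a gene-term annotation table
#'
#' @param path TSV with columns `gene` and `term`.
#' @param sep field separator.
#' @return named list mapping term id to gene symbols (direct annotations).
#' @export
read_annotations <- function(path, sep = "\t") {
  df <- read_table_file(path, sep)
  require_columns(df, c("gene", "term"), "annotation table")
  split(canon_symbol(df$gene), as.character(df$term))
}
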