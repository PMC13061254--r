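#' Confidence scoring, categories and family classification
#'
#' A gene's confidence score sums per-curator assessments (+5 per inclusion,
#' -5 per exclusion by default) and +2 per distinct line of supporting
#' evidence (a domain annotation, an interaction report, a literature motif).
#' Categories partition genes into 1 (at least one curator included the
#' gene), 2 (no curator inclusion but some reported evidence) and 3 (neither).
#' Family classification is rule-based: a shipped rule file maps each family
#' to the domain/motif claims and interaction partners that qualify a gene.
#'
#' @name curation
NULL

FAMILY_NAMES <- c("RING", "dRING", "HECT", "RBR", "atypical",
                  "CRL1_SR", "CRL2_SR", "CRL3_SR", "CRL4_SR", "CRL5_SR",
                  "APCC_SR", "pseudo")

#' Score weights for the confidence score
#'
#' @param w_yes weight of a curator "yes" vote (> 0).
#' @param w_no weight of a curator "no" vote (< 0).
#' @param w_evidence weight of each distinct evidence item (> 0).
#' @return a `score_weights` list.
#' @export
score_weights <- function(w_yes = 5L, w_no = -5L, w_evidence = 2L) {
  if (w_yes <= 0) stop_value("w_yes must be positive")
  if (w_no >= 0) stop_value("w_no must be negative")
  if (w_evidence <= 0) stop_value("w_evidence must be positive")
  structure(list(w_yes = as.integer(w_yes), w_no = as.integer(w_no),
                 w_evidence = as.integer(w_evidence)),
            class = "score_weights")
}

#' Load family classification rules
#'
#' Rules are data, not code: a YAML file maps each family to `domains`,
#' `motifs`, `partners` (each sufficient for membership) and `supporting`
#' (tallied but not sufficient). The default file shipped with the package
#' encodes the standard E3 family criteria (RING/dRING/HECT/RBR catalytic
#' domains; F-box, BC-box-CUL2-box, BTB + 3-box, helix-loop-helix and
#' SOCS-box substrate-receptor motifs with their Cullin/adaptor partners).
#'
#' @param path YAML rule file; defaults to the file shipped with the package.
#' @return a named list of rules, class `family_rules`.
#' @export
load_family_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "family_rules.yaml", package = "e3ome",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stop_value("rule file defines no families")
  rules <- lapply(raw, function(r) {
    list(domains = as.character(r$domains %||% character()),
         motifs = as.character(r$motifs %||% character()),
         partners = canon_symbol(as.character(r$partners %||% character())),
         supporting = as.character(r$supporting %||% character()))
  })
  structure(rules, class = "family_rules")
}

# votes relevant to a family context: context "any" sees every vote; a named
# context sees votes cast in that family plus votes cast without a family
votes_in_context <- function(ledger, gene, family_context) {
  v <- ledger$votes[ledger$votes$gene == gene, , drop = FALSE]
  if (identical(family_context, "any")) return(v)
  v[v$family %in% c(family_context, "any"), , drop = FALSE]
}

# evidence relevant to a family context under a rule set
evidence_in_context <- function(ledger, gene, family_context, rules) {
  e <- ledger$evidence[ledger$evidence$gene == gene, , drop = FALSE]
  if (identical(family_context, "any") || nrow(e) == 0) return(e)
  rule <- rules[[family_context]]
  if (is.null(rule)) stop_lookup(sprintf("unknown family context: %s", family_context))
  claims <- unique(c(rule$domains, rule$motifs, rule$partners, rule$supporting))
  e[e$claim %in% claims, , drop = FALSE]
}

check_gene <- function(gene, ledger) {
  sym <- resolve_symbol(gene, ledger)
  if (is.na(sym)) stop_lookup(sprintf("unknown gene: %s", gene))
  sym
}

#' Compute the confidence score of a gene
#'
#' `score = w_yes * n_yes + w_no * n_no + w_evidence * n_evidence`, where
#' `n_evidence` counts distinct `(source, claim)` evidence pairs relevant to
#' the family context ("any" counts every item). Inconclusive and unassessed
#' votes contribute 0. With `cap_votes = TRUE`, at most one yes and one no
#' vote are counted per gene.
#'
#' @param gene gene symbol or alias.
#' @param ledger an `e3_ledger`.
#' @param weights a [score_weights()] object.
#' @param family_context family name or `"any"` (default).
#' @param rules [load_family_rules()] output; required for named contexts.
#' @param cap_votes count at most one yes and one no vote per gene.
#' @return integer score.
#' @examples
#' led <- new_ledger(
#'   data.frame(symbol = "SKP2"),
#'   votes = data.frame(symbol = "SKP2", curator = "c1",
#'                      family = "CRL1_SR", verdict = "yes"),
#'   evidence = data.frame(symbol = "SKP2", source = "interpro_domain",
#'                         claim = "F-box"))
#' score_gene("SKP2", led)  # 5 + 2 = 7
#' @export
score_gene <- function(gene, ledger, weights = score_weights(),
                       family_context = "any", rules = NULL,
                       cap_votes = FALSE) {
  sym <- check_gene(gene, ledger)
  if (!identical(family_context, "any") && is.null(rules)) {
    rules <- load_family_rules()
  }
  v <- votes_in_context(ledger, sym, family_context)
  n_yes <- sum(v$verdict == "yes")
  n_no <- sum(v$verdict == "no")
  if (cap_votes) {
    n_yes <- min(n_yes, 1L)
    n_no <- min(n_no, 1L)
  }
  e <- evidence_in_context(ledger, sym, family_context, rules)
  n_evid <- nrow(unique(e[, c("source", "claim")]))
  as.integer(weights$w_yes * n_yes + weights$w_no * n_no +
             weights$w_evidence * n_evid)
}

#' Assign the confidence category of a gene
#'
#' Category 1: at least one curator voted yes (in the family context).
#' Category 2: no yes vote, but at least one evidence item. Category 3:
#' neither. By default category 2 considers evidence of any kind
#' (`evidence_scope = "any"`); with `"family"` only evidence matching the
#' family context's rule claims counts.
#'
#' @inheritParams score_gene
#' @param evidence_scope `"any"` (default) or `"family"`.
#' @return integer category in `1:3`.
#' @export
assign_category <- function(gene, ledger, family_context = "any",
                            rules = NULL, evidence_scope = c("any", "family")) {
  evidence_scope <- match.arg(evidence_scope)
  sym <- check_gene(gene, ledger)
  v <- votes_in_context(ledger, sym, family_context)
  if (any(v$verdict == "yes")) return(1L)
  if (evidence_scope == "any") {
    e <- ledger$evidence[ledger$evidence$gene == sym, , drop = FALSE]
  } else {
    if (!identical(family_context, "any") && is.null(rules)) rules <- load_family_rules()
    e <- evidence_in_context(ledger, sym, family_context, rules)
  }
  if (nrow(e) > 0) return(2L)
  3L
}

#' Score and categorize every gene in a ledger
#'
#' @inheritParams score_gene
#' @return a ranked tibble with columns `gene`, `score`, `category`, `rank`.
#' @export
score_ledger <- function(ledger, weights = score_weights(),
                         family_context = "any", rules = NULL,
                         cap_votes = FALSE) {
  genes <- ledger$genes$symbol
  res <- tibble::tibble(
    gene = genes,
    score = vapply(genes, score_gene, integer(1), ledger = ledger,
                   weights = weights, family_context = family_context,
                   rules = rules, cap_votes = cap_votes),
    category = vapply(genes, assign_category, integer(1), ledger = ledger,
                      family_context = family_context, rules = rules)
  )
  rank_genes(res)
}

#' Rank confidence results from high to low score
#'
#' Descending by score; ties broken by category (ascending) then by symbol
#' (lexicographic), so the ordering is deterministic.
#'
#' @param results tibble with columns `gene`, `score`, `category`.
#' @return the same tibble ordered, with a `rank` column (1 = highest).
#' @export
rank_genes <- function(results) {
  require_columns(results, c("gene", "score", "category"), "confidence results")
  ord <- order(-results$score, results$category, results$gene)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

# claims of a rule that are sufficient for membership, and all claims tallied
rule_sufficient <- function(rule) unique(c(rule$domains, rule$motifs, rule$partners))
rule_all_claims <- function(rule) unique(c(rule_sufficient(rule), rule$supporting))

#' Classify a gene into E3 families
#'
#' A gene is assigned to every family for which (a) any of the family's
#' sufficient rule claims is present in the gene's evidence, or (b) a curator
#' cast a yes/no vote in that family context. The assignment tier is `high`
#' when the gene is category 1 within the family context and `low` otherwise.
#' A gene may hold several assignments (e.g. a dual F-box plus
#' helix-loop-helix substrate receptor is both CRL1_SR and CRL4_SR).
#'
#' @inheritParams score_gene
#' @param rules a `family_rules` object (defaults to the shipped rule file).
#' @return tibble with columns `gene`, `family`, `tier` and a list-column
#'   `support` (named logical: which rule claims have evidence).
#' @export
classify_family <- function(gene, ledger, rules = load_family_rules()) {
  if (length(rules) == 0) stop_value("empty family rule set")
  sym <- check_gene(gene, ledger)
  ev <- ledger$evidence[ledger$evidence$gene == sym, , drop = FALSE]
  votes <- ledger$votes[ledger$votes$gene == sym, , drop = FALSE]
  rows <- list()
  for (fam in names(rules)) {
    rule <- rules[[fam]]
    claims <- rule_all_claims(rule)
    support <- stats::setNames(claims %in% ev$claim, claims)
    evidence_hit <- any(rule_sufficient(rule) %in% ev$claim)
    vote_hit <- any(votes$family == fam & votes$verdict %in% c("yes", "no"))
    if (!evidence_hit && !vote_hit) next
    tier <- if (assign_category(sym, ledger, family_context = fam,
                                rules = rules) == 1L) "high" else "low"
    rows[[fam]] <- tibble::tibble(gene = sym, family = fam, tier = tier,
                                  support = list(support))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(gene = character(), family = character(),
                          tier = character(), support = list()))
  }
  do.call(rbind, rows)
}

#' Enumerate families with Sankey-style stage tallies
#'
#' For each family: the number of input genes (genes assigned to the family),
#' the number of input genes carrying each rule claim, and the split into
#' high- and low-confidence genes. High + low always equals input.
#'
#' @param ledger an `e3_ledger`.
#' @param rules a `family_rules` object.
#' @return tibble with columns `family`, `input`, `high`, `low` and a
#'   list-column `claim_counts` (named integer).
#' @export
enumerate_families <- function(ledger, rules = load_family_rules()) {
  if (length(rules) == 0) stop_value("empty family rule set")
  assignments <- lapply(ledger$genes$symbol, classify_family,
                        ledger = ledger, rules = rules)
  assignments <- do.call(rbind, assignments)
  fams <- if (is.null(assignments) || nrow(assignments) == 0) {
    character()
  } else {
    sort(unique(assignments$family))
  }
  rows <- lapply(fams, function(fam) {
    d <- assignments[assignments$family == fam, , drop = FALSE]
    claims <- rule_all_claims(rules[[fam]])
    counts <- stats::setNames(integer(length(claims)), claims)
    for (s in d$support) counts <- counts + as.integer(s[claims])
    tibble::tibble(family = fam, input = nrow(d),
                   high = sum(d$tier == "high"), low = sum(d$tier == "low"),
                   claim_counts = list(counts))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(family = character(), input = integer(),
                          high = integer(), low = integer(),
                          claim_counts = list()))
  }
  do.call(rbind, rows)
}

#' Pairwise overlap matrix between gene lists
#'
#' `cell(i, j) = 100 * |Li intersect Lj| / |Li|` (row-normalized, so the
#' matrix is asymmetric between lists of different sizes and the diagonal is
#' always 100). With `normalize = "min"` the denominator is the smaller list.
#'
#' @param gene_lists named list of at least two non-empty character vectors.
#' @param normalize `"row"` (default) or `"min"`.
#' @return square numeric matrix of percentages with list names as dimnames.
#' @export
pairwise_overlap <- function(gene_lists, normalize = c("row", "min")) {
  normalize <- match.arg(normalize)
  if (length(gene_lists) < 2) stop_value("need at least two gene lists")
  gene_lists <- lapply(gene_lists, function(x) unique(canon_symbol(x)))
  if (any(lengths(gene_lists) == 0)) stop_value("gene lists must be non-empty")
  n <- length(gene_lists)
  nm <- names(gene_lists) %||% paste0("list", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      inter <- length(intersect(gene_lists[[i]], gene_lists[[j]]))
      denom <- if (normalize == "row") length(gene_lists[[i]]) else
        min(length(gene_lists[[i]]), length(gene_lists[[j]]))
      m[i, j] <- 100 * inter / denom
    }
  }
  m
}

#' Intersect a curated panel with an external gene set
#'
#' Both sets are alias-resolved against the ledger before intersection, so a
#' list naming a gene by an alias still intersects its canonical symbol.
#'
#' @param panel character vector of panel symbols.
#' @param external character vector of external symbols.
#' @param ledger optional `e3_ledger` used for alias resolution.
#' @return sorted character vector of shared canonical symbols.
#' @export
intersect_panel <- function(panel, external, ledger = NULL) {
  resolve <- function(x) {
    x <- canon_symbol(x)
    if (is.null(ledger)) return(x)
    vapply(x, function(t) {
      r <- resolve_symbol(t, ledger)
      if (is.na(r)) t else r
    }, character(1), USE.NAMES = FALSE)
  }
  sort(intersect(unique(resolve(panel)), unique(resolve(external))))
}
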