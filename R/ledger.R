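#' Evidence ledger for E3 candidate genes
#'
#' The ledger is the substrate of confidence scoring and family classification.
#' It holds gene records (HGNC-style symbols with aliases), curator votes
#' (yes / no / inconclusive / unassessed, optionally tied to a family context)
#' and typed evidence items (InterPro-style domain claims, BioGRID-style
#' interaction partners, literature motif annotations).
#'
#' @name e3_ledger
NULL

VERDICTS <- c("yes", "no", "inconclusive", "unassessed")
EVIDENCE_SOURCES <- c("interpro_domain", "biogrid_interaction", "literature_annotation")

#' Construct an evidence ledger from in-memory tables
#'
#' Symbols are canonicalized to uppercase with whitespace stripped. Rows are
#' stored in a canonical sort order so that ledgers built from permuted inputs
#' compare equal with [identical()].
#'
#' @param genes data frame with columns `symbol`, `aliases` (list of character
#'   vectors or pipe-delimited strings) and `protein_coding` (logical or 0/1).
#' @param votes data frame with columns `symbol`, `curator`, `family`,
#'   `verdict`. A missing/empty `family` defaults to `"any"`.
#' @param evidence data frame with columns `symbol`, `source`, `claim` and
#'   optionally `reference`.
#' @return an object of class `e3_ledger`: a list with tibbles `genes`,
#'   `votes`, `evidence`, a tibble `rejected` of rows whose symbol could not
#'   be resolved, and the internal alias map.
#' @export
new_ledger <- function(genes, votes = NULL, evidence = NULL) {
  genes <- tibble::as_tibble(genes)
  require_columns(genes, c("symbol"), "gene table")
  symbol <- canon_symbol(genes$symbol)
  if (any(symbol == "" | is.na(symbol))) stop_value("gene table contains an empty symbol")
  if (anyDuplicated(symbol)) stop_value("gene table contains duplicate symbols")

  aliases <- genes[["aliases"]] %||% vector("list", nrow(genes))
  if (!is.list(aliases)) {
    aliases <- strsplit(ifelse(is.na(aliases), "", as.character(aliases)), "|", fixed = TRUE)
  }
  aliases <- lapply(seq_along(aliases), function(i) {
    a <- canon_symbol(aliases[[i]])
    a <- setdiff(a[nzchar(a)], symbol[i])  # a symbol is never its own alias
    sort(unique(a))
  })
  pc <- genes[["protein_coding"]] %||% rep(TRUE, nrow(genes))
  if (is.character(pc)) pc <- trimws(tolower(pc)) %in% c("1", "true", "yes")
  pc <- as.logical(pc)
  pc[is.na(pc)] <- TRUE

  ord <- order(symbol)
  gene_tbl <- tibble::tibble(symbol = symbol[ord], aliases = aliases[ord],
                             protein_coding = pc[ord])

  # alias map: token -> canonical symbol(s); ambiguity is detected lazily in
  # resolve_symbol(), but cross-gene alias clashes with a symbol are an error
  alias_tok <- unlist(gene_tbl$aliases, use.names = FALSE)
  alias_sym <- rep(gene_tbl$symbol, lengths(gene_tbl$aliases))
  amap <- split(alias_sym, alias_tok)
  clash <- intersect(names(amap), gene_tbl$symbol)
  clash <- clash[vapply(clash, function(t) !all(amap[[t]] == t), logical(1))]
  if (length(clash) > 0) {
    stop_value(sprintf("alias collides with another gene's symbol: %s",
                       paste(clash, collapse = ", ")))
  }

  ledger <- structure(list(genes = gene_tbl,
                           votes = empty_votes(),
                           evidence = empty_evidence(),
                           rejected = empty_rejected(),
                           alias_map = amap),
                      class = "e3_ledger")

  if (!is.null(votes) && nrow(votes) > 0) ledger <- ledger_add_votes(ledger, votes)
  if (!is.null(evidence) && nrow(evidence) > 0) ledger <- ledger_add_evidence(ledger, evidence)
  ledger
}

empty_votes <- function() {
  tibble::tibble(gene = character(), curator = character(),
                 family = character(), verdict = character())
}
empty_evidence <- function() {
  tibble::tibble(gene = character(), source = character(),
                 claim = character(), reference = character())
}
empty_rejected <- function() {
  tibble::tibble(table = character(), row = integer(), symbol = character(),
                 reason = character())
}

resolve_many <- function(tokens, ledger, table, rows) {
  out <- rep(NA_character_, length(tokens))
  rejected <- empty_rejected()
  for (i in seq_along(tokens)) {
    res <- tryCatch(resolve_symbol(tokens[i], ledger),
                    e3ome_ambiguity_error = function(e) conditionMessage(e))
    if (is.na(res) || (!is.na(res) && !res %in% ledger$genes$symbol)) {
      rejected <- rbind(rejected,
                        tibble::tibble(table = table, row = rows[i],
                                       symbol = tokens[i],
                                       reason = if (is.na(res)) "unresolvable symbol" else res))
    } else {
      out[i] <- res
    }
  }
  list(symbol = out, rejected = rejected)
}

ledger_add_votes <- function(ledger, votes) {
  votes <- tibble::as_tibble(votes)
  require_columns(votes, c("symbol", "curator", "verdict"), "vote table")
  fam <- votes[["family"]] %||% rep("any", nrow(votes))
  fam <- trimws(as.character(fam))
  fam[is.na(fam) | fam == ""] <- "any"
  verdict <- trimws(tolower(as.character(votes$verdict)))
  bad <- which(!verdict %in% VERDICTS)
  if (length(bad) > 0) {
    stop_value(sprintf(
      "vote table row %d: verdict '%s' is not one of {%s}",
      bad[1], verdict[bad[1]], paste(VERDICTS, collapse = ", ")))
  }
  res <- resolve_many(canon_symbol(votes$symbol), ledger, "votes", seq_len(nrow(votes)))
  keep <- !is.na(res$symbol)
  v <- tibble::tibble(gene = res$symbol[keep],
                      curator = trimws(as.character(votes$curator[keep])),
                      family = fam[keep], verdict = verdict[keep])
  v <- unique(v)
  key <- paste(v$gene, v$curator, v$family, sep = "\r")
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    stop_value(sprintf("conflicting verdicts for the same (gene, curator, family): %s",
                       gsub("\r", " / ", k)))
  }
  v <- v[order(v$gene, v$curator, v$family), ]
  ledger$votes <- rbind(ledger$votes, v)
  ledger$rejected <- rbind(ledger$rejected, res$rejected)
  ledger
}

ledger_add_evidence <- function(ledger, evidence) {
  evidence <- tibble::as_tibble(evidence)
  require_columns(evidence, c("symbol", "source", "claim"), "evidence table")
  src <- trimws(tolower(as.character(evidence$source)))
  bad <- which(!src %in% EVIDENCE_SOURCES)
  if (length(bad) > 0) {
    stop_value(sprintf(
      "evidence table row %d: source '%s' is not one of {%s}",
      bad[1], src[bad[1]], paste(EVIDENCE_SOURCES, collapse = ", ")))
  }
  res <- resolve_many(canon_symbol(evidence$symbol), ledger, "evidence",
                      seq_len(nrow(evidence)))
  keep <- !is.na(res$symbol)
  ref <- evidence[["reference"]] %||% rep(NA_character_, nrow(evidence))
  e <- tibble::tibble(gene = res$symbol[keep], source = src[keep],
                      claim = trimws(as.character(evidence$claim[keep])),
                      reference = as.character(ref)[keep])
  key <- paste(e$gene, e$source, e$claim, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate evidence row(s)", sum(dup)),
            call. = FALSE)
    e <- e[!dup, ]
  }
  e <- e[order(e$gene, e$source, e$claim), ]
  ledger$evidence <- rbind(ledger$evidence, e)
  ledger$rejected <- rbind(ledger$rejected, res$rejected)
  ledger
}

#' Load an evidence ledger from tabular files
#'
#' Reads a gene table, a curator-vote table and one or more evidence tables
#' (all delimited text with a header row) and returns a validated
#' [new_ledger()] object. Unresolvable symbols are collected into the
#' `rejected` tibble of the result rather than raising an error; duplicate
#' `(gene, source, claim)` evidence rows are collapsed with a warning.
#'
#' Expected columns: gene table `symbol`, `aliases` (pipe-delimited),
#' `protein_coding` (0/1); vote table `symbol`, `curator`, `family`,
#' `verdict`; evidence tables `symbol`, `source`, `claim`, `reference`.
#'
#' @param gene_table path to the gene table.
#' @param vote_table path to the curator vote table (optional).
#' @param evidence_tables character vector of evidence table paths (optional).
#' @param sep field separator, `"\t"` by default; pass `","` for CSV input.
#' @return an `e3_ledger`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("symbol\taliases\tprotein_coding",
#'              "RNF31\tHOIP\t1", "SKP2\t\t1"), file.path(dir, "genes.tsv"))
#' writeLines(c("symbol\tcurator\tfamily\tverdict",
#'              "RNF31\tc1\tRING\tyes"), file.path(dir, "votes.tsv"))
#' led <- load_ledger(file.path(dir, "genes.tsv"), file.path(dir, "votes.tsv"))
#' resolve_symbol("hoip", led)
#' @export
load_ledger <- function(gene_table, vote_table = NULL, evidence_tables = character(),
                        sep = "\t") {
  genes <- read_table_file(gene_table, sep)
  require_columns(genes, c("symbol"), "gene table")
  ledger <- new_ledger(genes)
  if (!is.null(vote_table)) {
    ledger <- ledger_add_votes(ledger, read_table_file(vote_table, sep))
  }
  for (path in evidence_tables) {
    ledger <- ledger_add_evidence(ledger, read_table_file(path, sep))
  }
  ledger
}

#' Resolve a symbol or alias to its canonical gene symbol
#'
#' Matching is case-insensitive over both primary symbols and aliases. A token
#' matching the alias sets of two distinct genes raises an ambiguity error
#' listing the candidates.
#'
#' @param token character token to resolve.
#' @param ledger an `e3_ledger`.
#' @return the canonical symbol, or `NA_character_` if there is no match.
#' @export
resolve_symbol <- function(token, ledger) {
  stopifnot(inherits(ledger, "e3_ledger"), length(token) == 1)
  tok <- canon_symbol(token)
  if (is.na(tok) || tok == "") return(NA_character_)
  if (tok %in% ledger$genes$symbol) return(tok)
  hits <- unique(ledger$alias_map[[tok]])
  if (is.null(hits) || length(hits) == 0) return(NA_character_)
  if (length(hits) > 1) {
    stop_ambiguity(sprintf("token '%s' is ambiguous between: %s",
                           token, paste(sort(hits), collapse = ", ")))
  }
  hits
}

#' @export
print.e3_ledger <- function(x, ...) {
  cat(sprintf("<e3_ledger> %d genes, %d votes, %d evidence items",
              nrow(x$genes), nrow(x$votes), nrow(x$evidence)))
  if (nrow(x$rejected) > 0) cat(sprintf(", %d rejected rows", nrow(x$rejected)))
  cat("\n")
  invisible(x)
}

#' Read a curated compendium exported sheet-per-family
#'
#' The deposited compendium workbook stores one sheet per E3 family with, at
#' minimum, a gene symbol column, a confidence category column and per-source
#' evidence flags. This reader consumes the workbook exported as one delimited
#' text file per sheet (file name = family name) behind a tolerant
#' column-mapping layer: columns are located case-insensitively by the
#' patterns `symbol|gene`, `category`, `interpro|domain`, `biogrid|interaction`
#' and `literature|motif`.
#'
#' @param dir directory containing one `<FAMILY>.tsv` file per family sheet.
#' @param sep field separator.
#' @return a tibble with columns `family`, `symbol`, `category` (integer or
#'   NA) and logical evidence flags `interpro`, `biogrid`, `literature`.
#' @seealso [compendium_counts()] to tally per-family and per-category counts.
#' @export
read_compendium <- function(dir, sep = "\t") {
  files <- sort(list.files(dir, pattern = "\\.(tsv|csv|txt)$", full.names = TRUE))
  if (length(files) == 0) stop_schema(sprintf("no sheet files found under %s", dir))
  find_col <- function(nm, pattern) {
    hit <- grep(pattern, nm, ignore.case = TRUE)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  out <- lapply(files, function(f) {
    df <- read_table_file(f, sep)
    nm <- names(df)
    si <- find_col(nm, "symbol|^gene")
    if (is.na(si)) stop_schema(sprintf("sheet %s has no symbol/gene column", basename(f)))
    ci <- find_col(nm, "categ")
    flag <- function(i) {
      if (is.na(i)) return(rep(NA, nrow(df)))
      v <- df[[i]]
      if (is.logical(v)) v else !(is.na(v) | v %in% c("", "0", "no", "FALSE", 0))
    }
    tibble::tibble(
      family = sub("\\.[^.]+$", "", basename(f)),
      symbol = canon_symbol(df[[si]]),
      category = if (is.na(ci)) NA_integer_ else suppressWarnings(as.integer(df[[ci]])),
      interpro = flag(find_col(nm, "interpro|domain")),
      biogrid = flag(find_col(nm, "biogrid|interaction")),
      literature = flag(find_col(nm, "literature|motif"))
    )
  })
  do.call(rbind, out)
}

#' Tally a compendium table by family and confidence category
#'
#' @param compendium tibble from [read_compendium()].
#' @return a tibble with one row per family: `input` genes, `n_category1`,
#'   `n_category2`, `n_category3`, and per-source evidence counts.
#' @export
compendium_counts <- function(compendium) {
  fams <- sort(unique(compendium$family))
  rows <- lapply(fams, function(f) {
    d <- compendium[compendium$family == f, ]
    tibble::tibble(family = f, input = nrow(d),
                   n_category1 = sum(d$category == 1, na.rm = TRUE),
                   n_category2 = sum(d$category == 2, na.rm = TRUE),
                   n_category3 = sum(d$category == 3, na.rm = TRUE),
                   n_interpro = sum(d$interpro, na.rm = TRUE),
                   n_biogrid = sum(d$biogrid, na.rm = TRUE),
                   n_literature = sum(d$literature, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
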