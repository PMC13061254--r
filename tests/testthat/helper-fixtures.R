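# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (enumeration, direct formulas) and never call the
# package functions they are used to check.

# --- toy ledger -------------------------------------------------------------

toy_ledger <- function() {
  new_ledger(
    data.frame(symbol = c("RNF31", "SKP2", "FBXW5"),
               aliases = c("HOIP", "", ""),
               protein_coding = 1),
    votes = data.frame(symbol = c("RNF31", "SKP2"),
                       curator = "c1",
                       family = c("RING", "CRL1_SR"),
                       verdict = "yes"),
    evidence = data.frame(
      symbol = c("RNF31", "SKP2", "SKP2", "FBXW5"),
      source = c("interpro_domain", "interpro_domain",
                 "biogrid_interaction", "interpro_domain"),
      claim = c("RING", "F-box", "CUL1", "F-box")))
}

write_toy_ledger_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("symbol\taliases\tprotein_coding",
               "RNF31\tHOIP\t1",
               "SKP2\t\t1",
               "FBXW5\t\t1"),
             file.path(dir, "genes.tsv"))
  writeLines(c("symbol\tcurator\tfamily\tverdict",
               "RNF31\tc1\tRING\tyes",
               "SKP2\tc1\tCRL1_SR\tyes"),
             file.path(dir, "votes.tsv"))
  writeLines(c("symbol\tsource\tclaim\treference",
               "RNF31\tinterpro_domain\tRING\tIPR001841",
               "SKP2\tinterpro_domain\tF-box\tIPR001810",
               "SKP2\tbiogrid_interaction\tCUL1\tBG1",
               "FBXW5\tinterpro_domain\tF-box\tIPR001810"),
             file.path(dir, "evidence.tsv"))
  c(genes = file.path(dir, "genes.tsv"),
    votes = file.path(dir, "votes.tsv"),
    evidence = file.path(dir, "evidence.tsv"))
}

# --- statistical oracles ----------------------------------------------------

# upper-tail Fisher p by exhaustive enumeration over all tables with the
# observed margins, using exact rational-style products (no lgamma shortcut)
oracle_fisher_upper <- function(a, b, cc, d) {
  n_fam <- a + b
  n_term <- a + cc
  n_tot <- a + b + cc + d
  ks <- max(0, n_fam + n_term - n_tot):min(n_fam, n_term)
  probs <- vapply(ks, function(k) {
    choose(n_term, k) * choose(n_tot - n_term, n_fam - k) / choose(n_tot, n_fam)
  }, numeric(1))
  sum(probs[ks >= a])
}

# direct BH step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m], 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exhaustive two-sided rank-sum p over all group assignments
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  mu <- n1 * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  splits <- utils::combn(length(pooled), n1)
  sums <- apply(splits, 2, function(idx) sum(r[idx]))
  mean(abs(sums - mu) >= obs - 1e-9)
}

# brute-force ancestor closure: term -> union of its own and all
# descendants' direct annotations, via repeated edge relaxation
oracle_propagate <- function(edges, direct, ids) {
  sets <- stats::setNames(lapply(ids, function(i) direct[[i]] %||% character()),
                          ids)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      ch <- edges$child[k]; pa <- edges$parent[k]
      merged <- union(sets[[pa]], sets[[ch]])
      if (length(merged) != length(sets[[pa]])) {
        sets[[pa]] <- merged
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(sets, sort)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
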