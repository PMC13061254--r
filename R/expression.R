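#' Expression profiling: donor sampling, normalisation, marker detection
#'
#' Count matrices move through labelled layers (`raw` -> `auc_scaled` or
#' `cp10k` -> `log1p`); each operation refuses a matrix tagged with the
#' wrong layer, so a pipeline cannot silently normalise twice.
#'
#' @name expression_profiling
NULL

#' Construct a layered count matrix
#'
#' @param values numeric matrix (genes x samples/cells), or a sparse
#'   `Matrix`; must carry row and column names.
#' @param layer one of `"raw"`, `"auc_scaled"`, `"cp10k"`, `"log1p"`.
#' @return an `e3_counts` object.
#' @export
e3_counts <- function(values, layer = "raw") {
  layer <- match.arg(layer, c("raw", "auc_scaled", "cp10k", "log1p"))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_value("count matrix needs row (gene) and column (sample/cell) names")
  }
  if (any(values < 0, na.rm = TRUE)) stop_value("count matrix has negative entries")
  structure(list(values = values, layer = layer), class = "e3_counts")
}

#' @export
print.e3_counts <- function(x, ...) {
  cat(sprintf("<e3_counts> %d genes x %d columns, layer '%s'\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.e3_counts <- function(x) dim(x$values)

assert_layer <- function(m, allowed, op) {
  stopifnot(inherits(m, "e3_counts"))
  if (!m$layer %in% allowed) {
    stop_value(sprintf("%s expects layer %s, got '%s'",
                       op, paste(sQuote(allowed), collapse = " or "), m$layer))
  }
  invisible(m)
}

#' Retain one sample per donor and a fixed number of donors per tissue
#'
#' Enforces donor exclusivity (donors contributing samples to more than one
#' tissue are dropped), keeps one sample per donor (the lexicographically
#' smallest sample id), then draws exactly `per_tissue` donors per tissue
#' without replacement. Tissues and donors are processed in sorted order and
#' the draw uses one Mersenne-Twister stream seeded once, so the selection
#' is identical for a fixed seed.
#'
#' @param metadata tibble with columns `sample`, `donor`, `tissue`.
#' @param per_tissue donors to draw per tissue (default 9).
#' @param seed RNG seed (default 42).
#' @return the retained metadata rows (one per selected donor), sorted by
#'   tissue then donor.
#' @export
sample_donors <- function(metadata, per_tissue = 9, seed = 42) {
  metadata <- tibble::as_tibble(metadata)
  require_columns(metadata, c("sample", "donor", "tissue"), "sample metadata")
  metadata$sample <- as.character(metadata$sample)
  metadata$donor <- as.character(metadata$donor)
  metadata$tissue <- as.character(metadata$tissue)

  # donor exclusivity: drop donors seen in more than one tissue
  dt <- unique(metadata[, c("donor", "tissue")])
  multi <- unique(dt$donor[duplicated(dt$donor)])
  metadata <- metadata[!metadata$donor %in% multi, , drop = FALSE]

  # one sample per donor: lexicographically smallest sample id
  metadata <- metadata[order(metadata$donor, metadata$sample), , drop = FALSE]
  metadata <- metadata[!duplicated(metadata$donor), , drop = FALSE]

  tissues <- sort(unique(metadata$tissue))
  short <- tissues[vapply(tissues, function(t) {
    sum(metadata$tissue == t) < per_tissue
  }, logical(1))]
  if (length(short) > 0) {
    stop_capacity(sprintf(
      "tissue(s) with fewer than %d eligible donors: %s",
      per_tissue, paste(short, collapse = ", ")))
  }

  picked <- with_local_seed(seed, {
    unlist(lapply(tissues, function(t) {
      donors <- sort(metadata$donor[metadata$tissue == t])
      sample(donors, per_tissue, replace = FALSE)
    }))
  })
  out <- metadata[metadata$donor %in% picked, , drop = FALSE]
  out[order(out$tissue, out$donor), , drop = FALSE]
}

#' Scale columns to a common library size from area-under-coverage values
#'
#' Each column is multiplied by `target / auc[column]`, placing
#' coverage-level counts on a read-count scale; values are not rounded.
#'
#' @param matrix an `e3_counts` with layer `raw`.
#' @param auc_per_sample named positive numeric: AUC per column.
#' @param target common library size (default `4e7`).
#' @return an `e3_counts` with layer `auc_scaled`.
#' @export
auc_scale <- function(matrix, auc_per_sample, target = 4e7) {
  assert_layer(matrix, "raw", "auc_scale")
  cols <- colnames(matrix$values)
  auc <- auc_per_sample[cols]
  if (any(is.na(auc))) stop_value("missing AUC value for some columns")
  if (any(auc <= 0)) stop_value("AUC values must be positive")
  scaled <- sweep(matrix$values, 2, target / as.numeric(auc), `*`)
  e3_counts(scaled, layer = "auc_scaled")
}

#' Restrict a count matrix to a gene panel
#'
#' Rows are subset in panel order; panel genes absent from the matrix are
#' reported via the `missing` attribute and a message, never invented.
#'
#' @param matrix an `e3_counts` (any layer).
#' @param panel character vector of gene symbols.
#' @return an `e3_counts` restricted to the panel genes present, with
#'   attribute `missing` naming absent panel genes.
#' @export
restrict_panel <- function(matrix, panel) {
  stopifnot(inherits(matrix, "e3_counts"))
  panel <- unique(canon_symbol(panel))
  present <- panel[panel %in% rownames(matrix$values)]
  missing <- setdiff(panel, present)
  if (length(present) == 0) stop_value("no panel gene is present in the matrix")
  if (length(missing) > 0) {
    message(sprintf("restrict_panel: %d panel gene(s) absent from the matrix",
                    length(missing)))
  }
  out <- e3_counts(matrix$values[present, , drop = FALSE], layer = matrix$layer)
  attr(out, "missing") <- missing
  out
}

#' Normalise each cell to counts per 10,000
#'
#' Non-finite entries are replaced with zeros; each column is scaled by
#' `10000 / max(column sum, clip_min)`, so an all-zero cell stays all-zero
#' instead of dividing by zero.
#'
#' @param matrix an `e3_counts` with layer `raw`.
#' @param clip_min minimum library size (default `1e-12`).
#' @return an `e3_counts` with layer `cp10k`.
#' @export
cp10k_normalize <- function(matrix, clip_min = 1e-12) {
  assert_layer(matrix, "raw", "cp10k_normalize")
  v <- as.matrix(matrix$values)
  v[!is.finite(v)] <- 0
  libs <- pmax(colSums(v), clip_min)
  e3_counts(sweep(v, 2, 1e4 / libs, `*`), layer = "cp10k")
}

#' Natural-log log1p transform
#'
#' @param matrix an `e3_counts` with layer `cp10k`.
#' @return an `e3_counts` with layer `log1p`.
#' @export
log1p_transform <- function(matrix) {
  assert_layer(matrix, "cp10k", "log1p_transform")
  if (any(matrix$values < 0)) stop_value("log1p_transform: negative entries")
  e3_counts(log1p(as.matrix(matrix$values)), layer = "log1p")
}

#' Keep cell classes with enough cells
#'
#' @param labels named character vector mapping cell id to class label.
#' @param min_cells minimum class size, inclusive (default 20).
#' @return character vector of surviving class names.
#' @export
filter_classes <- function(labels, min_cells = 20) {
  if (length(labels) == 0) stop_value("no cell labels supplied")
  counts <- table(labels)
  keep <- names(counts)[counts >= min_cells]
  if (length(keep) == 0) {
    stop_capacity(sprintf("no class has at least %d cells", min_cells))
  }
  sort(keep)
}

# two-sided rank-sum p for one gene; exact by enumeration when both groups
# are small, else normal approximation with tie correction, no continuity
# correction (zero-variance genes return p = 1)
rank_sum_p <- function(x, in_group, exact_max = 8) {
  n <- length(x)
  n1 <- sum(in_group)
  n2 <- n - n1
  r <- rank(x)
  r1 <- sum(r[in_group])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    splits <- utils::combn(n, n1)
    sums <- colSums(base::matrix(r[splits], nrow = n1))
    dev <- abs(r1 - mu)
    return(mean(abs(sums - mu) >= dev - 1e-9))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (r1 - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' One-vs-rest Wilcoxon rank-sum marker detection
#'
#' For each surviving class and each gene, tests the class's cells against
#' all remaining cells pooled (two-sided rank-sum; exact enumeration when
#' both groups have at most `exact_max` cells, otherwise the normal
#' approximation with tie correction and no continuity correction).
#' P-values are Benjamini-Hochberg adjusted across genes within each class.
#' A log2 fold-change `log2((mean_in + eps)/(mean_out + eps))` with
#' `eps = 1e-9` is reported alongside.
#'
#' @param matrix an `e3_counts` with layer `cp10k` or `log1p`.
#' @param labels named character vector mapping column (cell) id to class.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param min_cells minimum class size (default 20; classes below are
#'   dropped before testing).
#' @param exact_max maximum per-group size for exact enumeration.
#' @return tibble with columns `gene`, `group`, `statistic` (z-like signed
#'   deviation of the rank sum), `log2fc`, `p`, `p_adj`, `significant`.
#' @export
wilcoxon_ovr <- function(matrix, labels, alpha = 0.05, min_cells = 20,
                         exact_max = 8) {
  assert_layer(matrix, c("cp10k", "log1p"), "wilcoxon_ovr")
  v <- as.matrix(matrix$values)
  labels <- labels[colnames(v)]
  if (any(is.na(labels))) stop_value("every matrix column needs a class label")
  classes <- filter_classes(labels, min_cells = min_cells)
  if (length(classes) < 2) {
    stop_capacity("need at least two surviving classes for one-vs-rest tests")
  }
  keep <- labels %in% classes
  v <- v[, keep, drop = FALSE]
  labels <- labels[keep]
  eps <- 1e-9
  n <- ncol(v)

  # ranks (and tie terms) do not depend on the focal class: compute once
  ranks <- t(apply(v, 1, rank))
  tie_term <- apply(ranks, 1, function(r) {
    tt <- tabulate(match(r, unique(r)))
    sum(tt^3 - tt) / (n * (n - 1))
  })

  out <- lapply(classes, function(cl) {
    in_group <- labels == cl
    n1 <- sum(in_group)
    if (n1 < 2) {
      warning(sprintf("class '%s' has fewer than 2 cells; skipped", cl),
              call. = FALSE)
      return(NULL)
    }
    n2 <- n - n1
    mu <- n1 * (n + 1) / 2
    r1 <- as.numeric(ranks %*% in_group)
    if (n1 <= exact_max && n2 <= exact_max) {
      p <- vapply(seq_len(nrow(v)), function(g) {
        rank_sum_p(v[g, ], in_group, exact_max = exact_max)
      }, numeric(1))
    } else {
      sigma2 <- unname(n1 * n2 / 12 * ((n + 1) - tie_term))
      z <- ifelse(sigma2 > 0, (r1 - mu) / sqrt(sigma2), 0)
      p <- ifelse(sigma2 > 0, pmin(1, 2 * stats::pnorm(-abs(z))), 1)
    }
    mean_in <- rowMeans(v[, in_group, drop = FALSE])
    mean_out <- rowMeans(v[, !in_group, drop = FALSE])
    p_adj <- bh_adjust(p)
    tibble::tibble(gene = rownames(v), group = cl, statistic = r1 - mu,
                   log2fc = log2((mean_in + eps) / (mean_out + eps)),
                   p = p, p_adj = p_adj, significant = p_adj < alpha)
  })
  do.call(rbind, out)
}

#' Call differentially expressed genes from an (fdr, log2fc) table
#'
#' Significance requires `fdr < fdr_max` (strict) and `|log2fc| >= lfc_min`
#' (inclusive), matching the usual reporting convention.
#'
#' @param results tibble with columns `fdr` and `log2fc` (other columns,
#'   e.g. `gene` and `tissue`, are carried through).
#' @param fdr_max FDR ceiling, strict (default 0.05).
#' @param lfc_min minimum absolute log2 fold-change, inclusive (default 1).
#' @return the input with a logical `significant` column.
#' @export
de_call <- function(results, fdr_max = 0.05, lfc_min = 1) {
  results <- tibble::as_tibble(results)
  require_columns(results, c("fdr", "log2fc"), "DE results")
  results$significant <- results$fdr < fdr_max & abs(results$log2fc) >= lfc_min
  results
}

#' Row-wise Z-scores
#'
#' Per row: `(x - row mean) / row sample SD` (divisor `n - 1`); constant
#' rows map to all-zeros rather than NaN.
#'
#' @param matrix numeric matrix with at least two columns.
#' @return matrix of the same shape.
#' @export
rowwise_zscore <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2) stop_value("row-wise Z-scores need at least two columns")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Read a count matrix from MTX or dense delimited text
#'
#' MTX input expects the MatrixMarket file plus row-name and column-name
#' sidecar files (one name per line); dense input expects genes in rows
#' with a header of column ids and row names in the first column.
#'
#' @param path matrix file (`.mtx` or delimited text).
#' @param row_names,col_names sidecar name files (MTX only).
#' @param layer layer tag for the result.
#' @param sep separator for dense input.
#' @return an `e3_counts`.
#' @export
read_counts <- function(path, row_names = NULL, col_names = NULL,
                        layer = "raw", sep = ",") {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(row_names) || is.null(col_names)) {
      stop_schema("MTX input needs row_names and col_names files")
    }
    rownames(m) <- readLines(row_names)
    colnames(m) <- readLines(col_names)
  } else {
    df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                            row.names = 1, stringsAsFactors = FALSE)
    m <- as.matrix(df)
  }
  e3_counts(m, layer = layer)
}
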