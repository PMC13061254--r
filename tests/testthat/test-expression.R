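# Donor sampling, layer discipline, normalisation, marker detection.

sc_matrix <- function(values, layer = "raw") {
  e3_counts(values, layer = layer)
}

test_that("donor sampling retains 9 donors per tissue deterministically", {
  md <- gen_tissue_metadata(generator_config(seed = 7, n_tissues = 31,
                                             donors_per_tissue = 12))
  sel <- sample_donors(md, per_tissue = 9, seed = 42)
  expect_equal(nrow(sel), 279)  # 31 tissues x 9 donors, one sample each
  expect_equal(anyDuplicated(sel$donor), 0)
  expect_equal(as.vector(table(sel$tissue)), rep(9L, 31))

  # donors disjoint across tissues by construction of the output
  dt <- unique(sel[, c("donor", "tissue")])
  expect_equal(anyDuplicated(dt$donor), 0)

  # bit-identical under the same seed, different under another
  sel2 <- sample_donors(md, per_tissue = 9, seed = 42)
  expect_identical(sel, sel2)
  sel3 <- sample_donors(md, per_tissue = 9, seed = 43)
  expect_false(identical(sel$donor, sel3$donor))
})

test_that("donor sampling enforces capacity and exclusivity", {
  md <- tibble::tibble(sample = paste0("s", 1:8), donor = paste0("d", 1:8),
                       tissue = "liver")
  expect_error(sample_donors(md, per_tissue = 9), "liver",
               class = "e3ome_capacity_error")

  # exact capacity: all donors retained
  md9 <- tibble::tibble(sample = paste0("s", 1:9), donor = paste0("d", 1:9),
                        tissue = "liver")
  sel <- sample_donors(md9, per_tissue = 9)
  expect_setequal(sel$donor, md9$donor)

  # a donor contributing to two tissues is excluded before sampling
  md_x <- rbind(md9, tibble::tibble(sample = "s10", donor = "d1",
                                    tissue = "lung"))
  expect_error(sample_donors(md_x, per_tissue = 9), "liver",
               class = "e3ome_capacity_error")
})

test_that("one retained sample per donor is the lexicographic minimum", {
  md <- tibble::tibble(sample = c("s2", "s1", "s3"),
                       donor = c("d1", "d1", "d2"),
                       tissue = "liver")
  sel <- sample_donors(md, per_tissue = 2)
  expect_setequal(sel$sample, c("s1", "s3"))
})

test_that("AUC scaling multiplies columns by target/auc without rounding", {
  m <- sc_matrix(matrix(c(1, 2, 3, 4), 2,
                        dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  out <- auc_scale(m, c(s1 = 2e7, s2 = 4e7), target = 4e7)
  expect_equal(out$values[, "s1"], c(g1 = 2, g2 = 4))  # doubled
  expect_equal(out$values[, "s2"], c(g1 = 3, g2 = 4))  # identity
  expect_equal(out$layer, "auc_scaled")

  # column sums scale exactly by target/auc
  set.seed(3)
  v <- matrix(stats::rpois(50, 10), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  auc <- stats::setNames(stats::runif(5, 1e6, 1e8), colnames(v))
  scaled <- auc_scale(sc_matrix(v), auc)
  expect_equal(colSums(scaled$values),
               colSums(v) * 4e7 / auc)

  expect_error(auc_scale(sc_matrix(v), stats::setNames(rep(0, 5), colnames(v))),
               class = "e3ome_value_error")
})

test_that("panel restriction subsets rows and reports missing genes", {
  v <- matrix(1, 10, 2, dimnames = list(paste0("G", 1:10), c("c1", "c2")))
  m <- sc_matrix(v)
  expect_message(out <- restrict_panel(m, c("G2", "G5", "G7", "GX")),
                 "1 panel gene")
  expect_equal(rownames(out$values), c("G2", "G5", "G7"))
  expect_equal(attr(out, "missing"), "GX")

  all_out <- restrict_panel(m, paste0("G", 1:10))
  expect_equal(dim(all_out$values), dim(v))
  expect_error(restrict_panel(m, "NOPE"), class = "e3ome_value_error")
})

test_that("CP10K normalisation scales cells to 10,000 with zero clipping", {
  v <- matrix(c(1, 1, 2, 0, 0, 0), 3,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  out <- cp10k_normalize(sc_matrix(v))
  expect_equal(out$values[, "c1"], c(g1 = 2500, g2 = 2500, g3 = 5000))
  expect_equal(out$values[, "c2"], c(g1 = 0, g2 = 0, g3 = 0))  # no 0/0
  expect_equal(out$layer, "cp10k")
  expect_equal(colSums(out$values)[["c1"]], 1e4)

  # non-finite entries become zeros
  v2 <- matrix(c(NA, Inf, 4), 3, 1,
               dimnames = list(paste0("g", 1:3), "c1"))
  out2 <- cp10k_normalize(sc_matrix(v2))
  expect_equal(unname(out2$values[, 1]), c(0, 0, 1e4))
})

test_that("log1p transform and layer discipline", {
  v <- matrix(c(0, exp(1) - 1), 1, 2,
              dimnames = list("g1", c("c1", "c2")))
  m <- e3_counts(v, layer = "cp10k")
  out <- log1p_transform(m)
  expect_equal(unname(out$values[1, ]), c(0, 1))
  expect_equal(out$layer, "log1p")

  # wrong-layer inputs are refused at every stage
  raw <- sc_matrix(v)
  expect_error(log1p_transform(raw), "layer", class = "e3ome_value_error")
  expect_error(cp10k_normalize(out), "layer", class = "e3ome_value_error")
  expect_error(auc_scale(out, c(c1 = 1, c2 = 1)), "layer",
               class = "e3ome_value_error")
  expect_error(wilcoxon_ovr(raw, c(c1 = "A", c2 = "B")), "layer",
               class = "e3ome_value_error")
})

test_that("class filtering is inclusive at the 20-cell floor", {
  labels <- rep(c("a", "b", "c"), c(25, 19, 20))
  names(labels) <- paste0("cell", seq_along(labels))
  expect_equal(filter_classes(labels), c("a", "c"))
  expect_equal(filter_classes(labels, min_cells = 1), c("a", "b", "c"))
  expect_error(filter_classes(labels, min_cells = 100),
               class = "e3ome_capacity_error")
})

test_that("rank-sum p-values match exhaustive permutation enumeration", {
  # frozen most-extreme split: {1,2,3} vs {4,5,6} -> 2/20
  v <- matrix(1:6, 1, dimnames = list("g1", paste0("c", 1:6)))
  labels <- stats::setNames(rep(c("A", "B"), each = 3), colnames(v))
  res <- wilcoxon_ovr(e3_counts(v, layer = "cp10k"), labels, min_cells = 1)
  expect_equal(res$p[res$group == "A"], 0.1)

  # random small groups, with ties, against the enumeration oracle
  set.seed(29)
  for (rep in 1:15) {
    n1 <- sample(3:7, 1)
    n2 <- sample(3:7, 1)
    x <- sample(0:4, n1, replace = TRUE)
    y <- sample(0:6, n2, replace = TRUE)
    v <- matrix(c(x, y), 1,
                dimnames = list("g1", paste0("c", seq_len(n1 + n2))))
    labels <- stats::setNames(rep(c("A", "B"), c(n1, n2)), colnames(v))
    res <- wilcoxon_ovr(e3_counts(v, layer = "cp10k"), labels, min_cells = 1)
    expect_equal(res$p[res$group == "A"], oracle_wilcoxon_exact(x, y),
                 tolerance = 1e-10)
  }
})

test_that("large-group approximation matches the standard rank-sum test", {
  set.seed(37)
  x <- stats::rpois(60, 4)
  y <- stats::rpois(80, 5)
  v <- matrix(c(x, y), 1,
              dimnames = list("g1", paste0("c", 1:140)))
  labels <- stats::setNames(rep(c("A", "B"), c(60, 80)), colnames(v))
  res <- wilcoxon_ovr(e3_counts(v, layer = "cp10k"), labels, min_cells = 1)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(res$p[res$group == "A"], ref, tolerance = 1e-10)
})

test_that("constant genes return p = 1 under the zero-variance convention", {
  v <- matrix(5, 2, 50, dimnames = list(c("g1", "g2"), paste0("c", 1:50)))
  labels <- stats::setNames(rep(c("A", "B"), 25), colnames(v))
  res <- wilcoxon_ovr(e3_counts(v, layer = "cp10k"), labels, min_cells = 1)
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
})

test_that("planted markers are recovered and top-ranked in their class", {
  cfg <- generator_config(seed = 11)  # 8-fold markers, 200 cells/class
  sc <- gen_sc_counts(cfg)
  norm <- cp10k_normalize(sc$counts)
  res <- wilcoxon_ovr(norm, sc$labels)
  hits <- merge(as.data.frame(res), as.data.frame(sc$truth),
                by.x = c("gene", "group"), by.y = c("gene", "class"))
  expect_gte(mean(hits$significant), 0.9)
  expect_true(all(hits$log2fc > 0))
  # planted genes sit in the top decile by p within their class
  for (cl in unique(sc$truth$class)) {
    cl_res <- res[res$group == cl, ]
    cutoff <- stats::quantile(cl_res$p, 0.1)
    planted_p <- cl_res$p[cl_res$gene %in%
                            sc$truth$gene[sc$truth$class == cl]]
    expect_true(all(planted_p <= cutoff))
  }
})

test_that("DE calls apply strict FDR and inclusive fold-change gates", {
  tab <- tibble::tibble(gene = paste0("g", 1:3),
                        fdr = c(0.049, 0.05, 0.001),
                        log2fc = c(1.0, 3.0, 0.99))
  out <- de_call(tab)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
})

test_that("row-wise Z-scores standardise with sample SD", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- rowwise_zscore(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))

  set.seed(41)
  r <- matrix(stats::rnorm(40), 4)
  z2 <- rowwise_zscore(r)
  expect_equal(unname(rowMeans(z2)), rep(0, 4))
  expect_equal(unname(apply(z2, 1, stats::sd)), rep(1, 4))
  expect_error(rowwise_zscore(matrix(1, 2, 1)), class = "e3ome_value_error")
})

test_that("count matrices round-trip through MTX with sidecar names", {
  v <- matrix(stats::rpois(12, 3), 3,
              dimnames = list(paste0("G", 1:3), paste0("c", 1:4)))
  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), file.path(dir, "m.mtx"))
  writeLines(rownames(v), file.path(dir, "rows.txt"))
  writeLines(colnames(v), file.path(dir, "cols.txt"))
  m <- read_counts(file.path(dir, "m.mtx"),
                   row_names = file.path(dir, "rows.txt"),
                   col_names = file.path(dir, "cols.txt"))
  expect_equal(as.matrix(m$values), v)
})
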