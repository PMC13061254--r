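# Confidence scoring, categories, ranking, family rules, overlaps.

test_that("scores follow the stated weight arithmetic", {
  # yes vote + three distinct evidence kinds: 5 + 2 + 2 + 2 = 11
  led <- new_ledger(
    data.frame(symbol = "G1"),
    votes = data.frame(symbol = "G1", curator = "c1", family = "any",
                       verdict = "yes"),
    evidence = data.frame(
      symbol = "G1",
      source = c("interpro_domain", "biogrid_interaction",
                 "literature_annotation"),
      claim = c("RING", "CUL1", "3-box")))
  expect_equal(score_gene("G1", led), 11L)

  # yes + no with no evidence cancel: +5 - 5 = 0
  led2 <- new_ledger(
    data.frame(symbol = "G1"),
    votes = data.frame(symbol = "G1", curator = c("c1", "c2"), family = "any",
                       verdict = c("yes", "no")))
  expect_equal(score_gene("G1", led2), 0L)

  # unassessed votes are neutral: evidence only, 2
  led3 <- new_ledger(
    data.frame(symbol = "G1"),
    votes = data.frame(symbol = "G1", curator = "c1", family = "any",
                       verdict = "unassessed"),
    evidence = data.frame(symbol = "G1", source = "interpro_domain",
                          claim = "RING"))
  expect_equal(score_gene("G1", led3), 2L)
})

test_that("score decomposition recounts from raw ledger rows", {
  # property: score == w_yes*n_yes + w_no*n_no + w_evidence*n_distinct_claims
  set.seed(11)
  w <- score_weights()
  for (rep in 1:10) {
    n_votes <- sample(0:4, 1)
    n_evid <- sample(0:5, 1)
    votes <- if (n_votes > 0) {
      data.frame(symbol = "G1", curator = paste0("c", seq_len(n_votes)),
                 family = "any",
                 verdict = sample(c("yes", "no", "inconclusive", "unassessed"),
                                  n_votes, replace = TRUE))
    } else NULL
    evidence <- if (n_evid > 0) {
      unique(data.frame(symbol = "G1",
                        source = sample(c("interpro_domain",
                                          "biogrid_interaction",
                                          "literature_annotation"),
                                        n_evid, replace = TRUE),
                        claim = sample(c("RING", "F-box", "CUL1"), n_evid,
                                       replace = TRUE)))
    } else NULL
    led <- new_ledger(data.frame(symbol = "G1"), votes = votes,
                      evidence = evidence)
    expected <- w$w_yes * sum(votes$verdict == "yes") +
      w$w_no * sum(votes$verdict == "no") +
      w$w_evidence * nrow(led$evidence)
    expect_equal(score_gene("G1", led), as.integer(expected))
  }
})

test_that("categories follow the inclusion/evidence partition", {
  led_yes <- new_ledger(
    data.frame(symbol = "G1"),
    votes = data.frame(symbol = "G1", curator = c("c1", "c2"), family = "any",
                       verdict = c("yes", "inconclusive")))
  expect_equal(assign_category("G1", led_yes), 1L)

  led_ev <- new_ledger(
    data.frame(symbol = "G1"),
    votes = data.frame(symbol = "G1", curator = "c1", family = "any",
                       verdict = "no"),
    evidence = data.frame(symbol = "G1", source = "biogrid_interaction",
                          claim = "CUL1"))
  expect_equal(assign_category("G1", led_ev), 2L)

  led_none <- new_ledger(
    data.frame(symbol = "G1"),
    votes = data.frame(symbol = "G1", curator = "c1", family = "any",
                       verdict = "unassessed"))
  expect_equal(assign_category("G1", led_none), 3L)
})

test_that("adding a yes vote or evidence never worsens score or category", {
  set.seed(23)
  for (rep in 1:8) {
    n_votes <- sample(0:3, 1)
    votes <- if (n_votes > 0) {
      data.frame(symbol = "G1", curator = paste0("c", seq_len(n_votes)),
                 family = "any",
                 verdict = sample(c("yes", "no", "inconclusive"), n_votes,
                                  replace = TRUE))
    } else NULL
    led <- new_ledger(data.frame(symbol = "G1"), votes = votes)
    base_score <- score_gene("G1", led)
    base_cat <- assign_category("G1", led)

    votes_plus <- rbind(votes, data.frame(symbol = "G1", curator = "cx",
                                          family = "any", verdict = "yes"))
    led_plus <- new_ledger(data.frame(symbol = "G1"), votes = votes_plus)
    expect_gte(score_gene("G1", led_plus), base_score)
    expect_lte(assign_category("G1", led_plus), base_cat)

    led_ev <- new_ledger(data.frame(symbol = "G1"), votes = votes,
                         evidence = data.frame(symbol = "G1",
                                               source = "interpro_domain",
                                               claim = "RING"))
    expect_false(base_cat == 2L && assign_category("G1", led_ev) == 3L)
    expect_gte(score_gene("G1", led_ev), base_score)
  }
})

test_that("every gene gets exactly one category and ranking is deterministic", {
  led <- toy_ledger()
  res <- score_ledger(led)
  expect_setequal(res$gene, led$genes$symbol)
  expect_true(all(res$category %in% 1:3))
  expect_equal(sort(res$rank), seq_len(nrow(res)))
  # descending score with documented tie-breaks
  expect_true(all(diff(res$score) <= 0))
})

test_that("rank tie-breaking is score desc, category asc, then symbol", {
  res <- rank_genes(tibble::tibble(gene = c("A", "B", "C"),
                                   score = c(11L, 2L, 2L),
                                   category = c(1L, 2L, 3L)))
  expect_equal(res$gene, c("A", "B", "C"))
  expect_equal(res$rank, 1:3)

  # all-equal collapses to lexicographic order
  res2 <- rank_genes(tibble::tibble(gene = c("Z", "M", "A"),
                                    score = 5L, category = 1L))
  expect_equal(res2$gene, c("A", "M", "Z"))

  # singleton gets rank 1
  res3 <- rank_genes(tibble::tibble(gene = "X", score = 0L, category = 3L))
  expect_equal(res3$rank, 1L)
})

test_that("family classification matches rule claims and votes", {
  rules <- load_family_rules()
  led <- new_ledger(
    data.frame(symbol = "SKP2"),
    votes = data.frame(symbol = "SKP2", curator = "c1", family = "CRL1_SR",
                       verdict = "yes"),
    evidence = data.frame(
      symbol = "SKP2",
      source = c("interpro_domain", "biogrid_interaction",
                 "biogrid_interaction"),
      claim = c("F-box", "CUL1", "SKP1")))
  asg <- classify_family("SKP2", led, rules)
  expect_equal(asg$family, "CRL1_SR")
  expect_equal(asg$tier, "high")
  expect_true(all(asg$support[[1]][c("F-box", "CUL1", "SKP1")]))
})

test_that("a dual-motif substrate receptor lands in two families", {
  rules <- load_family_rules()
  led <- new_ledger(
    data.frame(symbol = "FBXW5"),
    evidence = data.frame(
      symbol = "FBXW5",
      source = c("interpro_domain", "literature_annotation"),
      claim = c("F-box", "helix-loop-helix")))
  asg <- classify_family("FBXW5", led, rules)
  expect_setequal(asg$family, c("CRL1_SR", "CRL4_SR"))
  expect_true(all(asg$tier == "low"))  # no curator inclusion
})

test_that("genes with no claims and no votes get no assignment", {
  led <- new_ledger(data.frame(symbol = "G1"))
  expect_equal(nrow(classify_family("G1", led)), 0)
})

test_that("BTB alone does not qualify a CRL3 substrate receptor", {
  rules <- load_family_rules()
  led <- new_ledger(
    data.frame(symbol = c("KBTB1", "KLHL9")),
    evidence = data.frame(
      symbol = c("KBTB1", "KLHL9", "KLHL9"),
      source = c("interpro_domain", "interpro_domain",
                 "literature_annotation"),
      claim = c("BTB", "BTB", "3-box")))
  expect_equal(nrow(classify_family("KBTB1", led, rules)), 0)
  asg <- classify_family("KLHL9", led, rules)
  expect_equal(asg$family, "CRL3_SR")
  expect_true(asg$support[[1]][["BTB"]])  # still tallied as support
})

test_that("family tallies conserve input = high + low", {
  rules <- load_family_rules()
  # 4 CRL1 candidates, 3 with curator inclusion
  led <- new_ledger(
    data.frame(symbol = paste0("F", 1:4)),
    votes = data.frame(symbol = paste0("F", 1:3), curator = "c1",
                       family = "CRL1_SR", verdict = "yes"),
    evidence = data.frame(symbol = paste0("F", 1:4),
                          source = "interpro_domain", claim = "F-box"))
  tal <- enumerate_families(led, rules)
  crl1 <- tal[tal$family == "CRL1_SR", ]
  expect_equal(crl1$input, 4L)
  expect_equal(crl1$high, 3L)
  expect_equal(crl1$low, 1L)
  expect_equal(crl1$claim_counts[[1]][["F-box"]], 4L)
  expect_true(all(tal$high + tal$low == tal$input))
  expect_true(all(unlist(tal$claim_counts) <= rep(tal$input,
                                                  lengths(tal$claim_counts))))

  # empty ledger gives empty tallies
  led0 <- new_ledger(data.frame(symbol = "X1"))
  expect_equal(nrow(enumerate_families(led0, rules)), 0)
})

test_that("pairwise overlap is row-normalized with a 100 diagonal", {
  m <- pairwise_overlap(list(L1 = c("A", "B"), L2 = c("B", "C")))
  expect_equal(m["L1", "L2"], 50)
  expect_equal(m["L2", "L1"], 50)
  expect_equal(diag(m), c(L1 = 100, L2 = 100))

  ident <- pairwise_overlap(list(a = c("X", "Y"), b = c("X", "Y")))
  expect_true(all(ident == 100))

  disj <- pairwise_overlap(list(a = "X", b = "Y"))
  expect_equal(disj["a", "b"], 0)

  # asymmetry between lists of different sizes; all cells within [0, 100]
  asym <- pairwise_overlap(list(small = c("A", "B"),
                                big = c("A", "B", "C", "D")))
  expect_equal(asym["small", "big"], 100)
  expect_equal(asym["big", "small"], 50)
  expect_true(all(asym >= 0 & asym <= 100))

  expect_error(pairwise_overlap(list(a = character(), b = "X")),
               class = "e3ome_value_error")
})

test_that("panel intersection resolves aliases first", {
  led <- toy_ledger()
  expect_equal(intersect_panel(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_equal(intersect_panel(c("HOIP", "SKP2"), c("RNF31", "XYZ"),
                               ledger = led),
               "RNF31")
  expect_equal(intersect_panel(c("A", "B"), character()), character(0))
})
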