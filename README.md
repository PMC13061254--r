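# e3ome

Evidence-based curation and integration of the human E3 ubiquitin ligase
landscape.

Roughly 600–700 human genes encode E3 ubiquitin ligases — the enzymes that
confer substrate specificity on the ubiquitination cascade — but published
E3 gene lists disagree substantially, because each was built with different
inclusion criteria. `e3ome` is an R toolkit for the kind of systematic,
evidence-ledger curation that resolves this: it integrates curator
assessments, domain annotations, interaction reports and literature claims
into reproducible confidence scores and family classifications, and carries
the curated panel through the standard downstream analyses
(phenome-wide/GWAS association summarisation, phenotype-ontology term
enrichment, tissue and single-cell expression profiling). It is aimed at
groups curating gene families from heterogeneous evidence and at anyone who
needs the downstream statistical stages in a tested, scriptable form.

## The model at its core

Each gene's confidence score is a weighted evidence sum

```
S = w_yes * n_yes + w_no * n_no + w_ev * n_evidence      (+5, -5, +2 by default)
```

over curator inclusions/exclusions and distinct evidence items, with genes
partitioned into category 1 (curator-included), category 2 (evidence only)
and category 3 (neither). Family membership (RING, dRING, HECT, RBR,
CRL1–5 substrate receptors, APC/C, atypical, pseudo) is assigned by a
shipped, editable rule file mapping families to sufficient domain/motif
claims and interaction partners. Downstream statistics are implemented
exactly: one-sided Fisher tests from log-binomial tail sums,
Benjamini-Hochberg step-up adjustment, Haldane-Anscombe odds ratios
`(a+½)(d+½) / ((b+½)(c+½))`, and one-vs-rest Wilcoxon rank-sum marker
tests with tie correction (exact enumeration for small groups). Synthetic
generators with ground truth make every stage testable offline.

## Worked example

```r
library(e3ome)

# a synthetic curation campaign with known ground truth
cfg <- generator_config(seed = 42, n_genes = 40,
                        families = c(RING = 12L, HECT = 5L, CRL1_SR = 8L))
gen <- gen_evidence(cfg)
gen$ledger
#> <e3_ledger> 65 genes, 65 votes, 27 evidence items

head(score_ledger(gen$ledger), 5)
#>   gene   score category  rank
#> 1 G00022    11        1     1
#> 2 G00025    11        1     2
#> 3 G00021     9        1     3
#> 4 G00002     7        1     4
#> 5 G00003     7        1     5

enumerate_families(gen$ledger)[, c("family", "input", "high", "low")]
#>   family  input  high   low
#> 1 CRL1_SR     8     6     2
#> 2 HECT        5     4     1
#> 3 RING       12    10     2
```

A score of 11 is one curator inclusion (+5) plus three distinct evidence
items (+2 each); `high` counts the family members that are category 1 in
that family context, and `input = high + low` always holds. With curator
accuracy 0.9 and evidence sensitivity 0.8 some true genes land in the low
tier, as above.

The expression side reproduces the seeded donor-sampling arithmetic and the
enrichment statistics directly:

```r
md <- gen_tissue_metadata(generator_config(seed = 42))   # 31 tissues
nrow(sample_donors(md, per_tissue = 9, seed = 42))
#> [1] 279

tab <- build_table(family_genes = paste0("f", 1:28),
                   term_genes = c(paste0("f", 1:12), paste0("t", 1:28)),
                   universe_size = 19294)
tab                      #  a     b     c     d
#>    12    16    28 19238
fisher_one_sided(tab)    # one-sided enrichment p
#> [1] 3.0e-26
haldane_anscombe_or(tab)
#> [1] 511.4
```

12 of 28 family genes annotated to a 40-gene term in a 19,294-gene universe
is overwhelming enrichment; the Haldane-Anscombe pseudocount keeps the odds
ratio finite even when a cell is zero.

A thin command-line front-end (`inst/exec/e3ome`) exposes the same stages
as subcommands (`simulate`, `curate`, `phewas`, `gwas`, `hpo`, `markers`,
`overlap`) for file-in/file-out runs with JSON run reports.

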