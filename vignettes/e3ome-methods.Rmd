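---
title: "Methods: evidence integration and downstream analyses in e3ome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence integration and downstream analyses in e3ome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e3ome)
```

## The curation model

e3ome treats the identification of human E3 ubiquitin ligases as an
evidence-integration problem. Each candidate gene accumulates three kinds of
evidence in a ledger: curator assessments (one of *yes*, *no*,
*inconclusive*, *unassessed*, optionally tied to a family context), domain
annotations (InterPro-style claims such as RING, HECT, F-box or SOCS-box),
and interaction or literature claims (BioGRID-style partners such as CUL1 or
SKP1, motifs such as the 3-box or a helix-loop-helix).

The confidence score of a gene is a weighted sum

$$ S = w_{\mathrm{yes}}\, n_{\mathrm{yes}} + w_{\mathrm{no}}\, n_{\mathrm{no}}
     + w_{\mathrm{ev}}\, n_{\mathrm{ev}}, $$

with defaults $w_{\mathrm{yes}} = +5$, $w_{\mathrm{no}} = -5$ and
$w_{\mathrm{ev}} = +2$ per distinct evidence item. Inconclusive and
unassessed votes are neutral. Distinctness for evidence means distinct
(source, claim) pairs: two different interaction partners count twice, fifty
redundant reports of the same partner count once, because the score reflects
the *presence* of independent lines of evidence, not their multiplicity.
Independently of the score, genes fall into three confidence categories:
category 1 (at least one curator included the gene), category 2 (no curator
inclusion but some reported evidence), category 3 (neither). Ranking is by
score descending with deterministic tie-breaks (category ascending, then
symbol), so reruns are byte-identical.

Three points were genuinely open and were settled as package design choices:

* **Vote stacking.** Yes/no votes stack across curators (each inclusion adds
  $w_{\mathrm{yes}}$). Multiple independent assessments carry more
  information than one; a `cap_votes` option restricts to one inclusion and
  one exclusion per gene for the conservative reading.
* **Inconclusive votes** contribute 0. An assessment that reached no
  conclusion is evidence of effort, not of E3 activity.
* **Category-2 evidence scope.** "Some evidence" means at least one evidence
  item of *any* kind (`evidence_scope = "any"`), the weakest reading; a
  family-restricted scope is available.

## Family classification rules

Family membership is rule-driven and the rules are data, not code
(`inst/extdata/family_rules.yaml`): each family lists domain claims, motif
claims and interaction partners that are individually sufficient, plus
*supporting* claims that are tallied but not sufficient. The shipped
defaults encode the standard E3 taxonomy — RING, dRING (U-box, SP-RING,
hemiRING, RING-like), HECT, RBR (RING1–IBR–RING2), and the Cullin-RING
ligase substrate receptors CRL1 (F-box; CUL1/SKP1), CRL2
(BC-box-CUL2-box; CUL2/ELOB/ELOC), CRL3 (3-box; CUL3), CRL4
(helix-loop-helix; DDB1) and CRL5 (SOCS-box; CUL5/ELOB/ELOC). APC/C
substrate receptors, atypical E3s and pseudo-E3s are curator-only families:
membership comes from family-context votes, never from claims.

One deliberate refinement: for CRL3 substrate receptors the BTB domain is a
*supporting* claim only. Many BTB proteins are not CRL3 receptors, so
membership requires the 3-box motif or direct CUL3 interaction evidence;
the BTB flag still appears in the Sankey-style stage tallies.

A gene may hold several assignments (a dual F-box / helix-loop-helix
receptor is both CRL1 and CRL4). The assignment tier is *high* exactly when
the gene is category 1 within that family context, and each family tally
conserves `input = high + low`.

## Association summarisation

**PheWAS.** Variant-phenotype records under the four genetic models
(genotypic/additive, allelic, dominant, recessive) are filtered at
$p \le 10^{-8}$ (inclusive), collapsed per (variant, phenotype) to the
minimum-p model (exact ties resolved by a fixed model priority so reruns
are stable), and summarised per gene and phenotype category as the
arithmetic mean of odds ratios (binary traits) or of absolute effect sizes
(continuous traits). Means are taken on the odds-ratio scale, not log-OR,
and protective ORs are averaged directly by default; a `fold_protective`
option maps OR < 1 to 1/OR first for users who want magnitude-of-effect
summaries. Binary and continuous phenotypes are never averaged together.

**GWAS Catalog.** Five ordered stages: $p \le 5\times10^{-8}$; per
(gene set, variant, trait) keep the smallest p across studies; keep
variants uniquely mapped to one gene; keep high/moderate functional impact;
drop rows with missing or non-specific parent trait categories ("Other
trait", "Other disease", "NR", "Other measurement") and the highly
polygenic "Body measurement" category. The stage order is fixed and each
stage logs its survivor count, so a run report shows a non-increasing
cascade.

## Phenotype-term enrichment

Gene annotations are propagated up the ontology before testing (the
true-path rule: a term's gene set is the union of its own and all
descendants' annotations); a `propagate = FALSE` flag disables this for
annotation files that arrive pre-propagated. For each family, every term
annotated to at least `min_genes = 3` family members is tested with a
one-sided (enrichment) Fisher exact test computed from log-binomial
coefficients — no normal approximation, since the interesting cells are
small. Adjustment is Benjamini-Hochberg *within each family* over exactly
the tested terms; there is no global adjustment. Odds ratios use the
Haldane-Anscombe correction, $(a+\tfrac12)(d+\tfrac12) /
\big((b+\tfrac12)(c+\tfrac12)\big)$, which keeps them finite for zero
cells. The default universe size mirrors the HGNC protein-coding gene set
(19,294 genes); the universe is always an explicit input, never inferred
from the annotation file.

## Expression profiling

**Donor sampling.** For tissue-level expression, one sample per donor is
retained (the lexicographically smallest sample identifier — the choice is
arbitrary but must be deterministic), donors contributing to more than one
tissue are excluded, and exactly 9 donors per tissue are drawn without
replacement with a fixed seed (default 42). Reproducibility of a seeded
draw depends on traversal order, which general-purpose libraries leave
unspecified, so tissues and donors are processed in sorted order on a
single Mersenne-Twister stream.

**Layers.** Count matrices carry a layer tag (`raw`, `auc_scaled`,
`cp10k`, `log1p`) and every operation refuses the wrong layer, so a
pipeline cannot normalise twice or test raw counts by accident.
Area-under-coverage scaling multiplies each column by
$4\times10^{7}/\mathrm{AUC}$ without rounding. CP10K normalisation replaces
non-finite entries with zeros and clips library sizes at $10^{-12}$, so an
all-zero cell maps to an all-zero column instead of dividing by zero (the
"zero entries replaced with zeros" convention is a no-op and is implemented
as non-finite → 0). `log1p` is the natural logarithm of $1 + x$.

**Marker detection.** Cell classes with fewer than 20 cells are dropped
(inclusive threshold: a 20-cell class survives). Each surviving class is
tested one-versus-rest per gene with a two-sided Wilcoxon rank-sum test:
normal approximation with tie correction and no continuity correction
(the convention of the standard single-cell toolkits), exact enumeration
of all group assignments when both groups have at most 8 observations.
Zero-variance genes return $p = 1$ — no evidence of difference rather than
an undefined statistic. BH adjustment runs across genes within each class
and significance is called at adjusted $p < 0.05$. The reported fold-change
is $\log_2\!\big((\bar x_{\mathrm{in}} + \varepsilon)/(\bar
x_{\mathrm{out}} + \varepsilon)\big)$ with $\varepsilon = 10^{-9}$.

**Differential-expression calls** consume any engine's (FDR, log2FC) table
and apply FDR < 0.05 (strict) and $|\log_2 FC| \ge 1$ (inclusive). The
tissue-level DE engine of record in the source workflow is the
limma-voom/edgeR stack; this package deliberately does not reimplement TMM,
`filterByExpr`, voom precision weights or empirical-Bayes moderation — the
in-package Wilcoxon harness plus thresholding is the testable approximation,
and `de_call` is engine-agnostic. Row-wise Z-scores for visualisation use
the sample (n−1) standard deviation, with constant rows mapping to zeros.

## What the synthetic data emulates

The generators produce every input the pipeline reads, with ground truth:

* **Evidence ledgers** assign genes to true families, emit each sufficient
  rule claim with probability `evidence_sensitivity` (default 0.8) and one
  curator vote per gene matching truth with probability `curator_accuracy`
  (default 0.9). With both set to 1 the pipeline must recover categories
  and families exactly, which pins the scoring arithmetic.
* **PheWAS tables** mix null p-values ($U(0,1)$) with signal keys
  ($10^{-U(8,15)}$, all four models), log-normal odds ratios and normal
  betas over a fixed 20-phenotype, 5-category vocabulary.
* **Ontologies** are random DAGs with depth at most 5 and at most 3 parents
  per term — small enough that a brute-force transitive-closure oracle can
  verify propagation. Background annotation probability defaults to 0.01
  per gene and term; planted (family, term) pairs annotate family genes at
  an elevated probability (0.5 in the power checks).
* **Single-cell counts** are negative binomial parameterised by mean
  (default 1.0) and dispersion (default 0.5) with variance
  $\mu + \phi\mu^2$ — stated explicitly to avoid parameterisation drift —
  with `markers_per_class` genes per class whose in-class mean is
  multiplied by `marker_fold` (default 8).
* **Tissue metadata** gives each tissue its own donors (default 31 tissues,
  12 donors each) with 1–3 samples per donor, the structure the donor
  sampler needs to exercise exclusivity and capacity checks.

One master seed drives fixed per-generator sub-streams, so adding a
generator does not shift existing draws and identical configurations are
bit-identical. The generators emulate statistical structure only: they do
not attempt the marginal distributions, batch effects, gene-length or
GC biases, ambient contamination or donor covariates of real atlases, so a
passing recovery test demonstrates correctness of the procedures, not
performance on real data.

Problem sizes used in the shipped checks were chosen to keep the full suite
in the tens of seconds: 500-gene × 300–600-cell marker matrices (50
replicates for the null), 1,000 replicate families for the enrichment null,
and ledgers of tens to low hundreds of genes.

## Numerical choices

* Fisher tail sums accumulate `lchoose` terms and clamp at 1; enumeration
  agrees with the package's own upper-tail sum to 10⁻¹² for margins ≤ 30.
* BH is the textbook step-up: sort, $p_{(i)} m/i$, running minimum from the
  largest rank, cap at 1, original order restored.
* Exact rank-sum enumeration treats ties through midranks and compares
  absolute deviations of rank sums with a 10⁻⁹ guard against floating-point
  equality.
* All thresholds follow the stated inequality directions: $p \le 10^{-8}$
  and $p \le 5\times10^{-8}$ inclusive, FDR $< 0.05$ strict,
  $|\log_2 FC| \ge 1$ and class size $\ge 20$ inclusive.
* Written tables format doubles to 9 significant digits and sort keys, so
  reruns are byte-identical.

## Known limitations

* **The min-overlap screen biases the within-family adjustment.** Testing
  only terms that already share ≥ 3 genes with a family is an implicit
  selection over all terms, which the within-family BH (computed over the
  tested terms only, as the procedure prescribes) cannot see. On sparse
  synthetic annotations (1% background, 28-gene families) this makes the
  family-level any-discovery rate under the null noticeably exceed the
  nominal 5% — the flagged cases are exactly 3–4-gene coincidences on
  small terms whose individual Fisher p-values are correct. Users drawing
  conclusions from families with few, small significant terms should
  treat them as screening hits; a global adjustment across all terms, or
  larger `min_genes`, is the conservative alternative.
* The curation score weights (+5/−5/+2) are conventional, not estimated;
  the score is an ordering device, and categories — not scores — carry the
  confidence semantics.
* Symbol resolution is file-based (aliases shipped with the gene table);
  there is no live nomenclature service, so stale aliases surface as
  rejected rows rather than being silently fixed.
* The Wilcoxon normal approximation is used for all realistic group sizes;
  exact enumeration exists for validation, not for large groups.
* The compendium reader consumes sheet-per-family delimited exports behind
  a tolerant column mapping; workbook layouts whose column names match
  none of the documented patterns need an explicit export step.
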