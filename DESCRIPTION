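Package: e3ome
Title: Evidence-Based Curation and Integration of the Human E3 Ubiquitin Ligase Landscape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing a curated compendium of human E3
    ubiquitin-ligase genes. Implements an evidence ledger (curator votes,
    InterPro-style domain claims, BioGRID-style interactions, literature
    annotations) with confidence scoring and category assignment, rule-based
    family and substrate-receptor classification with Sankey-style stage
    tallies, PheWAS and GWAS Catalog association summarisation, Human
    Phenotype Ontology term enrichment (one-sided Fisher tests,
    Benjamini-Hochberg adjustment within each family, Haldane-Anscombe odds
    ratios), expression profiling utilities (seeded donor sampling, library
    scaling, CP10K normalisation, one-vs-rest Wilcoxon marker detection), and
    synthetic-data generators with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
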