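#' Synthetic data with ground truth
#'
#' Generators for every input the pipeline consumes: evidence ledgers with
#' controllable curator agreement and evidence sensitivity, PheWAS-style
#' variant association tables with mixed null/signal p-values, a random
#' phenotype ontology with planted family-term enrichment, negative-binomial
#' single-cell count matrices with planted class markers, and tissue/donor
#' sample metadata. Every generator is a pure function of its configuration
#' (seed included) and returns a truth object sufficient to score recovery.
#'
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' Defaults mirror the study conditions where the source procedures state
#' them (19,294-gene universe, 31 tissues, 9-donor draws, 20-cell class
#' floor, 8-fold planted markers) and desk-scale sizes elsewhere.
#'
#' @param seed master seed; each generator derives its own sub-stream from
#'   it, so adding a generator does not shift existing streams.
#' @param n_genes background genes in the evidence ledger.
#' @param families named integer vector: true genes per family.
#' @param curator_accuracy probability a curator vote matches truth.
#' @param evidence_sensitivity probability each rule claim of a true gene
#'   is emitted as an evidence item.
#' @param n_variants_per_gene variants simulated per gene.
#' @param signal_fraction fraction of variant-phenotype keys carrying signal.
#' @param or_meanlog,or_sdlog log-normal parameters for binary odds ratios.
#' @param n_terms ontology terms.
#' @param universe_size phenotype-annotation gene universe size.
#' @param annotation_prob background per-gene annotation probability.
#' @param planted_pairs list of `list(family =, term =, prob =)` planted
#'   enrichments.
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion
#'   (variance = mean + dispersion * mean^2).
#' @param n_classes,cells_per_class,markers_per_class,marker_fold
#'   single-cell design: balanced classes and planted fold-change markers.
#' @param n_sc_genes genes in the single-cell matrix.
#' @param n_tissues,donors_per_tissue tissue metadata design (donors unique
#'   across tissues, 1-3 samples per donor).
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 100L,
                             families = c(RING = 20L, HECT = 8L, RBR = 5L,
                                          CRL1_SR = 10L, CRL3_SR = 10L),
                             curator_accuracy = 0.9,
                             evidence_sensitivity = 0.8,
                             n_variants_per_gene = 10L,
                             signal_fraction = 0.1,
                             or_meanlog = log(1.5), or_sdlog = 0.3,
                             n_terms = 50L,
                             universe_size = 19294L,
                             annotation_prob = 0.01,
                             planted_pairs = list(),
                             nb_mean = 1.0, nb_dispersion = 0.5,
                             n_classes = 3L, cells_per_class = 200L,
                             markers_per_class = 10L, marker_fold = 8,
                             n_sc_genes = 500L,
                             n_tissues = 31L, donors_per_tissue = 12L) {
  cfg <- mget(names(formals()))
  probs <- c(curator_accuracy, evidence_sensitivity, signal_fraction,
             annotation_prob)
  if (any(probs < 0 | probs > 1)) stop_value("probabilities must lie in [0, 1]")
  counts <- c(n_genes, n_variants_per_gene, n_terms, universe_size,
              n_classes, cells_per_class, n_sc_genes, n_tissues,
              donors_per_tissue)
  if (any(counts <= 0)) stop_value("counts must be positive")
  structure(cfg, class = "generator_config")
}

# fixed per-generator sub-stream offsets (keep derived seeds < 2^31)
substream <- function(config, offset) (config$seed %% 2000000000L) + offset

#' Generate a synthetic evidence ledger with truth
#'
#' True genes are assigned to families; each sufficient rule claim of the
#' family is emitted as an evidence item with probability
#' `evidence_sensitivity` (domains as InterPro claims, motifs as literature
#' claims, partners as interaction claims). One curator votes per gene:
#' yes for true genes and no for background genes, each flipped with
#' probability `1 - curator_accuracy`. The truth table records each gene's
#' intended family and category (1 for true genes, 3 for background).
#'
#' @param config a [generator_config()].
#' @param rules a `family_rules` object; families named in the config must
#'   exist in it.
#' @return list with elements `ledger` (an `e3_ledger`) and `truth`
#'   (tibble `gene`, `family`, `category`).
#' @export
gen_evidence <- function(config, rules = load_family_rules()) {
  stopifnot(inherits(config, "generator_config"))
  unknown <- setdiff(names(config$families), names(rules))
  if (length(unknown) > 0) {
    stop_value(sprintf("families not in the rule vocabulary: %s",
                       paste(unknown, collapse = ", ")))
  }
  with_local_seed(substream(config, 101L), {
    fam_genes <- unlist(mapply(function(fam, n) {
      rep(fam, n)
    }, names(config$families), config$families, SIMPLIFY = FALSE))
    n_true <- length(fam_genes)
    n_total <- n_true + config$n_genes
    symbols <- sprintf("G%05d", seq_len(n_total))
    truth <- tibble::tibble(
      gene = symbols,
      family = c(fam_genes, rep("none", config$n_genes)),
      category = c(rep(1L, n_true), rep(3L, config$n_genes)))

    ev_rows <- list()
    for (i in seq_len(n_true)) {
      rule <- rules[[truth$family[i]]]
      claims <- rbind(
        if (length(rule$domains)) cbind("interpro_domain", rule$domains),
        if (length(rule$motifs)) cbind("literature_annotation", rule$motifs),
        if (length(rule$partners)) cbind("biogrid_interaction", rule$partners))
      if (is.null(claims)) next
      emit <- stats::runif(nrow(claims)) <= config$evidence_sensitivity
      if (!any(emit)) next
      ev_rows[[length(ev_rows) + 1L]] <- tibble::tibble(
        symbol = symbols[i], source = claims[emit, 1],
        claim = claims[emit, 2], reference = "synthetic")
    }
    evidence <- if (length(ev_rows)) do.call(rbind, ev_rows) else NULL

    correct <- stats::runif(n_total) <= config$curator_accuracy
    verdict <- ifelse(truth$family != "none",
                      ifelse(correct, "yes", "no"),
                      ifelse(correct, "no", "yes"))
    votes <- tibble::tibble(symbol = symbols, curator = "C1",
                            family = ifelse(truth$family != "none",
                                            truth$family, "any"),
                            verdict = verdict)
    genes <- tibble::tibble(symbol = symbols, aliases = "",
                            protein_coding = 1L)
    list(ledger = new_ledger(genes, votes = votes, evidence = evidence),
         truth = truth)
  })
}

PHENOTYPE_VOCAB <- data.frame(
  phenotype = sprintf("pheno_%02d", 1:20),
  category = rep(c("cardiovascular", "endocrine", "haematology",
                   "neurology", "immunology"), each = 4),
  type = rep(c("binary", "continuous"), 10),
  stringsAsFactors = FALSE)

#' Generate a synthetic PheWAS association table with truth
#'
#' Each gene receives `n_variants_per_gene` variants; each variant is paired
#' with one phenotype from a fixed vocabulary and tested under the four
#' genetic models. A fraction `signal_fraction` of variant-phenotype keys is
#' signal: all four model p-values are drawn as `10^-U(8, 15)`; null keys
#' draw `U(0, 1)`. Binary effects are log-normal odds ratios; continuous
#' effects are standard-normal betas.
#'
#' @param config a [generator_config()].
#' @param genes gene symbols to simulate for; defaults to
#'   `sprintf("G%05d", 1:n_genes)`.
#' @return list with `records` (validated PheWAS tibble) and `truth`
#'   (tibble `variant`, `phenotype`, `signal`).
#' @export
gen_phewas <- function(config, genes = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(config$n_genes))
  with_local_seed(substream(config, 202L), {
    n_keys <- length(genes) * config$n_variants_per_gene
    key <- tibble::tibble(
      variant = sprintf("rs%07d", seq_len(n_keys)),
      gene = rep(genes, each = config$n_variants_per_gene),
      pheno_idx = sample.int(nrow(PHENOTYPE_VOCAB), n_keys, replace = TRUE),
      signal = stats::runif(n_keys) <= config$signal_fraction)
    rec <- key[rep(seq_len(n_keys), each = 4L), ]
    rec$model <- rep(PHEWAS_MODELS, times = n_keys)
    rec$p <- ifelse(rec$signal,
                    10^(-stats::runif(nrow(rec), 8, 15)),
                    stats::runif(nrow(rec)))
    rec$phenotype <- PHENOTYPE_VOCAB$phenotype[rec$pheno_idx]
    rec$category <- PHENOTYPE_VOCAB$category[rec$pheno_idx]
    rec$type <- PHENOTYPE_VOCAB$type[rec$pheno_idx]
    rec$effect <- ifelse(rec$type == "binary",
                         stats::rlnorm(nrow(rec), config$or_meanlog,
                                       config$or_sdlog),
                         stats::rnorm(nrow(rec)))
    records <- validate_phewas(rec[, c("variant", "gene", "phenotype",
                                       "category", "model", "p", "effect",
                                       "type")])
    truth <- tibble::tibble(variant = key$variant,
                            phenotype = PHENOTYPE_VOCAB$phenotype[key$pheno_idx],
                            signal = key$signal)
    list(records = records, truth = truth)
  })
}

#' Generate a synthetic phenotype ontology with annotations and families
#'
#' Builds a random DAG (depth at most 5, at most 3 parents per term),
#' annotates universe genes to terms at a uniform background probability,
#' plants elevated annotation probabilities for configured (family, term)
#' pairs among that family's genes, and draws family gene sets from the
#' universe.
#'
#' @param config a [generator_config()]; `planted_pairs` entries are lists
#'   `list(family =, term =, prob =)` where `term` is an index into the
#'   generated terms.
#' @param family_sizes named integer vector of family gene-set sizes;
#'   defaults to `config$families`.
#' @return list with `ontology`, `direct` (term -> genes), `annotations`
#'   (propagated `annotation_map`), `families` (named list of gene sets)
#'   and `truth` (tibble of planted family-term pairs).
#' @export
gen_hpo <- function(config, family_sizes = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(family_sizes)) family_sizes <- config$families
  with_local_seed(substream(config, 303L), {
    n <- config$n_terms
    ids <- sprintf("HP:%07d", seq_len(n))
    depth <- 5L
    level <- sort(sample.int(depth, n, replace = TRUE))
    edges <- list()
    for (i in which(level > 1)) {
      pool <- which(level < level[i])
      if (length(pool) == 0) next
      k <- sample.int(min(3L, length(pool)), 1L)
      pars <- if (length(pool) == 1) pool else sample(pool, k)
      edges[[length(edges) + 1L]] <- tibble::tibble(child = ids[i],
                                                    parent = ids[pars])
    }
    edges <- if (length(edges)) do.call(rbind, edges) else
      tibble::tibble(child = character(), parent = character())
    ontology <- new_ontology(tibble::tibble(id = ids, name = paste("term", ids)),
                             edges)

    universe <- sprintf("U%05d", seq_len(config$universe_size))
    direct <- stats::setNames(lapply(ids, function(t) {
      universe[stats::runif(config$universe_size) <= config$annotation_prob]
    }), ids)

    families <- stats::setNames(lapply(family_sizes, function(k) {
      sample(universe, k)
    }), names(family_sizes))

    planted <- tibble::tibble(family = character(), term = character(),
                              prob = numeric())
    for (pp in config$planted_pairs) {
      term_id <- ids[[pp$term]]
      fam_genes <- families[[pp$family]]
      extra <- fam_genes[stats::runif(length(fam_genes)) <= pp$prob]
      direct[[term_id]] <- union(direct[[term_id]], extra)
      planted <- rbind(planted, tibble::tibble(family = pp$family,
                                               term = term_id,
                                               prob = pp$prob))
    }
    annotations <- propagate_annotations(ontology, direct, universe)
    list(ontology = ontology, direct = direct, annotations = annotations,
         families = families, truth = planted)
  })
}

#' Generate a synthetic single-cell count matrix with planted markers
#'
#' Counts are negative-binomial with mean `nb_mean` and dispersion
#' `nb_dispersion` (variance `mean + dispersion * mean^2`). Each class
#' receives `markers_per_class` dedicated marker genes whose in-class mean
#' is multiplied by `marker_fold`; class labels are balanced at
#' `cells_per_class`.
#'
#' @param config a [generator_config()].
#' @return list with `counts` (an `e3_counts`, layer `raw`), `labels`
#'   (named character vector cell -> class) and `truth` (tibble `gene`,
#'   `class` of planted markers).
#' @export
gen_sc_counts <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(substream(config, 404L), {
    n_genes <- config$n_sc_genes
    n_classes <- config$n_classes
    n_cells <- n_classes * config$cells_per_class
    genes <- sprintf("G%05d", seq_len(n_genes))
    cells <- sprintf("cell_%05d", seq_len(n_cells))
    classes <- sprintf("class_%02d", seq_len(n_classes))
    labels <- stats::setNames(rep(classes, each = config$cells_per_class), cells)

    mk <- config$markers_per_class
    if (mk * n_classes > n_genes) stop_value("more planted markers than genes")
    truth <- tibble::tibble(
      gene = genes[seq_len(mk * n_classes)],
      class = rep(classes, each = mk))

    mu <- base::matrix(config$nb_mean, nrow = n_genes, ncol = n_cells,
                       dimnames = list(genes, cells))
    if (config$marker_fold != 1 && mk > 0) {
      for (k in seq_len(n_classes)) {
        rows <- truth$gene[truth$class == classes[k]]
        cols <- names(labels)[labels == classes[k]]
        mu[rows, cols] <- mu[rows, cols] * config$marker_fold
      }
    }
    size <- 1 / config$nb_dispersion
    counts <- base::matrix(
      stats::rnbinom(n_genes * n_cells, mu = as.vector(mu), size = size),
      nrow = n_genes, dimnames = list(genes, cells))
    list(counts = e3_counts(counts, layer = "raw"), labels = labels,
         truth = truth)
  })
}

#' Generate synthetic tissue/donor sample metadata
#'
#' `n_tissues` tissues with `donors_per_tissue` donors each; donors are
#' unique across tissues and contribute one to three samples.
#'
#' @param config a [generator_config()].
#' @return tibble with columns `sample`, `donor`, `tissue`.
#' @export
gen_tissue_metadata <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(substream(config, 505L), {
    n_donors <- config$n_tissues * config$donors_per_tissue
    donors <- sprintf("D%05d", seq_len(n_donors))
    tissues <- rep(sprintf("tissue_%02d", seq_len(config$n_tissues)),
                   each = config$donors_per_tissue)
    n_samples <- sample.int(3L, n_donors, replace = TRUE)
    tibble::tibble(
      sample = sprintf("%s_s%d", rep(donors, n_samples),
                       unlist(lapply(n_samples, seq_len))),
      donor = rep(donors, n_samples),
      tissue = rep(tissues, n_samples))
  })
}

#' Write a synthetic evidence dataset to ledger input files
#'
#' Writes the gene, vote and evidence tables in the format [load_ledger()]
#' reads, plus a `truth.json` with the generating seed and truth table.
#'
#' @param gen output of [gen_evidence()].
#' @param dir output directory (created if needed).
#' @param seed seed echoed into `truth.json`.
#' @return invisibly, the written file paths.
#' @export
write_evidence_dataset <- function(gen, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  led <- gen$ledger
  genes <- tibble::tibble(
    symbol = led$genes$symbol,
    aliases = vapply(led$genes$aliases, paste, character(1), collapse = "|"),
    protein_coding = as.integer(led$genes$protein_coding))
  paths <- c(genes = file.path(dir, "genes.tsv"),
             votes = file.path(dir, "votes.tsv"),
             evidence = file.path(dir, "evidence.tsv"),
             truth = file.path(dir, "truth.json"))
  write_tsv_file(genes, paths[["genes"]])
  votes <- led$votes
  names(votes)[names(votes) == "gene"] <- "symbol"
  write_tsv_file(votes, paths[["votes"]])
  ev <- led$evidence
  names(ev)[names(ev) == "gene"] <- "symbol"
  write_tsv_file(ev, paths[["evidence"]])
  jsonlite::write_json(list(seed = seed, truth = gen$truth),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
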