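#' Minimal OBO ontology reader
#'
#' Parses `[Term]` stanzas from an OBO file, keeping the `id`, `name` and
#' `is_a` fields and skipping obsolete terms. Trailing `!` comments on
#' `is_a` lines are stripped. This covers what term enrichment needs (the
#' DAG structure); no other OBO semantics are interpreted.
#'
#' @param path OBO file path.
#' @return an `e3_ontology`: list with tibbles `terms` (`id`, `name`) and
#'   `edges` (`child`, `parent`).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("OBO file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  ids <- character(); names_ <- character()
  children <- character(); parents <- character()
  cur_id <- NA_character_; cur_name <- NA_character_
  cur_parents <- character(); obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (in_term && !is.na(cur_id) && !obsolete) {
      ids <<- c(ids, cur_id)
      names_ <<- c(names_, cur_name)
      if (length(cur_parents) > 0) {
        children <<- c(children, rep(cur_id, length(cur_parents)))
        parents <<- c(parents, cur_parents)
      }
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE; cur_id <- NA_character_; cur_name <- NA_character_
      cur_parents <- character(); obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) {
        cur_id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "name:")) {
        cur_name <- trimws(sub("^name:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        if (nzchar(p)) cur_parents <- c(cur_parents, p)
      } else if (startsWith(ln, "is_obsolete:") && grepl("true", ln)) {
        obsolete <- TRUE
      }
    }
  }
  flush()
  new_ontology(tibble::tibble(id = ids, name = names_),
               tibble::tibble(child = children, parent = parents))
}

#' Construct an ontology from term and edge tables
#'
#' @param terms tibble with columns `id`, `name`.
#' @param edges tibble with columns `child`, `parent` (is-a edges).
#' @return an `e3_ontology`.
#' @export
new_ontology <- function(terms, edges) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  require_columns(terms, c("id", "name"), "ontology terms")
  require_columns(edges, c("child", "parent"), "ontology edges")
  if (any(edges$child == edges$parent)) stop_value("ontology contains a self-parenting term")
  edges <- edges[edges$child %in% terms$id & edges$parent %in% terms$id, ]
  structure(list(terms = terms, edges = unique(edges)), class = "e3_ontology")
}

#' @export
print.e3_ontology <- function(x, ...) {
  cat(sprintf("<e3_ontology> %d terms, %d is-a edges\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

# topological order (leaves last); errors on cycles
topo_order <- function(ontology) {
  ids <- ontology$terms$id
  kids <- split(ontology$edges$child, ontology$edges$parent)
  indeg <- stats::setNames(integer(length(ids)), ids)  # number of parents
  tab <- table(ontology$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  queue <- ids[indeg == 0]
  out <- character(0)
  parent_of <- split(ontology$edges$parent, ontology$edges$child)
  child_of <- split(ontology$edges$child, ontology$edges$parent)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (c in child_of[[v]] %||% character()) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != length(ids)) stop_value("ontology contains a cycle")
  out
}
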