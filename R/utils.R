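# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a fixed RNG seed without disturbing the caller's stream
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Canonicalize a gene symbol token
#'
#' Uppercases and strips surrounding whitespace (HGNC convention).
#' @keywords internal
#' @noRd
canon_symbol <- function(x) toupper(trimws(as.character(x)))

# stop() wrappers carrying a class so callers can distinguish error kinds
stop_schema <- function(msg) {
  stop(errorCondition(msg, class = c("e3ome_schema_error", "error")))
}
stop_value <- function(msg) {
  stop(errorCondition(msg, class = c("e3ome_value_error", "error")))
}
stop_capacity <- function(msg) {
  stop(errorCondition(msg, class = c("e3ome_capacity_error", "error")))
}
stop_lookup <- function(msg) {
  stop(errorCondition(msg, class = c("e3ome_lookup_error", "error")))
}
stop_ambiguity <- function(msg) {
  stop(errorCondition(msg, class = c("e3ome_ambiguity_error", "error")))
}

#' Read a delimited table with a header row
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @keywords internal
#' @noRd
read_table_file <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_schema(sprintf("input file not found: %s", path))
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = c("NA", ""))
  tibble::as_tibble(df)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Write a tibble as TSV with deterministic formatting
#' @keywords internal
#' @noRd
write_tsv_file <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 9, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
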