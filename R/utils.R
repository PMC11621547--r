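#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif setNames
NULL

# Canonical RNA alphabet used throughout: gaps are '-', ambiguity collapses to N.
RNA_ALPHABET <- c("A", "C", "G", "U")
GAP_CHARS <- c("-", ".")

#' Canonicalize RNA residue strings
#'
#' Upper-cases, converts T to U, normalizes '.' gaps to '-', and collapses all
#' IUPAC ambiguity codes to N. Characters outside the IUPAC nucleotide set
#' raise an error.
#'
#' @param x character vector of residue strings (gapped or ungapped).
#' @param allow_gap keep gap characters (for alignment rows)?
#' @return character vector over \{A,C,G,U,N\} (plus '-' when `allow_gap`).
#' @export
canonicalize_rna <- function(x, allow_gap = TRUE) {
  x <- toupper(x)
  x <- chartr("T.", "U-", x)
  # every IUPAC ambiguity code (incl. N) -> N, so the N fraction after
  # collapsing equals the ambiguity-character fraction before it
  x <- gsub("[RYSWKMBDHVN]", "N", x)
  bad <- grepl(if (allow_gap) "[^ACGUN-]" else "[^ACGUN]", x)
  if (any(bad)) {
    abort(sprintf("non-nucleotide characters in sequence(s): %s",
                  paste(utils::head(which(bad), 3), collapse = ", ")))
  }
  x
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# rows of an aligned family as an R x L character matrix
family_matrix <- function(family) {
  do.call(rbind, strsplit(family$rows, "", fixed = TRUE))
}

# accept a tibble with id/seq columns, a named character vector, or a bare
# character vector; return a tibble(id, seq)
as_seq_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    tibble(id = as.character(x$id), seq = as.character(x$seq))
  } else {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    tibble(id = ids, seq = unname(as.character(x)))
  }
}

#' Format 1-based mutation names like "U2477C"
#' @param from,position,to vectors describing substitutions.
#' @return character vector of mutation names.
#' @export
mutation_name <- function(from, position, to) {
  paste0(from, position, to)
}
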