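#' Aligned RNA family
#'
#' Container for a multiple sequence alignment with an optional consensus
#' secondary structure (WUSS), a per-column consensus (match-column) mask, and
#' optional per-sequence optimal-growth-temperature labels in degrees Celsius.
#' All columns are 1-based.
#'
#' @param ids character vector of row identifiers (unique).
#' @param rows character vector of aligned strings over \{A,C,G,U,N,-\}, all of
#'   equal length.
#' @param ss_cons optional WUSS consensus-structure string of the same length.
#' @param consensus_mask optional logical vector flagging consensus (match)
#'   columns; defaults to all `TRUE`.
#' @param labels optional numeric vector of growth temperatures (degrees C),
#'   one per row.
#' @return an object of class `aligned_family`.
#' @export
aligned_family <- function(ids, rows, ss_cons = NULL, consensus_mask = NULL,
                           labels = NULL) {
  stopifnot(length(ids) == length(rows), length(rows) >= 1)
  if (anyDuplicated(ids)) abort("row ids must be unique")
  rows <- canonicalize_rna(rows, allow_gap = TRUE)
  n_columns <- nchar(rows[1])
  if (n_columns == 0) abort("alignment has zero columns")
  if (any(nchar(rows) != n_columns)) {
    abort(sprintf("ragged alignment: rows differ in length (expected %d)", n_columns))
  }
  if (!is.null(ss_cons)) {
    if (nchar(ss_cons) != n_columns) {
      abort("ss_cons length does not match the number of alignment columns")
    }
    pairs_from_wuss(ss_cons) # validates bracket balance
  }
  if (is.null(consensus_mask)) consensus_mask <- rep(TRUE, n_columns)
  stopifnot(length(consensus_mask) == n_columns)
  if (!is.null(labels)) stopifnot(length(labels) == length(rows))
  structure(
    list(ids = as.character(ids), rows = setNames(rows, ids),
         n_columns = n_columns, ss_cons = ss_cons,
         consensus_mask = as.logical(consensus_mask), labels = labels),
    class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family> %d rows x %d columns%s%s\n",
              length(x$rows), x$n_columns,
              if (!is.null(x$ss_cons)) ", with SS_cons" else "",
              if (!is.null(x$labels)) ", labeled" else ""))
  invisible(x)
}

#' Base pairs from a WUSS consensus-structure string
#'
#' Matches nested brackets of the four WUSS bracket families `<>`, `()`, `[]`
#' and `{}` innermost-first. Non-bracket characters (including pseudoknot
#' letters) are unpaired.
#'
#' @param ss WUSS string.
#' @return a tibble with 1-based columns `i < j`, one row per pair, ordered
#'   by `i`.
#' @export
pairs_from_wuss <- function(ss) {
  ch <- seq_chars(ss)
  open <- c("<" = ">", "(" = ")", "[" = "]", "{" = "}")
  stacks <- list("<" = integer(), "(" = integer(), "[" = integer(), "{" = integer())
  out_i <- integer(); out_j <- integer()
  for (pos in seq_along(ch)) {
    c0 <- ch[pos]
    if (c0 %in% names(open)) {
      stacks[[c0]] <- c(stacks[[c0]], pos)
    } else if (c0 %in% open) {
      key <- names(open)[match(c0, open)]
      st <- stacks[[key]]
      if (length(st) == 0) {
        abort(sprintf("unbalanced bracket '%s' at column %d", c0, pos))
      }
      out_i <- c(out_i, st[length(st)]); out_j <- c(out_j, pos)
      stacks[[key]] <- st[-length(st)]
    }
  }
  left <- unlist(lapply(stacks, identity))
  if (length(left) > 0) {
    abort(sprintf("unbalanced bracket at column %d", min(left)))
  }
  ord <- order(out_i)
  tibble(i = out_i[ord], j = out_j[ord])
}

#' Per-column occupancy of an aligned family
#'
#' @param family an [aligned_family()].
#' @return numeric vector in \[0,1\]: the fraction of rows with a non-gap
#'   residue in each column (N counts as occupied).
#' @export
column_occupancy <- function(family) {
  m <- family_matrix(family)
  colMeans(m != "-")
}

#' Project an alignment onto a reference row's coordinates
#'
#' Keeps exactly the columns where the reference row is non-gap, so that
#' column `k` of the result is nucleotide `k` of the reference sequence.
#' Consensus-structure pairs losing an endpoint are dropped from the
#' projected `ss_cons`.
#'
#' @param family an [aligned_family()].
#' @param ref_row_id id of the reference row.
#' @return a list with elements `family` (the projected [aligned_family()])
#'   and `column_map`, a tibble mapping `old` to `new` 1-based column indices.
#' @export
project_to_reference <- function(family, ref_row_id) {
  if (!ref_row_id %in% family$ids) {
    abort(sprintf("reference row '%s' not found in family", ref_row_id))
  }
  ref <- seq_chars(family$rows[[ref_row_id]])
  keep <- which(ref != "-")
  if (length(keep) == 0) abort("reference row is all gaps: empty projection")
  new_rows <- vapply(family$rows,
                     function(r) paste(seq_chars(r)[keep], collapse = ""), "")
  ss <- NULL
  if (!is.null(family$ss_cons)) {
    pr <- pairs_from_wuss(family$ss_cons)
    new_index <- rep(NA_integer_, family$n_columns)
    new_index[keep] <- seq_along(keep)
    ss_ch <- rep(".", length(keep))
    ok <- !is.na(new_index[pr$i]) & !is.na(new_index[pr$j])
    ss_ch[new_index[pr$i[ok]]] <- "("
    ss_ch[new_index[pr$j[ok]]] <- ")"
    ss <- paste(ss_ch, collapse = "")
  }
  fam <- aligned_family(family$ids, unname(new_rows), ss_cons = ss,
                        consensus_mask = family$consensus_mask[keep],
                        labels = family$labels)
  list(family = fam, column_map = tibble(old = keep, new = seq_along(keep)))
}

#' Restrict a pair list to surviving columns after projection
#'
#' @param pairs tibble with columns `i`, `j` in the original coordinates.
#' @param column_map the `column_map` returned by [project_to_reference()].
#' @return pairs re-indexed to the new coordinates; pairs with a dropped
#'   endpoint are removed.
#' @export
project_pairs <- function(pairs, column_map) {
  new_index <- rep(NA_integer_, max(column_map$old, pairs$j, 0))
  new_index[column_map$old] <- column_map$new
  i2 <- new_index[pairs$i]; j2 <- new_index[pairs$j]
  ok <- !is.na(i2) & !is.na(j2)
  tibble(i = i2[ok], j = j2[ok])
}
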