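#' Read RNA sequences from a FASTA file
#'
#' Residues are canonicalized on read: T becomes U, case is folded, and IUPAC
#' ambiguity codes collapse to N. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `seq`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  first <- which(!grepl("^\\s*$", lines))[1]
  if (is.na(first) || !startsWith(lines[first], ">")) {
    abort(sprintf("malformed FASTA in %s: line %d does not start a record",
                  path, if (is.na(first)) 1L else first))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- canonicalize_rna(as.character(set), allow_gap = FALSE)
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("empty sequence for record '%s'", ids[nchar(seqs) == 0][1]))
  }
  tibble(id = ids, seq = unname(seqs), description = desc)
}

#' Write sequences to a FASTA file
#'
#' @param sequences tibble with `id` and `seq` columns (optionally
#'   `description`), or a named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  tbl <- as_seq_tbl(sequences)
  desc <- if (is.data.frame(sequences) && "description" %in% names(sequences)) {
    sequences$description
  } else rep("", nrow(tbl))
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_len(nrow(tbl))) {
    hdr <- if (nzchar(desc[k])) paste(tbl$id[k], desc[k]) else tbl$id[k]
    writeLines(paste0(">", hdr), con)
    s <- tbl$seq[k]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Stockholm 1.0 alignment
#'
#' Supports interleaved blocks and the `#=GC SS_cons` and `#=GC RF` annotation
#' lines. Both `.` and `-` are read as gaps. Consensus (match) columns are
#' taken from the RF annotation when present; otherwise a column counts as
#' consensus when any row carries an upper-case residue or a `-` gap there
#' (lower-case/`.` columns are Rfam-style inserts).
#'
#' @param path path to a Stockholm file.
#' @return an [aligned_family()]; `ss_cons` is `NULL` when the file has no
#'   SS_cons line.
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^# STOCKHOLM", lines))) {
    abort(sprintf("%s is not a Stockholm 1.0 file (missing header)", path))
  }
  seqs <- list(); order <- character()
  ss <- ""; rf <- ""
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || ln == "//") next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#=GC\\s+(\\S+)\\s+(\\S+)\\s*$", ln))[[1]]
      if (length(m) == 3) {
        if (m[2] == "SS_cons") ss <- paste0(ss, m[3])
        if (m[2] == "RF") rf <- paste0(rf, m[3])
      }
      next
    }
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)\\s*$", ln))[[1]]
    if (length(m) != 3) abort(sprintf("malformed Stockholm sequence line: '%s'", ln))
    id <- m[2]
    if (is.null(seqs[[id]])) { seqs[[id]] <- ""; order <- c(order, id) }
    seqs[[id]] <- paste0(seqs[[id]], m[3])
  }
  if (length(seqs) == 0) abort(sprintf("no sequence rows in %s", path))
  raw <- unlist(seqs[order])
  widths <- nchar(raw)
  if (length(unique(widths)) != 1) {
    abort(sprintf("ragged Stockholm alignment: row lengths %s",
                  paste(unique(widths), collapse = ", ")))
  }
  n_col <- widths[1]
  if (nzchar(rf) && nchar(rf) == n_col) {
    mask <- !seq_chars(rf) %in% c(".", "-", "~")
  } else {
    cm <- do.call(rbind, strsplit(unname(raw), "", fixed = TRUE))
    mask <- apply(cm, 2, function(col) any(col == "-" | grepl("[A-Z]", col)))
  }
  ss_cons <- if (nzchar(ss)) {
    if (nchar(ss) != n_col) abort("SS_cons length does not match alignment width")
    ss
  } else NULL
  aligned_family(order, unname(raw), ss_cons = ss_cons, consensus_mask = mask)
}

#' Write an aligned family as Stockholm 1.0
#'
#' Writes a single-block alignment with `#=GC SS_cons` when present.
#'
#' @param family an [aligned_family()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(family, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  width <- max(nchar(family$ids), nchar("#=GC SS_cons")) + 2L
  for (k in seq_along(family$ids)) {
    writeLines(sprintf("%-*s%s", width, family$ids[k], family$rows[[k]]), con)
  }
  if (!is.null(family$ss_cons)) {
    writeLines(sprintf("%-*s%s", width, "#=GC SS_cons", family$ss_cons), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Export a projection column map as TSV
#'
#' @param column_map the `column_map` tibble from [project_to_reference()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_column_map <- function(column_map, path) {
  utils::write.table(column_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Strip gaps from aligned rows
#'
#' @param family an [aligned_family()].
#' @return a tibble with `id` and ungapped `seq` columns.
#' @export
ungap_family <- function(family) {
  tibble(id = family$ids, seq = unname(gsub("-", "", family$rows, fixed = TRUE)))
}
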