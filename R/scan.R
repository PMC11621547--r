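#' Per-column nucleotide frequencies of an aligned set
#'
#' Frequencies over \{A,C,G,U\}; gaps and N are excluded from the denominator
#' by default. With `gap_inclusive = TRUE` the gap is counted as a fifth
#' symbol (useful for alignment-coordinate model output, where deletions are
#' informative).
#'
#' @param rows an [aligned_family()], a character matrix, or a character
#'   vector of equal-width strings.
#' @param columns column indices (default: all).
#' @param gap_inclusive count '-' as a symbol?
#' @return a tibble with `column`, one frequency column per symbol, and
#'   `n_counted`; columns with nothing to count have `NA` frequencies and
#'   `n_counted = 0`.
#' @export
column_frequencies <- function(rows, columns = NULL, gap_inclusive = FALSE) {
  m <- rows_matrix(rows)
  columns <- columns %||% seq_len(ncol(m))
  syms <- if (gap_inclusive) c(RNA_ALPHABET, "-") else RNA_ALPHABET
  out <- lapply(columns, function(j) {
    col <- m[, j]
    counts <- vapply(syms, function(s) sum(col == s), 0)
    tot <- sum(counts)
    freqs <- if (tot > 0) counts / tot else rep(NA_real_, length(syms))
    c(list(column = j), as.list(setNames(freqs, syms)),
      list(n_counted = tot))
  })
  dplyr::bind_rows(lapply(out, tibble::as_tibble))
}

rows_matrix <- function(rows) {
  if (inherits(rows, "aligned_family")) return(family_matrix(rows))
  if (is.matrix(rows)) return(rows)
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

#' Jensen-Shannon divergence between two distributions
#'
#' `JSD(p, q) = H((p+q)/2) - (H(p) + H(q))/2` with base-2 entropy, so the
#' value is symmetric and bounded in \[0,1\], 0 iff p = q and 1 for disjoint
#' supports.
#'
#' @param p,q non-negative numeric vectors over the same support, each
#'   summing to 1 (tolerance 1e-6).
#' @return divergence in \[0,1\].
#' @export
jsd <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort("jsd() requires normalized probability vectors")
  }
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  h((p + q) / 2) - (h(p) + h(q)) / 2
}

#' Column-wise divergence scan between two generated-sequence sets
#'
#' Computes the Jensen-Shannon divergence of per-column nucleotide
#' frequencies (pretrained- vs finetuned-generated sets in the mutation
#' workflow), masking the columns used to seed generation and columns with
#' occupancy below `occupancy_min` in either set. Unmasked columns are
#' ranked by descending divergence, ties broken toward the lower column.
#'
#' For n-gram language models the seed mask should cover
#' `seed_nucleotides + (n - 1)` columns, since the first generated token
#' still overlaps the seed.
#'
#' @param pt_rows,ft_rows aligned sets in the same reference coordinates.
#' @param seed_mask_length leading columns to mask (reason `"seed"`).
#' @param occupancy_min minimum per-set occupancy for a column to be scored.
#' @param gap_inclusive passed to [column_frequencies()].
#' @return a `jsd_scan` tibble: column, jsd, occupancy_pt, occupancy_ft,
#'   masked, mask_reason, rank (NA for masked columns).
#' @export
jsd_scan <- function(pt_rows, ft_rows, seed_mask_length = 0,
                     occupancy_min = 0.5, gap_inclusive = FALSE) {
  mp <- rows_matrix(pt_rows); mf <- rows_matrix(ft_rows)
  if (ncol(mp) != ncol(mf)) {
    abort(sprintf("coordinate mismatch: %d vs %d columns", ncol(mp), ncol(mf)))
  }
  L <- ncol(mp)
  occ_p <- colMeans(mp != "-"); occ_f <- colMeans(mf != "-")
  fp <- column_frequencies(mp, gap_inclusive = gap_inclusive)
  ff <- column_frequencies(mf, gap_inclusive = gap_inclusive)
  syms <- setdiff(names(fp), c("column", "n_counted"))
  vals <- vapply(seq_len(L), function(j) {
    p <- as.numeric(fp[j, syms]); q <- as.numeric(ff[j, syms])
    if (anyNA(p) || anyNA(q)) return(NA_real_)
    jsd(p, q)
  }, 0)
  reason <- rep(NA_character_, L)
  reason[occ_p < occupancy_min | occ_f < occupancy_min | is.na(vals)] <- "low_occupancy"
  if (seed_mask_length > 0) reason[seq_len(min(seed_mask_length, L))] <- "seed"
  masked <- !is.na(reason)
  rank <- rep(NA_integer_, L)
  open <- which(!masked)
  rank[open[order(-vals[open], open)]] <- seq_along(open)
  out <- tibble(column = seq_len(L), jsd = vals,
                occupancy_pt = occ_p, occupancy_ft = occ_f,
                masked = masked, mask_reason = reason, rank = rank)
  class(out) <- c("jsd_scan", class(out))
  out
}

#' Overlap matrix of top-ranked columns across scans
#'
#' Entry (a, b) counts the shared columns among the `top_n` highest-ranked
#' columns of scans a and b; the diagonal is `top_n` (or the available
#' ranking length, flagged via attribute `truncated`).
#'
#' @param rankings named list of `jsd_scan` tibbles or ranked column-index
#'   vectors.
#' @param top_n ranks considered.
#' @return symmetric integer matrix.
#' @export
overlap_matrix <- function(rankings, top_n = 200) {
  stopifnot(length(rankings) >= 2)
  tops <- lapply(rankings, function(r) {
    v <- if (is.data.frame(r)) {
      ok <- !is.na(r$rank)
      r$column[ok][order(r$rank[ok])]
    } else as.integer(r)
    utils::head(v, top_n)
  })
  truncated <- any(vapply(tops, length, 0L) < top_n)
  n <- length(tops)
  M <- matrix(0L, n, n,
              dimnames = list(names(rankings), names(rankings)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    M[a, b] <- length(intersect(tops[[a]], tops[[b]]))
  }
  if (truncated) attr(M, "truncated") <- TRUE
  M
}

#' Specify a set of point substitutions
#'
#' @param position 1-based positions in the wild-type sequence.
#' @param from wild-type nucleotides at those positions (checked).
#' @param to replacement nucleotides.
#' @return a `mutation_spec` tibble with a canonical `name` (e.g. "U2477C").
#' @export
mutation_spec <- function(position = integer(), from = character(),
                          to = character()) {
  stopifnot(length(position) == length(from), length(from) == length(to))
  if (anyDuplicated(position)) abort("mutation positions must be distinct")
  out <- tibble(position = as.integer(position), from = from, to = to)
  attr(out, "label") <- paste(mutation_name(from, position, to),
                              collapse = "+")
  class(out) <- c("mutation_spec", class(out))
  out
}

apply_mutations <- function(wt, spec) {
  ch <- seq_chars(wt)
  if (nrow(spec) == 0) return(wt)
  if (any(spec$position < 1 | spec$position > length(ch))) {
    abort("mutation position outside the sequence")
  }
  mism <- which(ch[spec$position] != spec$from)
  if (length(mism) > 0) {
    abort(sprintf("wild-type mismatch at position %d: sequence has %s, spec says %s",
                  spec$position[mism[1]], ch[spec$position[mism[1]]],
                  spec$from[mism[1]]))
  }
  ch[spec$position] <- spec$to
  paste(ch, collapse = "")
}

#' Finetuned-vs-pretrained log-probability score of a mutation
#'
#' Builds the mutant by substitution and computes
#' `ddlogP = (logP_FT(mut) - logP_PT(mut)) - (logP_FT(wt) - logP_PT(wt))`:
#' the wild type serves as the normalization control, and positive values
#' mean the finetuned model supports the mutant better than the pretrained
#' model does, beyond its baseline preference for the wild type.
#'
#' @param ft_model,pt_model finetuned and pretrained models sharing a
#'   vocabulary.
#' @param wt wild-type sequence.
#' @param spec a [mutation_spec()]; empty spec scores the wild type (0).
#' @param logprob log-probability function `f(model, seqs)`; defaults to
#'   [sequence_log_probability()] (use [gnn_log_probability()] for
#'   alignment-coordinate models).
#' @param wt_logp optional precomputed `c(ft, pt)` wild-type log-probs.
#' @return a `mutation_score` tibble row: name, the four log-probabilities,
#'   and `ddlogp`.
#' @export
ddlogp <- function(ft_model, pt_model, wt, spec,
                   logprob = sequence_log_probability, wt_logp = NULL) {
  mut <- apply_mutations(wt, spec)
  if (is.null(wt_logp)) {
    wt_logp <- c(ft = as.numeric(logprob(ft_model, wt)),
                 pt = as.numeric(logprob(pt_model, wt)))
  }
  lf <- as.numeric(logprob(ft_model, mut))
  lp <- as.numeric(logprob(pt_model, mut))
  out <- tibble(name = attr(spec, "label") %||% "WT",
                logp_ft_mut = lf, logp_pt_mut = lp,
                logp_ft_wt = unname(wt_logp[1]), logp_pt_wt = unname(wt_logp[2]),
                ddlogp = (lf - lp) - (unname(wt_logp[1]) - unname(wt_logp[2])))
  class(out) <- c("mutation_score", class(out))
  out
}

#' Reference distribution of all single-nucleotide mutants
#'
#' Scores every possible single substitution of the wild type (3L mutants)
#' with [ddlogp()] and returns the empirical distribution together with a
#' strict percentile function: `percentile(x)` is 100 times the fraction of
#' reference values strictly below x, matching the reading "supported better
#' than P% of all possible single mutants".
#'
#' @inheritParams ddlogp
#' @param batch_size mutants scored per model call.
#' @return a `single_mutant_reference` list: `scores` (tibble position,
#'   from, to, name, ddlogp), `percentile` (function), `mean`, `sd`.
#' @export
single_mutant_reference <- function(ft_model, pt_model, wt,
                                    logprob = sequence_log_probability,
                                    batch_size = 256) {
  ch <- seq_chars(wt)
  L <- length(ch)
  grid <- dplyr::bind_rows(lapply(seq_len(L), function(pos) {
    tibble(position = pos, from = ch[pos],
           to = setdiff(RNA_ALPHABET, ch[pos]))
  }))
  muts <- vapply(seq_len(nrow(grid)), function(r) {
    z <- ch; z[grid$position[r]] <- grid$to[r]; paste(z, collapse = "")
  }, "")
  wt_f <- as.numeric(logprob(ft_model, wt))
  wt_p <- as.numeric(logprob(pt_model, wt))
  lf <- numeric(length(muts)); lp <- numeric(length(muts))
  i <- 1L
  while (i <= length(muts)) {
    take <- i:min(i + batch_size - 1L, length(muts))
    lf[take] <- as.numeric(logprob(ft_model, muts[take]))
    lp[take] <- as.numeric(logprob(pt_model, muts[take]))
    i <- i + batch_size
  }
  scores <- grid
  scores$name <- mutation_name(grid$from, grid$position, grid$to)
  scores$ddlogp <- (lf - lp) - (wt_f - wt_p)
  vals <- scores$ddlogp
  structure(list(scores = scores,
                 percentile = function(x) 100 * mean(vals < x),
                 mean = mean(vals), sd = stats::sd(vals),
                 wt_logp = c(ft = wt_f, pt = wt_p)),
            class = "single_mutant_reference")
}

#' @export
print.single_mutant_reference <- function(x, ...) {
  cat(sprintf("<single_mutant_reference> %d mutants; ddlogP mean %.3f, sd %.3f\n",
              nrow(x$scores), x$mean, x$sd))
  invisible(x)
}

#' Write a JSD scan or mutation table as TSV
#' @param x a tibble (e.g. from [jsd_scan()] or [single_mutant_reference()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
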