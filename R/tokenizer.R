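#' Build an overlapping n-gram tokenizer vocabulary
#'
#' The vocabulary holds every n-gram over \{A,C,G,U\} in lexicographic order
#' (ids contiguous from 0) followed by the three special tokens BOS, EOS and
#' PAD. Tokens advance in 1-nucleotide steps, so consecutive n-grams overlap
#' by n-1 nucleotides.
#'
#' @param n n-gram size: 1, 2 or 3.
#' @return a `tok_spec` list with fields `n`, `tokens`, `bos_id`, `eos_id`,
#'   `pad_id`, `vocab_size` (ids are 0-based).
#' @export
build_vocab <- function(n) {
  if (!n %in% 1:3) abort("n-gram size must be 1, 2 or 3")
  grams <- RNA_ALPHABET
  if (n >= 2) {
    for (k in 2:n) {
      grams <- as.vector(t(outer(grams, RNA_ALPHABET, paste0)))
    }
  }
  grams <- sort(grams)
  tokens <- c(grams, "<bos>", "<eos>", "<pad>")
  structure(list(n = as.integer(n), tokens = tokens,
                 bos_id = 4L^n, eos_id = 4L^n + 1L, pad_id = 4L^n + 2L,
                 vocab_size = length(tokens)),
            class = "tok_spec")
}

#' @export
print.tok_spec <- function(x, ...) {
  cat(sprintf("<tok_spec> overlapping %d-gram, vocab %d (= 4^%d + 3 specials)\n",
              x$n, x$vocab_size, x$n))
  invisible(x)
}

# 0-based codes A=0 C=1 G=2 U=3, NA for anything else
nt_codes <- function(chars) {
  match(chars, RNA_ALPHABET) - 1L
}

#' Encode an RNA sequence as overlapping n-gram token ids
#'
#' @param seq residue string over \{A,C,G,U\} of length >= n. Sequences
#'   containing N must be filtered upstream (quality control); they are
#'   rejected here.
#' @param spec a [build_vocab()] tokenizer.
#' @return a `tok_seq` list: `ids` (0-based integer vector
#'   `[BOS, ngrams..., EOS]`) and `source_length`.
#' @export
encode <- function(seq, spec) {
  ch <- seq_chars(seq)
  codes <- nt_codes(ch)
  if (anyNA(codes)) {
    abort(paste("sequence contains characters outside {A,C,G,U}",
                "(N and gaps must be removed by QC before encoding)"))
  }
  n <- spec$n; L <- length(codes)
  if (L < n) abort(sprintf("sequence length %d is shorter than n-gram size %d", L, n))
  body <- integer(L - n + 1)
  for (k in 0:(n - 1)) {
    body <- body + codes[(1 + k):(L - n + 1 + k)] * 4L^(n - 1 - k)
  }
  structure(list(ids = c(spec$bos_id, body, spec$eos_id),
                 source_length = L),
            class = "tok_seq")
}

#' Decode overlapping n-gram token ids back to a sequence
#'
#' Reconstructs the sequence from the first character of each body token plus
#' the trailing n-1 characters of the last one, counting adjacent token pairs
#' whose (n-1)-nucleotide overlap disagrees. `decode(encode(s))` returns
#' `(s, 0)` exactly.
#'
#' @param tokens a `tok_seq` or 0-based integer id vector starting with BOS.
#' @param spec the tokenizer used to encode.
#' @return list with `seq` (character) and `inconsistencies` (count).
#' @export
decode <- function(tokens, spec) {
  ids <- if (inherits(tokens, "tok_seq")) tokens$ids else as.integer(tokens)
  if (length(ids) == 0 || ids[1] != spec$bos_id) {
    abort("token sequence must begin with BOS")
  }
  body <- ids[-1]
  eos_at <- match(spec$eos_id, body)
  if (!is.na(eos_at)) body <- body[seq_len(eos_at - 1)]
  if (spec$pad_id %in% body) abort("PAD token inside the sequence body")
  if (any(body >= 4L^spec$n)) abort("unexpected special token inside the body")
  if (length(body) == 0) return(list(seq = "", inconsistencies = 0L))
  toks <- spec$tokens[body + 1L]
  n <- spec$n
  seq <- paste0(paste(substr(toks, 1, 1), collapse = ""),
                substr(toks[length(toks)], 2, n))
  inc <- 0L
  if (n > 1 && length(toks) > 1) {
    prev_tail <- substr(toks[-length(toks)], 2, n)
    next_head <- substr(toks[-1], 1, n - 1)
    inc <- sum(prev_tail != next_head)
  }
  list(seq = seq, inconsistencies = inc)
}

#' Encode a set of sequences
#'
#' @param sequences tibble with `id`/`seq` or a named character vector.
#' @param spec a [build_vocab()] tokenizer.
#' @return named list of 0-based integer id vectors.
#' @export
encode_dataset <- function(sequences, spec) {
  tbl <- as_seq_tbl(sequences)
  out <- lapply(tbl$seq, function(s) encode(s, spec)$ids)
  names(out) <- tbl$id
  out
}

#' Perplexity from a mean negative log-likelihood
#'
#' Token perplexity `exp(mean NLL)`, where the mean is taken over non-PAD
#' tokens. Because tokens advance in 1-nucleotide steps, each prediction
#' reveals exactly one new nucleotide and token perplexity doubles as
#' per-nucleotide perplexity: 4 is the random floor for RNA under every
#' n-gram scheme, 1 is perfect certainty.
#'
#' @param mean_nll_per_token mean negative log-likelihood (natural log).
#' @return perplexity (>= 1 for a proper model).
#' @export
perplexity_from_nll <- function(mean_nll_per_token) {
  if (any(mean_nll_per_token < 0)) abort("negative NLL is not a valid mean NLL")
  exp(mean_nll_per_token)
}

#' Serialize a tokenizer to JSON
#' @param spec a `tok_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vocab <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a tokenizer serialized with [write_vocab()]
#' @param path JSON path.
#' @return a `tok_spec`.
#' @export
read_vocab <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- build_vocab(x$n)
  if (!identical(spec$tokens, x$tokens)) abort("vocabulary file is inconsistent")
  spec
}
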