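#' Save a model checkpoint
#'
#' Stores configuration, tokenizer (with a content hash), parameters and
#' provenance metadata in a single RDS file.
#'
#' @param model an `rna_lm` or `rna_gnn`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  payload <- list(class = class(model)[1], model = model,
                  vocab_hash = if (!is.null(model$spec)) {
                    rlang::hash(model$spec$tokens)
                  } else NA_character_)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path a file written by [write_checkpoint()].
#' @return the stored model; the tokenizer hash is re-verified.
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such checkpoint: %s", path))
  payload <- readRDS(path)
  model <- payload$model
  if (!is.null(model$spec) && !is.na(payload$vocab_hash) &&
      !identical(rlang::hash(model$spec$tokens), payload$vocab_hash)) {
    abort("checkpoint vocabulary hash mismatch")
  }
  model
}
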