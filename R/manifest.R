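#' Write a JSON run manifest
#'
#' Records the command, configuration snapshot, seeds, input/output file
#' digests, package version and timestamps for an artifact-producing run;
#' every CLI subcommand writes exactly one.
#'
#' @param command command name.
#' @param config a named list snapshot of the configuration used.
#' @param seeds named list or vector of RNG seeds.
#' @param inputs,outputs character vectors of file paths (digested when they
#'   exist).
#' @param path manifest destination; defaults to `<command>_manifest.json`.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(command, config = list(), seeds = list(),
                               inputs = character(), outputs = character(),
                               path = paste0(command, "_manifest.json")) {
  digest_file <- function(f) {
    if (file.exists(f)) rlang::hash(readBin(f, "raw", file.size(f))) else NA_character_
  }
  manifest <- list(
    command = command,
    toolkit_version = as.character(utils::packageVersion("rnaforge")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    config = config,
    inputs = lapply(setNames(inputs, inputs), digest_file),
    outputs = lapply(setNames(outputs, outputs), digest_file))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
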