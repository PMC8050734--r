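#' Read a YAML run configuration
#'
#' One declarative file naming inputs, thresholds and seeds for an analysis
#' run; values passed in `overrides` (e.g. parsed command-line flags) take
#' precedence over the file.
#'
#' @param path path to a YAML file (may be NULL for defaults only).
#' @param overrides named list overriding file values.
#' @param defaults named list of fallback values.
#' @return named list of settings.
#' @export
read_config <- function(path = NULL, overrides = list(), defaults = list(
                          q_threshold = 0.05, period = 24,
                          shift_threshold = 4, seed = 1
                        )) {
  cfg <- defaults
  if (!is.null(path)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  utils::modifyList(cfg, overrides)
}

#' Append a replayability log record for an analysis run
#'
#' Writes one JSON line with a timestamp, the seed, the thresholds in the
#' configuration, and MD5 hashes of the named input files, so that any run
#' can be replayed and checked against its inputs.
#'
#' @param log_path file to append to (created if missing).
#' @param config named list of settings (see [read_config()]).
#' @param inputs character vector of input file paths to hash.
#' @return the log record, invisibly.
#' @export
log_run <- function(log_path, config, inputs = character()) {
  rec <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = as.list(tools::md5sum(inputs))
  )
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  con <- file(log_path, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(rec)
}
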