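#' Write a trace to CSV with a JSON sidecar
#'
#' The trace goes to `<path>` as a two-column CSV (`time_ms`, `value`) at
#' full float round-trip precision; metadata (kind, dt, units, protocol,
#' amplitude, cell, condition) goes to `<path>.json`.
#'
#' @param trace a [new_trace()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace"))
  df <- data.frame(time_ms = format(trace_times(trace), digits = 17,
                                    trim = TRUE, scientific = FALSE),
                   value = format(trace$samples, digits = 17, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(kind = trace$kind, dt_ms = trace$dt,
               units = if (trace$kind == "voltage") "mV" else "pA",
               amplitude = trace$amplitude,
               cell_id = trace$meta$cell_id,
               condition = trace$meta$condition)
  if (!is.null(trace$protocol)) {
    p <- trace$protocol
    side$protocol <- list(mode = p$mode, pre_ms = p$pre_ms,
                          stim_ms = p$stim_ms, post_ms = p$post_ms,
                          amplitudes = p$amplitudes,
                          ramp_start = p$ramp_start, dt = p$dt)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV file path; `<path>.json` must exist.
#' @return a [new_trace()].
#' @export
read_trace <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  df <- tryCatch(read.csv(path, colClasses = "numeric"),
                 warning = function(w) stop("malformed CSV at ", path, ": ",
                                            conditionMessage(w)))
  if (!all(c("time_ms", "value") %in% names(df)))
    stop("CSV at ", path, " must have columns time_ms, value")
  if (anyNA(df$value))
    stop("truncated CSV at ", path, ": missing value at row ",
         which(is.na(df$value))[1])
  proto <- NULL
  if (!is.null(side$protocol)) {
    pr <- side$protocol
    proto <- stimulus_protocol(pr$mode, pr$pre_ms, pr$stim_ms, pr$post_ms,
                               pr$amplitudes,
                               ramp_start = pr$ramp_start, dt = pr$dt)
    expected <- round(protocol_total_ms(proto) / side$dt_ms) + 1
    if (abs(nrow(df) - expected) > 1)
      stop("sample count ", nrow(df), " at ", path,
           " inconsistent with sidecar field dt_ms/protocol (expected ",
           expected, ")")
  }
  tr <- new_trace(side$kind, df$value, side$dt_ms, proto,
                  amplitude = if (is.null(side$amplitude)) NA else side$amplitude)
  tr$meta$cell_id <- side$cell_id
  tr$meta$condition <- side$condition
  tr
}

#' Write a per-cell feature table as TSV
#'
#' One row per (cell, condition); columns are the [extract_features()]
#' fields.
#'
#' @param features data.frame of stacked feature rows.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Records command, configuration hash, seed, timestamps and input/output
#' paths of a pipeline run, for provenance: a run is reproducible from its
#' manifest (configuration hash plus seed).
#'
#' @param path output JSON path.
#' @param command the command or function being recorded.
#' @param config the configuration object (hashed into the manifest).
#' @param seed integer seed used.
#' @param inputs,outputs character vectors of paths.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config = NULL, seed = NA_integer_,
                           inputs = character(), outputs = character()) {
  manifest <- list(
    command = command,
    config_hash = config_hash(config),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("somafit")),
    inputs = inputs, outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# deterministic digest of a configuration object (polynomial rolling hash
# over its serialization, modulo a Mersenne prime)
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  bytes <- as.numeric(serialize(config, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
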