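# Interchange formats: the fixed CSV sensor dialect
# (timestamp,Tin,RHin,CO2,WS,Tout,RHout; ISO-8601 timestamps; empty
# field = missing), single-file model checkpoints, and run manifests.

#' Write / read a sensor table in the package CSV dialect
#'
#' @param table A sensor table.
#' @param path File path.
#' @return `read_series_csv()` returns an `rhp_series` tibble;
#'   `write_series_csv()` its path, invisibly.
#' @export
write_series_csv <- function(table, path) {
  stopifnot_series(table)
  out <- table[, c("timestamp", rhp_channels())]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("timestamp", rhp_channels())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("unrecognized header in ", path, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(raw), required)
  if (length(extra) > 0) {
    warn(paste0("ignoring extra column(s): ", paste(extra, collapse = ", ")))
  }
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(ts)) {
    abort(sprintf("unparseable timestamp at row %d", which(is.na(ts))[1]))
  }
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1
    abort(sprintf("timestamps are not strictly increasing: row %d (%s)",
                  bad, format(ts[bad])))
  }
  if (length(unique(d)) > 1) {
    bad <- which(d != d[1])[1] + 1
    abort(sprintf("irregular sampling step at row %d (%s)", bad, format(ts[bad])))
  }
  out <- tibble(timestamp = ts)
  for (ch in rhp_channels()) out[[ch]] <- as.numeric(raw[[ch]])
  out <- set_step_minutes(out, if (length(d)) d[1] / 60 else NA_real_)
  class(out) <- c("rhp_series", class(out))
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the weights and the embedded
#' model configuration (including ablation flags), so a reloaded model
#' reproduces forward outputs bit-identically.
#'
#' @param model An `rhp_model` or `rhp_baseline`.
#' @param path File path.
#' @param config Optional [rhp_config()] the loaded checkpoint must
#'   match; a mismatch raises an error naming the differing field.
#' @return `load_checkpoint()` returns the model; `save_checkpoint()`
#'   its path, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("rhp_model", "rhp_baseline")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, config = NULL) {
  model <- readRDS(path)
  if (!inherits(model, c("rhp_model", "rhp_baseline"))) {
    abort("file is not an rhpcast checkpoint")
  }
  if (!is.null(config)) {
    for (nm in setdiff(names(config), c("seed"))) {
      if (!identical(config[[nm]], model$config[[nm]])) {
        abort(sprintf("checkpoint config mismatch in field `%s`: %s vs %s",
                      nm, deparse(model$config[[nm]]), deparse(config[[nm]])))
      }
    }
  }
  model
}

#' Write a run manifest
#'
#' Records command, configuration snapshot, seeds, input digests and
#' output paths so a run can be re-executed exactly. Written atomically
#' (temp file + rename) at run end.
#'
#' @param dir Run directory.
#' @param command Command or function name.
#' @param config Configuration list snapshot.
#' @param seeds Named seed list/vector.
#' @param inputs Character vector of input file paths (digested).
#' @param outputs Character vector of output paths.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config = list(), seeds = list(),
                           inputs = character(), outputs = character()) {
  digest_file <- function(p) {
    if (!file.exists(p)) return(NA_character_)
    sprintf("size:%d;mtime-independent-sum:%.0f", file.size(p),
            sum(as.numeric(charToRaw(paste(readLines(p, warn = FALSE), collapse = "\n")))))
  }
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("rhpcast")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    config = config, seeds = seeds,
    inputs = lapply(setNames(inputs, inputs), digest_file),
    outputs = as.list(outputs))
  path <- file.path(dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(path)
}
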