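# Required header of a feature-table file: identifiers plus the 12
# properties with units fixed in the column names.
REQUIRED_TABLE_COLUMNS <- c("neuron_id", "population", EPHYS_FEATURES)

table_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t",
         stop("unrecognized table extension: ", ext,
              " (expected .csv or .tsv)"))
}

#' Read a feature table from delimited text
#'
#' TSV or CSV, auto-detected by extension. The required header is
#' `neuron_id`, `population`, and the 12 feature columns (units in the
#' names); optional columns (e.g. `firing_type`, `cluster`) and unknown
#' columns are preserved. Missing values are empty fields. Both Unix and
#' Windows line endings are accepted.
#'
#' @param path File path.
#' @return A feature table `data.frame`.
#' @export
read_feature_table <- function(path) {
  sep <- table_sep(path)
  tab <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(REQUIRED_TABLE_COLUMNS, names(tab))
  if (length(missing) > 0) {
    stop("missing column ", paste(missing, collapse = ", "))
  }
  for (f in EPHYS_FEATURES) {
    if (!is.numeric(tab[[f]])) {
      bad <- which(!is.na(tab[[f]]) &
                     is.na(suppressWarnings(as.numeric(tab[[f]]))))
      stop(sprintf("non-numeric value in column %s, row %d", f, bad[1]))
    }
  }
  if (anyDuplicated(tab$neuron_id)) stop("duplicated neuron_id values")
  tab
}

#' Write a feature table to delimited text
#'
#' @param table A feature table.
#' @param path Destination (.csv or .tsv); the write/read round trip is
#'   lossless for values and column order.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  sep <- table_sep(path)
  write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Write a recording as a trace bundle
#'
#' A trace bundle is a directory holding a JSON manifest (neuron id,
#' sampling rate, sweep list with clamp mode, stimulus description and
#' epoch markers, plus the ground-truth block for synthetic recordings)
#' and one three-column delimited text file per sweep (`time_ms`,
#' `command`, `response`) at full double precision.
#'
#' @param recording A `neuron_recording`.
#' @param dir Destination directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trace_bundle <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sweep_entries <- lapply(names(recording$sweeps), function(nm) {
    sw <- recording$sweeps[[nm]]
    file <- paste0(nm, ".tsv")
    df <- data.frame(time_ms = sprintf("%.10g", sw$time_ms),
                     command = sprintf("%.10g", sw$command),
                     response = sprintf("%.17g", sw$response))
    write.table(df, file.path(dir, file), sep = "\t", row.names = FALSE,
                quote = FALSE)
    list(name = nm, file = file, clamp_mode = sw$clamp_mode,
         stimulus = sw$stimulus, epoch_ms = sw$epoch_ms)
  })
  manifest <- list(
    neuron_id = recording$neuron_id,
    sampling_rate_hz = recording$sampling_rate_hz,
    holding_mv = recording$holding_mv,
    sweeps = sweep_entries,
    ground_truth = recording$ground_truth
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a trace bundle
#'
#' @param dir Bundle directory written by [write_trace_bundle()].
#' @return A `neuron_recording`.
#' @export
read_trace_bundle <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  files <- vapply(manifest$sweeps, function(s) s$file, character(1))
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing) > 0) {
    stop("manifest references absent sweep file(s): ",
         paste(missing, collapse = ", "))
  }
  sweeps <- list()
  for (s in manifest$sweeps) {
    df <- read.delim(file.path(dir, s$file))
    sweeps[[s$name]] <- new_sweep(
      s$clamp_mode, df$time_ms, df$command, df$response,
      unlist(s$epoch_ms), lapply(s$stimulus, function(x) x)
    )
  }
  gt <- manifest$ground_truth
  if (!is.null(gt)) {
    gt$features <- unlist(gt$features)
    if (!is.null(gt$fi_counts)) {
      gt$fi_counts <- do.call(rbind.data.frame, gt$fi_counts)
    }
    if (!is.null(gt$supra_spike_times_ms)) {
      gt$supra_spike_times_ms <- unlist(gt$supra_spike_times_ms)
    }
  }
  structure(
    list(neuron_id = manifest$neuron_id,
         sampling_rate_hz = manifest$sampling_rate_hz,
         holding_mv = manifest$holding_mv,
         sweeps = sweeps, ground_truth = gt),
    class = "neuron_recording"
  )
}
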