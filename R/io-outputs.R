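# Tidy writers for per-trial and per-participant outputs. Numeric columns are
# serialized with 17 significant digits so the reader reproduces them exactly;
# missing values are empty fields, never sentinel numbers.

.formatFull <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- NA_character_
      df[[nm]] <- v
    }
  }
  df
}

#' Write / read a burst table
#'
#' One row per (non-rejected) trial with detection flag, go- and stop-locked
#' latencies, amplitude, motor time, rise time, AUC and the EMG class label.
#' CSV with empty fields for missing values; numeric values round-trip at
#' full double precision.
#'
#' @param bursts burst table from [extractBursts()].
#' @param path output path.
#' @return `path` invisibly (writer); the burst table (reader).
#' @export
writeBurstTable <- function(bursts, path) {
  utils::write.table(.formatFull(bursts), path, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeBurstTable
#' @export
readBurstTable <- function(path) {
  df <- utils::read.csv(path, na.strings = c("NA", ""))
  for (nm in intersect(c("detected", "onset_warn", "pre_stop_peak"),
                       names(df)))
    df[[nm]] <- as.logical(df[[nm]])
  df
}

#' Write / read a participant summary
#'
#' One row per participant holding the behavioural block (accuracies, RTs,
#' SSD, SSRT) and the EMG block (detection counts and percentages, latencies,
#' amplitudes, motor/rise times, AUC, prEMG latency estimators, latency sd).
#' Absent estimates (e.g. no prEMG trials) are written as empty fields.
#'
#' @param summary data.frame, one row per participant.
#' @param path output path.
#' @return `path` invisibly (writer); the summary table (reader).
#' @export
writeSummary <- function(summary, path) {
  utils::write.table(.formatFull(summary), path, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeSummary
#' @export
readSummary <- function(path) {
  utils::read.csv(path, na.strings = c("NA", ""))
}

#' Write a machine-readable JSON report
#'
#' @param report named list (parameters, seeds, rejection counts, summary
#'   metrics).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
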