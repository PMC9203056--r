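#' Read a continuous EMG recording
#'
#' Reads a continuous bipolar EMG recording either from a BrainVision triplet
#' (`.vhdr`/`.eeg`/`.vmrk`, as written by BrainAmp amplifiers) or from a
#' delimited text file (one column per channel) accompanied by a small YAML
#' sidecar declaring the sampling rate, amplitude unit and channel-to-hand
#' map. Amplitudes are returned in microvolts regardless of the stored unit.
#'
#' Hand assignment is never inferred from channel names: it comes from the
#' sidecar (delimited) or from the `hands` argument, which overrides any
#' sidecar value.
#'
#' @param path path to the `.vhdr` header (BrainVision) or to the data file
#'   (delimited).
#' @param format `"brainvision"` or `"delimited"`. Defaults from the file
#'   extension.
#' @param hands optional named character vector mapping channel labels to
#'   `"left"`/`"right"`.
#' @return a validated [ContinuousRecording-class].
#' @export
readContinuousRecording <- function(path,
                                    format = c("auto", "brainvision",
                                               "delimited"),
                                    hands = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vhdr$", path, ignore.case = TRUE))
      "brainvision" else "delimited"
  rec <- switch(format,
    brainvision = .readBrainVision(path),
    delimited   = .readDelimited(path))
  if (!is.null(hands)) rec@hands <- hands
  validObject(rec)
  rec
}

# ---- BrainVision ------------------------------------------------------------

.parseIni <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- character(0)
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[section]][trimws(key)] <- trimws(val)
    }
  }
  out
}

.unitScale <- function(unit) {
  u <- gsub("µ|μ", "u", trimws(unit))
  scale <- c(uV = 1, mV = 1e3, V = 1e6)[u]
  if (is.na(scale)) stop(sprintf("unknown amplitude unit '%s'", unit),
                         call. = FALSE)
  unname(scale)
}

.readBrainVision <- function(vhdr) {
  if (!file.exists(vhdr)) stop(sprintf("header file absent: %s", vhdr),
                               call. = FALSE)
  ini <- .parseIni(readLines(vhdr, warn = FALSE))
  ci  <- ini[["Common Infos"]]
  dir <- dirname(vhdr)
  dataFile   <- file.path(dir, ci[["DataFile"]])
  markerFile <- if (!is.null(ci) && "MarkerFile" %in% names(ci))
    file.path(dir, ci[["MarkerFile"]]) else NA_character_
  nch  <- as.integer(ci[["NumberOfChannels"]])
  if (is.na(nch) || nch < 1L) stop("zero channels declared", call. = FALSE)
  rate <- 1e6 / as.numeric(ci[["SamplingInterval"]])  # interval in us
  orientation <- toupper(ci[["DataOrientation"]])
  fmt <- toupper(ini[["Binary Infos"]][["BinaryFormat"]])

  chInfo <- ini[["Channel Infos"]]
  labels <- character(nch); res <- rep(1, nch); units <- rep("uV", nch)
  for (k in seq_len(nch)) {
    parts <- strsplit(chInfo[[sprintf("Ch%d", k)]], ",", fixed = TRUE)[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[k] <- as.numeric(parts[3])
    if (length(parts) >= 4 && nzchar(parts[4])) units[k] <- parts[4]
  }

  if (!file.exists(dataFile))
    stop(sprintf("data file absent: %s", dataFile), call. = FALSE)
  sz <- file.size(dataFile)
  con <- file(dataFile, "rb"); on.exit(close(con))
  raw <- switch(fmt,
    IEEE_FLOAT_32 = readBin(con, "numeric", n = sz / 4, size = 4,
                            endian = "little"),
    INT_16 = readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                     endian = "little"),
    stop(sprintf("unsupported BinaryFormat '%s'", fmt), call. = FALSE))
  nsamp <- length(raw) %/% nch
  samples <- if (identical(orientation, "VECTORIZED"))
    matrix(raw[seq_len(nch * nsamp)], nrow = nch, byrow = TRUE)
  else
    matrix(raw[seq_len(nch * nsamp)], nrow = nch)
  samples <- samples * res * vapply(units, .unitScale, numeric(1))
  rownames(samples) <- labels

  if (is.na(markerFile) || !file.exists(markerFile))
    stop("marker file absent", call. = FALSE)
  events <- .readVmrk(markerFile, rate)

  new("ContinuousRecording", samples = samples, rate = rate,
      channels = labels, hands = character(0), events = events,
      meta = list(source = vhdr, format = "brainvision",
                  binary_format = fmt))
}

.readVmrk <- function(vmrk, rate) {
  ini <- .parseIni(readLines(vmrk, warn = FALSE))
  mk  <- ini[["Marker Infos"]]
  if (is.null(mk) || !length(mk))
    return(data.frame(time = numeric(0), code = character(0)))
  time <- numeric(0); code <- character(0)
  for (v in mk) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    if (length(parts) < 3 || identical(parts[1], "New Segment")) next
    time <- c(time, (as.numeric(parts[3]) - 1) / rate)
    code <- c(code, parts[2])
  }
  data.frame(time = time, code = code)
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `basename.vhdr`, `basename.vmrk` and `basename.eeg`
#' (IEEE_FLOAT_32, multiplexed). Used by the simulator to produce fixtures
#' that exercise the same reader as laboratory data.
#'
#' @param recording a [ContinuousRecording-class].
#' @param basename output path without extension.
#' @return the `.vhdr` path, invisibly.
#' @export
writeBrainVision <- function(recording, basename) {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg  <- paste0(basename, ".eeg")
  stem <- basename(basename)
  nch  <- nrow(recording@samples)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nch),
    sprintf("SamplingInterval=%g", 1e6 / recording@rate),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(nch), recording@channels))
  writeLines(hdr, vhdr)

  ev <- recording@events
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", stem),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (nrow(ev))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(ev)) + 1L, ev$code,
                        as.integer(round(ev$time * recording@rate)) + 1L))
  writeLines(mk, vmrk)

  con <- file(eeg, "wb")
  writeBin(as.numeric(recording@samples), con, size = 4, endian = "little")
  close(con)
  invisible(vhdr)
}

# ---- delimited fallback -----------------------------------------------------

.sidecarPath <- function(path) paste0(sub("\\.[^.]+$", "", path), ".yml")

.readDelimited <- function(path) {
  if (!file.exists(path)) stop(sprintf("data file absent: %s", path),
                               call. = FALSE)
  side <- .sidecarPath(path)
  if (!file.exists(side))
    stop(sprintf("sidecar absent: %s", side), call. = FALSE)
  meta <- yaml::read_yaml(side)
  if (is.null(meta$rate)) stop("sidecar must declare 'rate'", call. = FALSE)
  unit <- if (is.null(meta$unit)) "uV" else meta$unit
  dat  <- utils::read.delim(path, check.names = FALSE)
  if (!ncol(dat)) stop("zero channels", call. = FALSE)
  samples <- t(as.matrix(dat)) * .unitScale(unit)
  labels  <- colnames(dat)
  rownames(samples) <- labels
  hands <- if (!is.null(meta$hands)) unlist(meta$hands) else character(0)
  events <- if (!is.null(meta$events))
    do.call(rbind, lapply(meta$events, function(e)
      data.frame(time = e$time, code = as.character(e$code))))
  else data.frame(time = numeric(0), code = character(0))
  new("ContinuousRecording", samples = samples, rate = as.numeric(meta$rate),
      channels = labels, hands = hands, events = events,
      meta = list(source = path, format = "delimited", unit = unit))
}

#' Write a recording as delimited text plus a YAML sidecar
#'
#' One column per channel, tab-separated, with a sidecar declaring rate,
#' unit, hand map and events. Round-trips through
#' [readContinuousRecording()].
#'
#' @param recording a [ContinuousRecording-class].
#' @param path output data-file path (sidecar gets the same stem + `.yml`).
#' @return `path`, invisibly.
#' @export
writeDelimitedRecording <- function(recording, path) {
  dat <- as.data.frame(t(recording@samples))
  names(dat) <- recording@channels
  utils::write.table(dat, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  ev <- recording@events
  side <- list(rate = recording@rate, unit = "uV",
               hands = as.list(recording@hands))
  if (nrow(ev))
    side$events <- lapply(seq_len(nrow(ev)), function(i)
      list(time = ev$time[i], code = ev$code[i]))
  yaml::write_yaml(side, .sidecarPath(path))
  invisible(path)
}
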