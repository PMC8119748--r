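#' Continuous EEG container
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param rate Sampling rate in Hz.
#' @param channels Channel labels (unique, length `nrow(data)`).
#' @param reference Label of the recording reference.
#' @return Object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, rate, channels = rownames(data),
                           reference = "Iz") {
  stopifnot(is.matrix(data), rate > 0, length(channels) == nrow(data),
            !anyDuplicated(channels), all(is.finite(data)))
  rownames(data) <- channels
  structure(list(data = data, rate = rate, channels = channels,
                 reference = reference),
            class = "eeg_continuous")
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("<eeg_continuous> %d channels x %d samples @ %g Hz (ref %s)\n",
              nrow(x$data), ncol(x$data), x$rate, x$reference))
  invisible(x)
}

#' Write / read a BrainVision file triplet
#'
#' Minimal BrainVision Core Data Format support: a `.vhdr` text header, a
#' `.vmrk` marker file carrying the stimulus events, and a `.eeg` binary
#' payload (IEEE float32, multiplexed channel order). Units are microvolts.
#'
#' @param eeg An `eeg_continuous`.
#' @param basepath Path without extension; the three files are written next
#'   to each other.
#' @param events Optional event table with at least `onset_sample` (1-based)
#'   and `bin`; written as `Stimulus` markers.
#' @return `write_brainvision` invisibly returns `basepath`;
#'   `read_brainvision` an `eeg_continuous` with an `events` attribute
#'   (onset/description from the markers).
#' @export
write_brainvision <- function(eeg, basepath, events = NULL) {
  stem <- basename(basepath)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(eeg$data)),
    paste0("SamplingInterval=", format(1e6 / eeg$rate, scientific = FALSE)),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,%s,1,µV", seq_len(nrow(eeg$data)), eeg$channels,
            eeg$reference))
  writeLines(hdr, paste0(basepath, ".vhdr"), useBytes = TRUE)

  mk <- c("BrainVision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]", paste0("DataFile=", stem, ".eeg"),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(events) && nrow(events))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(events)) + 1L,
                        as.character(events$bin), events$onset_sample))
  writeLines(mk, paste0(basepath, ".vmrk"), useBytes = TRUE)

  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(eeg$data), con, size = 4, endian = "little")
  invisible(basepath)
}

#' @rdname write_brainvision
#' @param path Path to the `.vhdr` header (or the basepath).
#' @export
read_brainvision <- function(path) {
  if (!grepl("\\.vhdr$", path)) path <- paste0(path, ".vhdr")
  lines <- readLines(path, encoding = "UTF-8")
  get <- function(key) sub(paste0("^", key, "="), "",
                           grep(paste0("^", key, "="), lines, value = TRUE)[1])
  n_ch <- as.integer(get("NumberOfChannels"))
  rate <- 1e6 / as.numeric(get("SamplingInterval"))
  if (toupper(get("BinaryFormat")) != "IEEE_FLOAT_32")
    stop("only IEEE_FLOAT_32 BrainVision payloads are supported")
  if (toupper(get("DataOrientation")) != "MULTIPLEXED")
    stop("only MULTIPLEXED BrainVision payloads are supported")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  channels <- vapply(parts, `[`, "", 1)
  reference <- parts[[1]][2]
  if (is.na(reference) || !nzchar(reference)) reference <- "unknown"

  eegfile <- file.path(dirname(path), get("DataFile"))
  sz <- file.info(eegfile)$size
  con <- file(eegfile, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  data <- matrix(vals, nrow = n_ch)

  out <- eeg_continuous(data, rate, channels, reference)
  vmrk <- file.path(dirname(path), sub("\\.eeg$", ".vmrk", get("DataFile")))
  if (file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk), value = TRUE)
    if (length(ml)) {
      p <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
      attr(out, "events") <- data.frame(
        onset_sample = as.integer(vapply(p, `[`, "", 3)),
        bin = vapply(p, `[`, "", 2), stringsAsFactors = FALSE)
    }
  }
  out
}

#' Write / read the events table
#'
#' Tab-separated, one row per trial: `onset_sample`, `bin`, `correct`,
#' `rt_s`, `question`, `question_correct`.
#'
#' @param events Event data.frame (as in a `synthetic_session`).
#' @param path File path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  ev$correct <- as.logical(ev$correct)
  ev$question <- as.logical(ev$question)
  if ("question_correct" %in% names(ev))
    ev$question_correct <- as.logical(ev$question_correct)
  ev
}
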