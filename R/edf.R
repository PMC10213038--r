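#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, one signal per EEG channel, physical unit microvolts. The
#' physical range is set symmetrically from the data's peak amplitude, so
#' quantization error is at most `peak / 32767`.
#'
#' @param rec a `session_recording` with an integer number of seconds.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "session_recording"))
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  fs <- as.integer(round(rec$fs))
  if (n %% fs != 0) stop("EDF writer requires a whole number of seconds")
  n_rec <- n %/% fs
  pmax_ <- max(1, ceiling(max(abs(rec$data))))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(paste0("X X X ", rec$subject_id), 80),
    pad(paste0("Startdate 01-JAN-2000 session ", rec$session_index), 80),
    "01.01.00", "00.00.00",
    pad(256 * (1 + ns), 8), pad("", 44),
    pad(n_rec, 8), pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  sig <- paste0(
    paste(pad(paste("EEG", rec$channel_names), 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(rep(pad(-pmax_, 8), ns), collapse = ""),
    paste(rep(pad(pmax_, 8), ns), collapse = ""),
    paste(rep(pad(-32767L, 8), ns), collapse = ""),
    paste(rep(pad(32767L, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(sig, con, nchars = nchar(sig), eos = NULL)
  dig <- matrix(as.integer(round(rec$data / pmax_ * 32767)), nrow = ns)
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses the EDF header and 16-bit data records back into a
#' `session_recording` (subject id and session index are recovered from the
#' header fields this package writes; generic EDF files yield empty ids).
#'
#' @param path EDF file path.
#' @return A `session_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nch) trimws(readChar(con, nch, useBytes = TRUE))
  rd(8)
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                       # transducer
  for (i in seq_len(ns)) rd(8)                        # dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                       # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates are not supported")
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1])               # samples x signals
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
  }
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- data * scale + (pmin_ - dmin_ * scale)
  subject <- sub("^X X X ", "", patient)
  sess <- suppressWarnings(as.integer(sub(".*session ", "", recording)))
  session_recording(subject, ifelse(is.na(sess), 1L, sess), data,
                    sub("^EEG ", "", labels), fs = spr[1] / rec_dur)
}
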