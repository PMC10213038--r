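#' Design the analysis band-pass filter
#'
#' Linear-phase FIR band-pass (Hamming-windowed) with cut-offs at 2 and
#' 45 Hz. The filter order equals `taps`, giving `taps + 1` coefficients and
#' an exactly integer group delay of `taps / 2` samples, which
#' [bandpass_filter()] compensates in a single pass.
#'
#' @param fs sampling rate in Hz.
#' @param lo,hi cut-off frequencies in Hz.
#' @param taps filter order (default 1000).
#' @return Numeric vector of `taps + 1` FIR coefficients.
#' @export
design_bandpass <- function(fs = 500, lo = 2, hi = 45, taps = 1000) {
  stopifnot(fs > 2 * hi, lo > 0, hi > lo)
  if (taps %% 2 != 0) stop("taps must be even for integer delay compensation")
  signal::fir1(taps, c(lo, hi) / (fs / 2), type = "pass")
}

#' Band-pass filter a recording
#'
#' Applies the linear-phase FIR of [design_bandpass()] per channel by FFT
#' convolution and removes the constant group delay, so the output is
#' zero-phase aligned with the input and has the same shape.
#'
#' @param rec a `session_recording`.
#' @param lo,hi,taps filter design parameters.
#' @return The filtered `session_recording`.
#' @export
bandpass_filter <- function(rec, lo = 2, hi = 45, taps = 1000) {
  stopifnot(inherits(rec, "session_recording"))
  n <- ncol(rec$data)
  if (n <= taps)
    stop("signal length (", n, ") must exceed the filter order (", taps, ")")
  b <- design_bandpass(rec$fs, lo, hi, taps)
  delay <- taps / 2
  out <- t(apply(rec$data, 1, function(x) {
    y <- signal::fftfilt(b, c(x, numeric(delay)))
    y[(delay + 1):(delay + n)]
  }))
  if (!all(is.finite(out))) stop("filter produced non-finite output")
  rec$data <- out
  rec
}

#' Remove per-channel mean and linear trend
#'
#' Subtracts the least-squares best-fit line from every channel, leaving each
#' channel with zero mean and zero linear trend.
#'
#' @param rec a `session_recording`.
#' @return The detrended `session_recording`.
#' @export
demean_detrend <- function(rec) {
  stopifnot(inherits(rec, "session_recording"))
  n <- ncol(rec$data)
  if (n < 2) stop("need at least 2 samples to detrend")
  t0 <- seq_len(n) - (n + 1) / 2               # centered time, orthogonal to 1
  stt <- sum(t0^2)
  mu <- rowMeans(rec$data)
  slope <- as.vector(rec$data %*% t0) / stt
  rec$data <- rec$data - mu - outer(slope, t0)
  rec
}

#' Drop contaminated channels and re-reference to Cz
#'
#' Removes the four frontal channels, subtracts the Cz trace from every
#' remaining channel, then removes Cz itself, leaving 27 channels for the
#' standard montage.
#'
#' @param rec a `session_recording`.
#' @param drop channels to remove before re-referencing.
#' @param ref reference channel (subtracted, then excluded).
#' @return A `session_recording` with `length(channels) - length(drop) - 1`
#'   channels.
#' @export
drop_and_rereference <- function(rec, drop = excluded_frontal_channels(),
                                 ref = "Cz") {
  stopifnot(inherits(rec, "session_recording"))
  missing <- setdiff(c(drop, ref), rec$channel_names)
  if (length(missing))
    stop("channel(s) not present in recording: ", paste(missing, collapse = ", "))
  keep <- !(rec$channel_names %in% drop)
  data <- rec$data[keep, , drop = FALSE]
  chans <- rec$channel_names[keep]
  refrow <- data[match(ref, chans), ]
  data <- sweep(data, 2, refrow, "-")
  keep2 <- chans != ref
  rec$data <- data[keep2, , drop = FALSE]
  rec$channel_names <- chans[keep2]
  rec
}

#' Epoch start indices
#'
#' Sliding windows of `window` seconds advancing by
#' `window * (1 - overlap)` seconds. A 120-s recording at 4 s / 50% overlap
#' yields 59 epochs.
#'
#' @param n_samples recording length in samples.
#' @param fs sampling rate in Hz.
#' @param window epoch length in seconds (default 4).
#' @param overlap fractional overlap between consecutive epochs (default 0.5).
#' @return Integer vector of 1-based start samples.
#' @export
epoch_starts <- function(n_samples, fs, window = 4, overlap = 0.5) {
  stopifnot(window > 0, overlap >= 0, overlap < 1)
  wlen <- as.integer(round(window * fs))
  if (n_samples < wlen) stop("recording shorter than one epoch")
  step <- as.integer(round(wlen * (1 - overlap)))
  seq.int(1L, n_samples - wlen + 1L, by = step)
}

#' Flag artifact-free epochs
#'
#' An epoch is rejected when any retained channel contains a sample whose
#' absolute amplitude exceeds `threshold` (microvolts). Rejection is applied
#' at epoch granularity because features are epoch-based.
#'
#' @param rec a `session_recording` (post-filter, pre-reference by default).
#' @param threshold amplitude threshold in microvolts (default 100).
#' @param window,overlap epoching parameters.
#' @return Logical vector over epochs: TRUE = retained.
#' @export
artifact_mask <- function(rec, threshold = 100, window = 4, overlap = 0.5) {
  stopifnot(inherits(rec, "session_recording"))
  if (threshold <= 0) stop("threshold must be positive")
  starts <- epoch_starts(ncol(rec$data), rec$fs, window, overlap)
  wlen <- as.integer(round(window * rec$fs))
  absd <- abs(rec$data)                         # per-sample max over channels
  peak <- do.call(pmax, lapply(seq_len(nrow(absd)), function(i) absd[i, ]))
  vapply(starts, function(s) all(peak[s:(s + wlen - 1L)] <= threshold),
         logical(1))
}

#' Per-channel relative band power of one epoch
#'
#' Power spectral density is estimated with a Hann-windowed periodogram on
#' the full epoch (a one-segment Welch estimate); band power is the sum of
#' the PSD over frequency bins in the half-open interval `[low, high)`, and
#' relative power divides by the total over the 2-45 Hz analysis range, so
#' each channel's five fractions sum to exactly 1.
#'
#' @param epoch numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param bands band definition table (default [eeg_bands()]).
#' @return Matrix channels x bands of fractions, or NULL (flagged
#'   undefined) when a channel has zero total power.
#' @export
relative_band_power <- function(epoch, fs, bands = eeg_bands()) {
  stopifnot(is.matrix(epoch))
  n <- ncol(epoch)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))   # Hann
  xw <- sweep(epoch, 2, w, "*")
  spec <- Mod(t(stats::mvfft(t(xw))))^2                     # channels x bins
  freqs <- (seq_len(n) - 1) * fs / n
  power <- do.call(cbind, lapply(seq_len(nrow(bands)), function(b) {
    idx <- which(freqs >= bands$low_hz[b] & freqs < bands$high_hz[b])
    rowSums(spec[, idx, drop = FALSE])
  }))
  total <- rowSums(power)
  if (any(total <= 0)) return(NULL)
  out <- power / total
  dimnames(out) <- list(rownames(epoch), bands$band)
  out
}

#' Median aggregation of epoch features
#'
#' Elementwise median over retained epochs, followed by a per-channel
#' renormalization (the elementwise median does not exactly preserve the
#' sum-to-one property of relative powers).
#'
#' @param epoch_features list of channels x bands matrices.
#' @return A channels x bands matrix whose rows sum to 1.
#' @export
aggregate_median <- function(epoch_features) {
  epoch_features <- Filter(Negate(is.null), epoch_features)
  if (!length(epoch_features)) stop("no retained epochs to aggregate")
  arr <- simplify2array(epoch_features)
  med <- apply(arr, c(1, 2), stats::median)
  med / rowSums(med)
}

#' Extract the 135-dimensional feature vector of one recording
#'
#' Full preprocessing chain: FIR band-pass (2-45 Hz), demean/detrend,
#' frontal-channel exclusion, amplitude-threshold epoch rejection (applied
#' after filtering, before re-referencing, unless `reject_after_reref`),
#' Cz re-referencing, 4-s / 50%-overlap epoching, per-epoch relative band
#' power and elementwise median over retained epochs.
#'
#' @param rec a `session_recording` (32 channels for the standard montage).
#' @param threshold artifact amplitude threshold in microvolts.
#' @param window,overlap epoching parameters (seconds / fraction).
#' @param lo,hi,taps filter parameters.
#' @param reject_after_reref if TRUE, the amplitude threshold is applied to
#'   the re-referenced data instead.
#' @param bands band definition table.
#' @return List with `features` (named numeric vector, 135 values for the
#'   standard montage), `matrix` (channels x bands), `n_epochs`,
#'   `n_rejected`, `subject_id`, `session_index`.
#' @export
extract_features <- function(rec, threshold = 100, window = 4, overlap = 0.5,
                             lo = 2, hi = 45, taps = 1000,
                             reject_after_reref = FALSE, bands = eeg_bands()) {
  rec <- bandpass_filter(rec, lo, hi, taps)
  rec <- demean_detrend(rec)
  # frontal channels never participate in rejection or features
  keepmask <- !(rec$channel_names %in% excluded_frontal_channels())
  rec$data <- rec$data[keepmask, , drop = FALSE]
  rec$channel_names <- rec$channel_names[keepmask]
  if (!reject_after_reref)
    mask <- artifact_mask(rec, threshold, window, overlap)
  rec <- drop_and_rereference(rec, drop = character(0), ref = "Cz")
  if (reject_after_reref)
    mask <- artifact_mask(rec, threshold, window, overlap)
  if (!any(mask)) stop("all epochs rejected: no usable data")
  starts <- epoch_starts(ncol(rec$data), rec$fs, window, overlap)
  wlen <- as.integer(round(window * rec$fs))
  eps <- lapply(starts[mask], function(s)
    relative_band_power(rec$data[, s:(s + wlen - 1L), drop = FALSE],
                        rec$fs, bands))
  feat <- aggregate_median(eps)
  rownames(feat) <- rec$channel_names
  v <- as.vector(t(feat))
  names(v) <- feature_names(rec$channel_names)
  list(features = v, matrix = feat,
       n_epochs = length(starts), n_rejected = sum(!mask),
       subject_id = rec$subject_id, session_index = rec$session_index)
}

#' Feature table from a set of recordings
#'
#' @param recordings list of `session_recording`.
#' @param ... passed to [extract_features()].
#' @return data.frame: `subject_id`, `session_index`, then one column per
#'   feature (135 for the standard montage).
#' @export
features_table <- function(recordings, ...) {
  rows <- lapply(recordings, function(r) {
    f <- extract_features(r, ...)
    data.frame(subject_id = f$subject_id, session_index = f$session_index,
               t(f$features), check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
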