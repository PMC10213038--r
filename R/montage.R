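#' Standard 32-channel 10-20 montage
#'
#' Channel labels of the 32-electrode 10-20 recording montage, in the fixed
#' order used throughout the package. The flattened feature vector follows
#' this order (minus the excluded channels).
#'
#' @return Character vector of 32 channel labels.
#' @export
eeg_montage <- function() {
  c("P8", "T8", "AF7", "AF8", "F8", "F4", "C4", "P4", "FC5", "AF4",
    "Fp2", "Fp1", "AF3", "Fz", "C6", "Cz", "C5", "PO3", "O1", "Oz",
    "O2", "PO4", "Pz", "Fpz", "FC6", "P3", "C3", "F3", "F7", "FCz",
    "T7", "P7")
}

#' Frontal channels excluded from analysis
#' @return Character vector of the four frontal labels dropped before
#'   feature extraction (eye-movement contamination).
#' @export
excluded_frontal_channels <- function() c("AF4", "Fp2", "Fp1", "AF3")

#' Canonical EEG frequency bands
#'
#' Band edges are half-open intervals `[low, high)` so that shared edges
#' (4, 8, 13, 30 Hz) are never double-counted; together the five bands tile
#' the 2-45 Hz analysis range.
#'
#' @return A data.frame with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    band    = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(2, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Channels retained in the feature space
#'
#' The montage minus the four frontal channels and the Cz reference:
#' 27 channels, hence 27 x 5 = 135 relative-band-power features.
#'
#' @param ref reference channel removed after re-referencing (default "Cz")
#' @return Character vector of 27 labels in montage order.
#' @export
retained_channels <- function(ref = "Cz") {
  setdiff(eeg_montage(), c(excluded_frontal_channels(), ref))
}

#' Names of the flattened feature vector
#'
#' @param channels channel labels (default the 27 retained channels)
#' @return Character vector `"<channel>_<band>"`, channels outer, bands
#'   delta to gamma inner; length 135 for the default montage.
#' @export
feature_names <- function(channels = retained_channels()) {
  bands <- eeg_bands()$band
  as.vector(t(outer(channels, bands, paste, sep = "_")))
}

#' Construct a single-session EEG recording
#'
#' @param subject_id subject identifier
#' @param session_index session number (1-4 in the standard design)
#' @param data numeric matrix, channels x samples, in microvolts
#' @param channel_names channel labels, one per row of `data`
#' @param fs sampling rate in Hz
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(subject_id, session_index, data, channel_names,
                              fs = 500) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names), fs > 0)
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  structure(
    list(subject_id = as.character(subject_id),
         session_index = as.integer(session_index),
         channel_names = as.character(channel_names),
         fs = fs,
         data = data),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> subject %s session %d: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session_index, nrow(x$data), ncol(x$data),
              x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

# Deterministic sub-seed derivation: hash the global seed together with a
# stage / entity tag so every stage and every subject-session is independently
# reproducible. Kept within the 32-bit signed integer range.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(parts)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}
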