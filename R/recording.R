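#' Construct a multichannel EEG recording
#'
#' @param signal numeric matrix, channels x samples, microvolts.
#' @param sfreq sampling rate in Hz.
#' @param channels channel labels (rownames of `signal` if missing).
#' @param montage `"referential"`, `"common_average"` or `"bipolar"`.
#' @return object of class `eeg_recording`.
#' @export
new_recording <- function(signal, sfreq, channels = rownames(signal),
                          montage = "referential") {
  if (!is.matrix(signal)) stop("signal must be a channels x samples matrix")
  if (is.null(channels)) stop("channel names required")
  if (length(channels) != nrow(signal)) {
    stop("channel count does not match signal rows")
  }
  if (!is.numeric(sfreq) || sfreq <= 0) stop("sampling rate must be > 0")
  montage <- match.arg(montage, c("referential", "common_average", "bipolar"))
  rownames(signal) <- channels
  structure(list(signal = signal, sfreq = as.numeric(sfreq),
                 channels = as.character(channels), montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %.1f s @ %g Hz (%s montage)\n",
              nrow(x$signal), ncol(x$signal) / x$sfreq, x$sfreq, x$montage))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$signal) / rec$sfreq

#' Validate a recording against the standard 19-channel 10-20 pipeline
#'
#' @param rec an `eeg_recording`.
#' @return the recording, invisibly; errors name any missing 10-20 label.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$montage != "bipolar") {
    missing <- setdiff(CHANNELS_1020, rec$channels)
    if (length(missing)) {
      stop("recording is missing 10-20 channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(rec)
}
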