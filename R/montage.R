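#' Re-reference a recording to another montage
#'
#' Transformations start from the referential montage. The common-average
#' montage subtracts the instantaneous mean across all channels from every
#' channel; the bipolar montage is the fixed longitudinal ("double banana")
#' chain, each derivation being anode minus cathode.
#'
#' @param rec an `eeg_recording` in the referential montage.
#' @param target `"common_average"`, `"bipolar"` or `"referential"`.
#' @return a new `eeg_recording`.
#' @export
to_montage <- function(rec, target = c("common_average", "bipolar",
                                       "referential")) {
  target <- match.arg(target)
  stopifnot(inherits(rec, "eeg_recording"))
  if (target == rec$montage) return(rec)
  if (rec$montage != "referential") {
    stop("montage transformations are only defined from the referential montage",
         call. = FALSE)
  }
  if (target == "common_average") {
    avg <- colMeans(rec$signal)
    sig <- sweep(rec$signal, 2, avg)
    return(new_recording(sig, rec$sfreq, rec$channels,
                         montage = "common_average"))
  }
  # bipolar
  miss <- setdiff(unique(as.vector(BIPOLAR_CHAIN)), rec$channels)
  if (length(miss)) {
    stop("bipolar montage needs channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sig <- rec$signal[BIPOLAR_CHAIN[, 1], , drop = FALSE] -
    rec$signal[BIPOLAR_CHAIN[, 2], , drop = FALSE]
  labels <- paste0(BIPOLAR_CHAIN[, 1], "-", BIPOLAR_CHAIN[, 2])
  new_recording(sig, rec$sfreq, labels, montage = "bipolar")
}
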