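HYPNO_STAGES <- c("W", "N1", "N2", "N3", "NREM")
SLEEP_STAGES <- c("N1", "N2", "N3", "NREM")

#' Construct a hypnogram
#'
#' A sequence of sleep-stage labels in fixed-length epochs (30 s by
#' convention). Stages are `W`, `N1`, `N2`, `N3`, or the collapsed `NREM`
#' label used when discrimination between NREM stages is impossible;
#' `NREM` is mutually exclusive with `N1`/`N2`/`N3` within one recording.
#'
#' @param stages character vector of stage labels, one per epoch.
#' @param epoch_length epoch length in seconds (default 30).
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length = 30) {
  stages <- as.character(stages)
  bad <- which(!stages %in% HYPNO_STAGES)
  if (length(bad)) {
    stop("hypnogram: unknown stage token '", stages[bad[1]], "' at epoch ",
         bad[1] - 1, call. = FALSE)
  }
  if ("NREM" %in% stages && any(c("N1", "N2", "N3") %in% stages)) {
    stop("hypnogram: collapsed NREM label mixed with N1/N2/N3", call. = FALSE)
  }
  if (length(stages) == 0) stop("hypnogram: empty stage sequence", call. = FALSE)
  structure(list(stages = stages, epoch_length = as.numeric(epoch_length)),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(factor(x$stages, levels = HYPNO_STAGES))
  tb <- tb[tb > 0]
  cat("<hypnogram> ", length(x$stages), " x ", x$epoch_length, "-s epochs (",
      paste(sprintf("%s: %.1f min", names(tb),
                    as.integer(tb) * x$epoch_length / 60), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

hypnogram_duration <- function(hyp) length(hyp$stages) * hyp$epoch_length

# seconds spent in each stage, optionally clipped to a recording duration
stage_seconds <- function(hyp, clip_s = NULL) {
  ep <- hyp$epoch_length
  starts <- (seq_along(hyp$stages) - 1) * ep
  lens <- rep(ep, length(starts))
  if (!is.null(clip_s)) lens <- pmax(0, pmin(starts + ep, clip_s) - starts)
  vapply(split(lens, hyp$stages), sum, numeric(1))
}

# [start, end) intervals (seconds) covered by `stage`, merging contiguous
# epochs; optionally clipped to a recording duration
stage_intervals <- function(hyp, stage, clip_s = NULL) {
  is_stage <- hyp$stages %in% stage
  if (!any(is_stage)) return(matrix(numeric(0), ncol = 2))
  r <- rle(is_stage)
  ends_ep <- cumsum(r$lengths)
  starts_ep <- ends_ep - r$lengths
  keep <- r$values
  out <- cbind(starts_ep[keep] * hyp$epoch_length,
               ends_ep[keep] * hyp$epoch_length)
  if (!is.null(clip_s)) {
    out[, 2] <- pmin(out[, 2], clip_s)
    out <- out[out[, 1] < out[, 2], , drop = FALSE]
  }
  out
}

# logical sample mask of a stage for a recording of n_samples at sfreq
stage_sample_mask <- function(hyp, stage, sfreq, n_samples) {
  mask <- logical(n_samples)
  iv <- stage_intervals(hyp, stage, clip_s = n_samples / sfreq)
  if (nrow(iv)) {
    for (k in seq_len(nrow(iv))) {
      i0 <- floor(iv[k, 1] * sfreq) + 1
      i1 <- min(n_samples, ceiling(iv[k, 2] * sfreq))
      if (i1 >= i0) mask[i0:i1] <- TRUE
    }
  }
  mask
}
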