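# Sleep-spindle detection in N2 sleep by percentile thresholding of the
# smoothed band-power envelope, fast/slow classification, IED exclusion,
# and rate/topography summaries.

#' Parameters of the spindle detector
#'
#' @param band_lo,band_hi detection band, Hz (10-16).
#' @param fast_lo boundary between slow (10-12 Hz) and fast (12-16 Hz)
#'   spindles; exactly 12 Hz classifies as fast (the fast band is printed as
#'   12-16 Hz), configurable here.
#' @param min_dur,max_dur admissible spindle duration, seconds (0.5-3).
#' @param smooth_window moving-average smoothing window, seconds (0.3).
#' @param threshold_percentile boundary percentile of the envelope over N2
#'   samples (80): defines event extent and duration.
#' @param confirm_factor confirmation level as a multiple of the boundary
#'   threshold (5): a candidate run must hold the envelope above
#'   `confirm_factor` x the 80th-percentile threshold for `confirm_min_s`.
#'   Percentile-threshold spindle detectors of this family are
#'   dual-threshold (a low boundary threshold delimits the event, a high
#'   threshold confirms it); a single 80th percentile boundary with a 0.5-s
#'   minimum duration admits sustained runs of band-limited background
#'   noise at any amplitude scale. Anchoring the high threshold to the
#'   boundary percentile keeps it scale-invariant and independent of how
#'   much of N2 is occupied by spindles.
#' @param confirm_min_s minimum time above the confirmation level, seconds.
#' @param min_n2_duration minimum N2 duration for rate eligibility, s (60).
#' @param threshold_scope `"channel"` (per-channel percentile, default) or
#'   `"global"` (one percentile over all channels).
#' @param merge_window cross-channel merge window for rate counting, s.
#' @return list of class `spindle_params`.
#' @export
spindle_params <- function(band_lo = 10, band_hi = 16, fast_lo = 12,
                           min_dur = 0.5, max_dur = 3, smooth_window = 0.3,
                           threshold_percentile = 80, confirm_factor = 5,
                           confirm_min_s = 0.15, min_n2_duration = 60,
                           threshold_scope = c("channel", "global"),
                           merge_window = 0.5) {
  threshold_scope <- match.arg(threshold_scope)
  stopifnot(min_dur < max_dur, band_lo < fast_lo, fast_lo < band_hi,
            threshold_percentile > 0, threshold_percentile < 100,
            confirm_factor >= 1)
  structure(list(band_lo = band_lo, band_hi = band_hi, fast_lo = fast_lo,
                 min_dur = min_dur, max_dur = max_dur,
                 smooth_window = smooth_window,
                 threshold_percentile = threshold_percentile,
                 confirm_factor = confirm_factor,
                 confirm_min_s = confirm_min_s,
                 min_n2_duration = min_n2_duration,
                 threshold_scope = threshold_scope,
                 merge_window = merge_window),
            class = "spindle_params")
}

#' Detect sleep spindles in N2 sleep
#'
#' Per channel: band-pass 10-16 Hz, square, smooth with a 300-ms centered
#' moving average, and threshold at the 80th percentile of the smoothed
#' envelope over N2 samples. Supra-threshold runs lasting 0.5-3 s within N2
#' become detections. The percentile threshold makes detection invariant to
#' amplitude rescaling of the recording.
#'
#' Works in the common average montage; a referential recording is
#' re-referenced internally.
#'
#' @param rec an `eeg_recording` (referential or common average).
#' @param hyp the recording's `hypnogram`.
#' @param params a `spindle_params`.
#' @return an `event_set` of per-channel spindle detections with estimated
#'   `freq_hz`; empty with attribute `status = "skipped_no_n2"` when the
#'   hypnogram has no N2.
#' @export
detect_spindles <- function(rec, hyp, params = spindle_params()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(hyp, "hypnogram"))
  if (rec$montage == "bipolar") {
    stop("spindle detection requires a referential or common-average montage",
         call. = FALSE)
  }
  if (rec$montage == "referential") rec <- to_montage(rec, "common_average")
  sf <- rec$sfreq
  n <- ncol(rec$signal)
  mask <- stage_sample_mask(hyp, "N2", sf, n)
  if (!any(mask)) {
    out <- empty_event_set()
    attr(out, "status") <- "skipped_no_n2"
    return(out)
  }
  sm <- max(1L, round(params$smooth_window * sf))
  env <- matrix(0, nrow = nrow(rec$signal), ncol = n)
  for (i in seq_len(nrow(rec$signal))) {
    bp <- fft_bandpass(rec$signal[i, ], sf, params$band_lo, params$band_hi)
    env[i, ] <- moving_average(bp^2, sm)
  }
  q <- params$threshold_percentile / 100
  thr <- if (params$threshold_scope == "global") {
    rep(quantile(env[, mask], q), nrow(env))
  } else {
    apply(env[, mask, drop = FALSE], 1, quantile, probs = q)
  }
  thr_hi <- params$confirm_factor * thr
  res <- list()
  for (i in seq_len(nrow(env))) {
    supra <- env[i, ] > thr[i] & mask
    r <- rle(supra)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    for (k in keep) {
      # the moving average smears the envelope of a strong burst by about
      # the full smoothing window; correct the run length before gating so
      # sub-min_dur bursts are not promoted past the duration criterion
      dur <- r$lengths[k] / sf - params$smooth_window
      if (dur < params$min_dur || dur > params$max_dur) next
      i0 <- starts[k]; i1 <- ends[k]
      # sustained confirmation: hold the high envelope level
      if (sum(env[i, i0:i1] > thr_hi[i]) < params$confirm_min_s * sf) next
      seg <- rec$signal[i, i0:i1]
      f <- periodogram_peak(seg, sf, params$band_lo, params$band_hi)
      res[[length(res) + 1]] <- data.frame(
        onset = (i0 - 1) / sf + params$smooth_window / 2, duration = dur,
        channels = rec$channels[i], freq_hz = f,
        score = max(env[i, i0:i1]) / thr[i])
    }
  }
  if (!length(res)) return(empty_event_set())
  df <- do.call(rbind, res)
  event_set(onset = df$onset, duration = df$duration, type = "spindle",
            channels = df$channels, source = "detected", score = df$score,
            freq_hz = df$freq_hz)
}

#' Classify a spindle as fast or slow
#'
#' Dominant frequency at or above the fast boundary (12 Hz) is fast,
#' below is slow.
#'
#' @param freq_hz dominant frequency in Hz (vectorized).
#' @param params a `spindle_params`.
#' @return character vector, `"fast"` or `"slow"`.
#' @export
classify_spindle <- function(freq_hz, params = spindle_params()) {
  ifelse(freq_hz >= params$fast_lo, "fast", "slow")
}

#' Estimate the dominant frequency of a spindle event
#'
#' Spectral peak of the event segment within the detection band, from a
#' zero-padded Hann periodogram (robust for events as short as 0.5 s).
#'
#' @param rec the `eeg_recording`.
#' @param event one-row `event_set` slice.
#' @param params a `spindle_params`.
#' @return frequency in Hz.
#' @export
spindle_frequency <- function(rec, event, params = spindle_params()) {
  sf <- rec$sfreq
  ch <- event_channels(event)[[1]][1]
  i <- match(ch, rec$channels)
  i0 <- round(event$onset[1] * sf) + 1
  i1 <- min(ncol(rec$signal), i0 + round(event$duration[1] * sf) - 1)
  periodogram_peak(rec$signal[i, i0:i1], sf, params$band_lo, params$band_hi)
}

#' Exclude spindle detections overlapping IED activity
#'
#' Removes any spindle whose span intersects an IED span (the fixed 250-ms
#' peak-centered window) or a burst span; detections at the time of an IED
#' are potential misdetections.
#'
#' @param spindles spindle `event_set`.
#' @param ieds `event_set` with IED/burst rows on the same time base.
#' @return the filtered spindle `event_set`.
#' @export
exclude_ied_overlap <- function(spindles, ieds) {
  if (nrow(spindles) == 0) return(spindles)
  spans <- event_spans(filter_events(ieds, ieds$type %in% c("IED", "burst")))
  if (nrow(spans) == 0) return(spindles)
  s <- event_spans(spindles)
  keep <- vapply(seq_len(nrow(s)), function(k) {
    !any(s[k, 1] < spans[, 2] & spans[, 1] < s[k, 2])
  }, logical(1))
  filter_events(spindles, keep)
}

# cross-channel merge: detections within merge_window of a cluster's
# earliest onset count once (rates are per recording, not per channel)
merge_spindles <- function(spindles, merge_window) {
  if (nrow(spindles) == 0) return(spindles)
  o <- order(spindles$onset)
  ev <- spindles[o, , drop = FALSE]
  rep_rows <- integer(0)
  anchor <- -Inf
  for (k in seq_len(nrow(ev))) {
    if (ev$onset[k] - anchor > merge_window) {
      rep_rows <- c(rep_rows, k)
      anchor <- ev$onset[k]
    }
  }
  filter_events(ev, seq_len(nrow(ev)) %in% rep_rows)
}

#' Spindle rates per minute of N2 sleep
#'
#' Applies the 1-min N2 eligibility rule, merges cross-channel detections of
#' the same spindle (earliest onset wins), and reports overall, fast and
#' slow rates plus per-channel rates for topographic maps.
#' `rate_all = rate_fast + rate_slow` exactly.
#'
#' @param events spindle `event_set` (after IED exclusion).
#' @param hyp the recording's `hypnogram`.
#' @param params a `spindle_params`.
#' @param clip_s optional recording duration to clip the hypnogram.
#' @return list of class `spindle_report`: `eligible`, `n2_duration`,
#'   `rate_all`, `rate_fast`, `rate_slow`, `per_channel_rates`,
#'   `n_detections`.
#' @export
spindle_rates <- function(events, hyp, params = spindle_params(),
                          clip_s = NULL) {
  iv <- stage_intervals(hyp, "N2", clip_s = clip_s)
  n2 <- if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0
  if (n2 < params$min_n2_duration) {
    return(structure(list(eligible = FALSE, n2_duration = n2,
                          rate_all = NA_real_, rate_fast = NA_real_,
                          rate_slow = NA_real_, per_channel_rates = NULL,
                          n_detections = nrow(events)),
                     class = "spindle_report"))
  }
  minutes <- n2 / 60
  merged <- merge_spindles(events, params$merge_window)
  cls <- classify_spindle(merged$freq_hz, params)
  per_ch <- table(unlist(event_channels(events)))
  per_channel <- setNames(numeric(length(CHANNELS_1020)), CHANNELS_1020)
  per_channel[names(per_ch)[names(per_ch) %in% CHANNELS_1020]] <-
    as.integer(per_ch[names(per_ch) %in% CHANNELS_1020]) / minutes
  structure(list(eligible = TRUE, n2_duration = n2,
                 rate_all = nrow(merged) / minutes,
                 rate_fast = sum(cls == "fast") / minutes,
                 rate_slow = sum(cls == "slow") / minutes,
                 per_channel_rates = per_channel,
                 n_detections = nrow(events)),
            class = "spindle_report")
}

#' @export
print.spindle_report <- function(x, ...) {
  if (!x$eligible) {
    cat(sprintf("spindle analysis ineligible: %.0f s of N2 (< minimum)\n",
                x$n2_duration))
  } else {
    cat(sprintf(
      "spindles in %.1f min N2: %.2f/min (fast %.2f, slow %.2f)\n",
      x$n2_duration / 60, x$rate_all, x$rate_fast, x$rate_slow))
  }
  invisible(x)
}
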