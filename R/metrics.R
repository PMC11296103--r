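# IED-derived endpoints: vigilance-state matching, IEA burden, channel
# involvement, gamma precursor proportion, percentage change.

#' Select the vigilance state common to a recording pair
#'
#' Among stages present in both hypnograms, returns the one maximizing the
#' minimum of the two stage durations, with any sleep stage preferred over
#' wake regardless of duration (IED rates are typically higher in NREM
#' sleep, so comparisons are made in sleep whenever both recordings allow
#' it). Ties break toward the deeper stage.
#'
#' @param hyp_pre,hyp_post `hypnogram`s of the two recordings.
#' @return a stage label (`"W"`, `"N1"`, `"N2"`, `"N3"` or `"NREM"`).
#' @export
select_common_state <- function(hyp_pre, hyp_post) {
  d_pre <- stage_seconds(hyp_pre)
  d_post <- stage_seconds(hyp_post)
  common <- intersect(names(d_pre)[d_pre > 0], names(d_post)[d_post > 0])
  if (!length(common)) stop("no vigilance state common to both recordings",
                            call. = FALSE)
  sleep <- intersect(common, SLEEP_STAGES)
  cand <- if (length(sleep)) sleep else common
  min_dur <- pmin(d_pre[cand], d_post[cand])
  depth <- match(cand, c("W", "N1", "NREM", "N2", "N3"))  # deeper wins ties
  cand[order(-min_dur, -depth)][1]
}

# union of half-open intervals; returns total covered length
interval_union_length <- function(spans, clip = NULL) {
  if (nrow(spans) == 0) return(0)
  if (!is.null(clip)) {
    spans[, 1] <- pmax(spans[, 1], clip[1])
    spans[, 2] <- pmin(spans[, 2], clip[2])
    spans <- spans[spans[, 1] < spans[, 2], , drop = FALSE]
    if (nrow(spans) == 0) return(0)
  }
  o <- order(spans[, 1])
  s <- spans[o, 1]; e <- spans[o, 2]
  tot <- 0; cs <- s[1]; ce <- e[1]
  for (k in seq_along(s)[-1]) {
    if (s[k] > ce) { tot <- tot + (ce - cs); cs <- s[k]; ce <- e[k] }
    else ce <- max(ce, e[k])
  }
  tot + (ce - cs)
}

#' Compute the interictal epileptic activity (IEA) burden
#'
#' Burden is the percentage of analyzed recording time covered by IEDs and
#' bursts: each IED contributes its fixed 250-ms span, bursts their full
#' annotated duration, and overlapping spans are unioned before summation
#' (coverage cannot exceed 100%).
#'
#' @param events an `event_set`, already restricted to the analyzed
#'   vigilance state.
#' @param total_duration duration of the analyzed segments, seconds (> 0).
#' @param analyzed_state optional stage label carried into the report.
#' @return list of class `burden_report` with `burden_percent`, `n_ieds`,
#'   `n_bursts`, `analyzed_state`, `analyzed_duration`,
#'   `ied_event_duration`.
#' @export
compute_burden <- function(events, total_duration, analyzed_state = NA) {
  if (!is.numeric(total_duration) || total_duration <= 0) {
    stop("total_duration must be > 0", call. = FALSE)
  }
  keep <- events$type %in% c("IED", "burst")
  ev <- filter_events(events, keep)
  covered <- interval_union_length(event_spans(ev))
  burden <- 100 * covered / total_duration
  structure(list(burden_percent = min(burden, 100),
                 n_ieds = sum(ev$type == "IED"),
                 n_bursts = sum(ev$type == "burst"),
                 analyzed_state = analyzed_state,
                 analyzed_duration = total_duration,
                 ied_event_duration = IED_DURATION_S),
            class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat(sprintf("IEA burden: %.2f%% (%d IEDs, %d bursts in %.1f min of %s)\n",
              x$burden_percent, x$n_ieds, x$n_bursts,
              x$analyzed_duration / 60,
              if (is.na(x$analyzed_state)) "recording" else x$analyzed_state))
  invisible(x)
}

#' Channels involved in IED events
#'
#' Counts attributed channels per IED/burst event; the per-recording summary
#' is the 95th percentile of the count distribution (linear interpolation
#' between closest ranks, the R type-7 default).
#'
#' @param events an `event_set` with channel attributions.
#' @return list with `per_event` (integer vector) and `p95` (numeric,
#'   `NA` for an empty event set).
#' @export
channel_involvement <- function(events) {
  ev <- filter_events(events, events$type %in% c("IED", "burst"))
  counts <- vapply(event_channels(ev), length, integer(1))
  list(per_event = counts,
       p95 = if (length(counts)) unname(quantile(counts, 0.95, type = 7))
             else NA_real_)
}

#' Parameters of the gamma-precursor analysis
#'
#' @param band_lo,band_hi gamma band edges, Hz (30-70).
#' @param precursor_window window before IED onset, seconds.
#' @param criterion_sd presence criterion: precursor RMS must exceed the
#'   mean background RMS by this many background SDs.
#' @param min_background_windows minimum event-free reference windows.
#' @return list of class `gamma_params`.
#' @export
gamma_params <- function(band_lo = 30, band_hi = 70, precursor_window = 0.2,
                         criterion_sd = 2, min_background_windows = 20) {
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 precursor_window = precursor_window,
                 criterion_sd = criterion_sd,
                 min_background_windows = min_background_windows),
            class = "gamma_params")
}

#' Proportion of IEDs with preceding gamma activity
#'
#' For each IED the 30-70 Hz band RMS in the precursor window (default
#' 200 ms ending at the IED span onset) is compared, per attributed channel,
#' against the distribution of band RMS in event-free windows of the same
#' channel; gamma is present when any attributed channel exceeds
#' mean + `criterion_sd` x SD of its background RMS.
#'
#' @param rec the `eeg_recording` (sampling rate must exceed twice the upper
#'   band edge).
#' @param events an `event_set`; IED rows are analyzed, all spans define the
#'   event-free background.
#' @param params a `gamma_params`.
#' @return percentage of IEDs with gamma (`NA` with a warning if there are
#'   no IEDs).
#' @export
gamma_proportion <- function(rec, events, params = gamma_params()) {
  if (rec$sfreq <= 2 * params$band_hi) {
    stop("sampling rate too low for the gamma band", call. = FALSE)
  }
  ieds <- filter_events(events, events$type == "IED")
  if (nrow(ieds) == 0) {
    warning("no IEDs: gamma proportion undefined")
    return(NA_real_)
  }
  sf <- rec$sfreq
  n <- ncol(rec$signal)
  wlen <- round(params$precursor_window * sf)
  need_ch <- unique(unlist(event_channels(ieds)))
  need_ch <- intersect(need_ch, rec$channels)
  if (!length(need_ch)) need_ch <- rec$channels[1]
  # gamma power of an isolated window via its own Hann periodogram: the
  # window content alone determines the estimate, so the adjacent spike
  # (outside the window) cannot leak in, unlike any band-pass of the
  # continuous signal
  h <- hann_window(wlen)
  nfft <- 2L^ceiling(log2(4 * wlen))
  f <- seq(0, nfft - 1) / nfft * sf
  sel <- f >= params$band_lo & f <= params$band_hi
  band_rms_at <- function(ch, start_s) {
    i0 <- max(1, round(start_s * sf) + 1)
    if (i0 + wlen - 1 > n) return(NA_real_)
    seg <- rec$signal[match(ch, rec$channels), i0:(i0 + wlen - 1)]
    seg <- (seg - mean(seg)) * h
    sqrt(sum(Mod(fft(c(seg, numeric(nfft - wlen))))[sel]^2))
  }
  # event-free background reference windows on a deterministic grid
  spans <- event_spans(events)
  grid <- seq(0.5, n / sf - params$precursor_window - 0.5,
              by = params$precursor_window * 2)
  free <- vapply(grid, function(s) {
    !overlaps_any(s - 0.3, s + params$precursor_window + 0.3, spans,
                  margin = 0)
  }, logical(1))
  grid <- grid[free]
  if (length(grid) < params$min_background_windows) {
    stop("too few event-free segments to form the gamma reference distribution",
         call. = FALSE)
  }
  bg_stats <- lapply(need_ch, function(ch) {
    r <- vapply(grid, function(s) band_rms_at(ch, s), numeric(1))
    c(mean = mean(r), sd = sd(r))
  })
  names(bg_stats) <- need_ch
  ch_lists <- event_channels(ieds)
  positive <- vapply(seq_len(nrow(ieds)), function(k) {
    chs <- intersect(ch_lists[[k]], need_ch)
    if (!length(chs)) chs <- need_ch[1]
    t0 <- ieds$onset[k] - params$precursor_window
    if (t0 < 0) return(FALSE)
    any(vapply(chs, function(ch) {
      st <- bg_stats[[ch]]
      v <- band_rms_at(ch, t0)
      !is.na(v) && v >= st["mean"] + params$criterion_sd * st["sd"]
    }, logical(1)))
  }, logical(1))
  100 * mean(positive)
}

#' Percentage change of a metric
#'
#' `100 * (post - pre) / pre`; negative values indicate improvement for
#' burden-like metrics. Undefined (NA with a warning) when `pre <= 0`.
#'
#' @param pre,post metric values.
#' @return percentage change.
#' @export
percent_change <- function(pre, post) {
  out <- 100 * (post - pre) / pre
  bad <- !is.na(pre) & pre <= 0
  if (any(bad)) {
    warning("percent change undefined for non-positive baseline value(s)")
    out[bad] <- NA_real_
  }
  out
}

#' Per-subject endpoint table of a cohort, from ground truth or detections
#'
#' For each subject: selects the common vigilance state, restricts IED/burst
#' events to it and computes the burden; computes N2 spindle rates (fast,
#' slow, all) with the 1-min N2 eligibility rule applied to both arms.
#' Works on event times alone, so it accepts cohorts generated with
#' `signals = FALSE`.
#'
#' @param cohort a `paired_cohort`.
#' @param spindle_par a `spindle_params` (for the eligibility minimum).
#' @return data.frame with one row per subject.
#' @export
cohort_metrics <- function(cohort, spindle_par = spindle_params()) {
  rows <- lapply(cohort$subjects, function(su) {
    state <- select_common_state(su$pre$hypnogram, su$post$hypnogram)
    arm_burden <- function(arm) {
      dur <- arm$params$duration
      iv <- stage_intervals(arm$hypnogram, state, clip_s = dur)
      ev <- restrict_events_to_intervals(arm$events, iv)
      compute_burden(ev, sum(iv[, 2] - iv[, 1]), analyzed_state = state)
    }
    b_pre <- arm_burden(su$pre); b_post <- arm_burden(su$post)
    arm_spindles <- function(arm) {
      sp <- filter_events(arm$events, arm$events$type == "spindle")
      spindle_rates(sp, arm$hypnogram, spindle_par,
                    clip_s = arm$params$duration)
    }
    s_pre <- arm_spindles(su$pre); s_post <- arm_spindles(su$post)
    eligible <- s_pre$eligible && s_post$eligible
    data.frame(
      subject = su$id, state = state,
      burden_pre = b_pre$burden_percent, burden_post = b_post$burden_percent,
      spindle_eligible = eligible,
      spindle_all_pre = if (eligible) s_pre$rate_all else NA_real_,
      spindle_all_post = if (eligible) s_post$rate_all else NA_real_,
      spindle_fast_pre = if (eligible) s_pre$rate_fast else NA_real_,
      spindle_fast_post = if (eligible) s_post$rate_fast else NA_real_,
      spindle_slow_pre = if (eligible) s_pre$rate_slow else NA_real_,
      spindle_slow_post = if (eligible) s_post$rate_slow else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
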