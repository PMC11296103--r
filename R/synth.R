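# Synthetic EEG cohort generator with known ground truth.
#
# The stated world: 19-channel scalp EEG at 256 Hz with 1/f background and a
# posterior alpha rhythm; spike(-wave) IED templates and multi-second bursts
# placed by a homogeneous Poisson process with overlap rejection; 10-16 Hz
# amplitude-modulated spindles confined to N2; optional 30-70 Hz gamma
# precursors before a fraction of IEDs; block hypnograms W->N1->N2->N3.
# Baseline/post presets are calibrated so that the nominal IEA burden is
# 5.4% / 1.5% and fast-spindle rates 0.8 / 1.5 per minute of N2.

#' Parameters of the synthetic EEG generator
#'
#' Returns a validated parameter list. Defaults encode the baseline
#' (`condition = "baseline"`) or post-treatment (`condition = "post"`)
#' operating point: event rates are chosen so the nominal IEA burden
#' (`0.25 s x ied_rate + burst_rate x burst_duration`, per minute) equals
#' 5.4% at baseline and 1.5% post, and N2 spindle rates total 1.1/min
#' (0.8 fast + 0.3 slow) at baseline and 1.8/min (1.5 + 0.3) post.
#'
#' @param condition preset selector, `"baseline"` or `"post"`.
#' @param sampling_rate Hz (default 256; the source protocol states none).
#' @param duration recording length in seconds.
#' @param n_channels number of 10-20 channels (19 for the standard pipeline).
#' @param background_exponent spectral slope beta of the 1/f^beta background.
#' @param background_sd per-channel background standard deviation, microvolts.
#' @param ied_rate,burst_rate events per minute (whole recording).
#' @param burst_duration mean burst length, seconds (jittered +/-40%).
#' @param spindle_rate_n2 spindles per minute of N2 sleep.
#' @param spindle_freq nominal fast-spindle frequency in Hz, within [10, 16].
#' @param spindle_slow_fraction fraction of spindles drawn from the slow
#'   (10-12 Hz) band.
#' @param gamma_precursor_fraction fraction of IEDs preceded by a 30-70 Hz
#'   gamma burst, in [0, 1].
#' @param ied_snr IED peak amplitude in units of channel background SD.
#' @param spindle_snr spindle amplitude in units of the channel's 10-16 Hz
#'   band SD.
#' @param gamma_snr gamma-precursor amplitude in units of the channel's
#'   30-70 Hz band SD.
#' @param stage_fractions named fractions of the recording spent in
#'   W/N1/N2/N3 (block hypnogram in that order).
#' @param collapse_nrem collapse N1/N2/N3 to the single `NREM` label (the
#'   scoring fallback when stage discrimination is impossible).
#' @param seed integer seed; a fixed seed makes every product bit-identical.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(condition = c("baseline", "post"),
                         sampling_rate = 256, duration = 1200,
                         n_channels = 19, background_exponent = 2,
                         background_sd = 15,
                         ied_rate = NULL, burst_rate = NULL,
                         burst_duration = 3.6,
                         spindle_rate_n2 = NULL, spindle_freq = 13,
                         spindle_slow_fraction = NULL,
                         gamma_precursor_fraction = NULL,
                         ied_snr = 6, spindle_snr = 8, gamma_snr = 3,
                         stage_fractions = c(W = 0.25, N1 = 0.15,
                                             N2 = 0.40, N3 = 0.20),
                         collapse_nrem = FALSE, seed = 1L) {
  condition <- match.arg(condition)
  eff <- 1.5 / 5.4                      # post/baseline ratio of burden medians
  if (is.null(ied_rate)) ied_rate <- if (condition == "baseline") 6.5 else 6.5 * eff
  if (is.null(burst_rate)) burst_rate <- if (condition == "baseline") 0.45 else 0.45 * eff
  if (is.null(spindle_rate_n2)) {
    spindle_rate_n2 <- if (condition == "baseline") 0.8 + 0.3 else 1.5 + 0.3
  }
  if (is.null(spindle_slow_fraction)) {
    spindle_slow_fraction <- if (condition == "baseline") 0.3 / 1.1 else 0.3 / 1.8
  }
  if (is.null(gamma_precursor_fraction)) {
    gamma_precursor_fraction <- if (condition == "baseline") 0.143 else 0.286
  }
  p <- list(condition = condition, sampling_rate = sampling_rate,
            duration = duration, n_channels = n_channels,
            background_exponent = background_exponent,
            background_sd = background_sd,
            ied_rate = ied_rate, burst_rate = burst_rate,
            burst_duration = burst_duration,
            spindle_rate_n2 = spindle_rate_n2, spindle_freq = spindle_freq,
            spindle_slow_fraction = spindle_slow_fraction,
            gamma_precursor_fraction = gamma_precursor_fraction,
            ied_snr = ied_snr, spindle_snr = spindle_snr,
            gamma_snr = gamma_snr,
            stage_fractions = stage_fractions,
            collapse_nrem = collapse_nrem, seed = as.integer(seed))
  class(p) <- "synth_params"
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  stopifnot(inherits(p, "synth_params"))
  if (p$duration <= 0) stop("synth_params: duration must be > 0", call. = FALSE)
  if (p$sampling_rate <= 0) stop("synth_params: sampling_rate must be > 0",
                                 call. = FALSE)
  rates <- c(p$ied_rate, p$burst_rate, p$spindle_rate_n2)
  if (any(rates < 0)) stop("synth_params: rates must be >= 0", call. = FALSE)
  if (p$spindle_freq < 10 || p$spindle_freq > 16) {
    stop("synth_params: spindle_freq must lie in [10, 16] Hz", call. = FALSE)
  }
  if (p$gamma_precursor_fraction < 0 || p$gamma_precursor_fraction > 1) {
    stop("synth_params: gamma_precursor_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  if (p$n_channels < 1 || p$n_channels > 19) {
    stop("synth_params: n_channels must be in 1..19", call. = FALSE)
  }
  fr <- p$stage_fractions
  if (!all(c("W", "N1", "N2", "N3") %in% names(fr)) ||
      abs(sum(fr) - 1) > 1e-6 || any(fr < 0)) {
    stop("synth_params: stage_fractions must be named W/N1/N2/N3 and sum to 1",
         call. = FALSE)
  }
  invisible(p)
}

#' Nominal IEA burden implied by generator rates
#'
#' `100 * (0.25 * ied_rate + burst_rate * burst_duration) / 60`: the expected
#' percentage of recording time covered by injected IEDs plus bursts.
#'
#' @param params a `synth_params`.
#' @return percentage in `[0, 100]`.
#' @export
nominal_burden_percent <- function(params) {
  100 * (IED_DURATION_S * params$ied_rate +
           params$burst_rate * params$burst_duration) / 60
}

#' Generate a block hypnogram
#'
#' Deterministic fixed block sequence W -> N1 -> N2 -> N3 with epoch counts
#' proportional to `stage_fractions` (largest-remainder rounding to whole
#' 30-s epochs). With `collapse_nrem` all sleep epochs carry the `NREM`
#' label.
#'
#' @param params a `synth_params` (uses duration, stage_fractions,
#'   collapse_nrem).
#' @param epoch_length epoch length in seconds.
#' @return a `hypnogram` covering at least `params$duration`.
#' @export
generate_hypnogram <- function(params, epoch_length = 30) {
  n_ep <- ceiling(params$duration / epoch_length)
  fr <- params$stage_fractions[c("W", "N1", "N2", "N3")]
  raw <- fr * n_ep
  counts <- floor(raw)
  rem <- n_ep - sum(counts)
  if (rem > 0) {
    give <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[give] <- counts[give] + 1
  }
  stages <- rep(c("W", "N1", "N2", "N3"), times = counts)
  if (params$collapse_nrem) stages[stages != "W"] <- "NREM"
  hypnogram(stages, epoch_length = epoch_length)
}

#' Generate the event-free synthetic background EEG
#'
#' Per-channel 1/f^beta Gaussian noise scaled to `background_sd`, plus a
#' low-amplitude amplitude-modulated 10-Hz alpha rhythm on posterior
#' channels during wake epochs only (alpha attenuates with sleep onset;
#' rendering it in N2 would bleed a common 10-Hz component into every
#' channel of the common-average montage and contaminate the spindle band).
#' Bit-identical under a fixed seed.
#'
#' @param params a `synth_params`.
#' @return an `eeg_recording` (referential montage, microvolts).
#' @export
generate_background <- function(params) {
  validate_synth_params(params)
  sf <- params$sampling_rate
  n <- round(params$duration * sf)
  chans <- CHANNELS_1020[seq_len(params$n_channels)]
  withr::with_seed(params$seed, {
    sig <- matrix(0, nrow = length(chans), ncol = n)
    for (i in seq_along(chans)) {
      sig[i, ] <- pink_noise(n, params$background_exponent) * params$background_sd
    }
    tt <- seq_len(n) / sf
    wake <- stage_sample_mask(generate_hypnogram(params), "W", sf, n)
    if (any(wake)) {
      for (ch in intersect(POSTERIOR_CHANNELS, chans)) {
        phase <- runif(2, 0, 2 * pi)
        am <- 0.6 + 0.4 * sin(2 * pi * 0.05 * tt + phase[2])
        alpha <- 0.25 * params$background_sd *
          sin(2 * pi * 10 * tt + phase[1]) * am * wake
        i <- match(ch, chans)
        sig[i, ] <- sig[i, ] + alpha
      }
    }
    new_recording(sig, sf, chans, montage = "referential")
  })
}

# ---- event drawing ---------------------------------------------------------

overlaps_any <- function(start, end, occupied, margin = 0.05) {
  if (nrow(occupied) == 0) return(FALSE)
  any(start - margin < occupied[, 2] & occupied[, 1] < end + margin)
}

place_span <- function(len, lo, hi, occupied, margin = 0.05, tries = 500,
                       n_occ = nrow(occupied)) {
  if (hi - lo < len) return(NA_real_)
  occ_s <- occupied[seq_len(n_occ), 1]
  occ_e <- occupied[seq_len(n_occ), 2]
  for (k in seq_len(tries)) {
    s <- runif(1, lo, hi - len)
    if (n_occ == 0 ||
        !any(s - margin < occ_e & occ_s < s + len + margin)) return(s)
  }
  NA_real_
}

# Core seeded draw.  Documented draw order (relied on by replay oracles):
# (1) n_ied <- rpois(1, ied_rate * minutes)
# (2) n_burst <- rpois(1, burst_rate * minutes)
# (3) n_spindle <- rpois(1, spindle_rate_n2 * n2_minutes)
# then burst placement, IED placement, spindle placement, channel draws,
# gamma flags.
draw_events_impl <- function(params, hyp) {
  dur <- params$duration
  minutes <- dur / 60
  chans <- CHANNELS_1020[seq_len(params$n_channels)]
  n2_iv <- stage_intervals(hyp, "N2", clip_s = dur)
  n2_minutes <- if (nrow(n2_iv)) sum(n2_iv[, 2] - n2_iv[, 1]) / 60 else 0

  n_ied <- rpois(1, params$ied_rate * minutes)
  n_burst <- rpois(1, params$burst_rate * minutes)
  n_spindle <- rpois(1, params$spindle_rate_n2 * n2_minutes)

  cap_n <- n_ied + n_burst + n_spindle
  occupied <- matrix(NA_real_, nrow = max(cap_n, 1), ncol = 2)
  n_occ <- 0L
  push_span <- function(s, e) {
    n_occ <<- n_occ + 1L
    occupied[n_occ, ] <<- c(s, e)
  }
  edge <- 0.5
  fail <- function(what) {
    stop("synthetic event placement: retry budget exhausted while placing ",
         what, " (nominal rates too high for the recording length)",
         call. = FALSE)
  }

  bursts <- list(onset = numeric(n_burst), duration = numeric(n_burst))
  if (n_burst > 0) {
    blen <- params$burst_duration * runif(n_burst, 0.6, 1.4)
    for (k in seq_len(n_burst)) {
      s <- place_span(blen[k], edge, dur - edge, occupied, n_occ = n_occ)
      if (is.na(s)) fail("a burst")
      push_span(s, s + blen[k])
      bursts$onset[k] <- s
      bursts$duration[k] <- blen[k]
    }
  }

  ied_onsets <- numeric(n_ied)
  if (n_ied > 0) {
    # isolated discharges keep >= 1.25 s clearance (closer runs of spikes
    # are what the burst type models); dense regimes where that clearance
    # is infeasible fall back to plain overlap rejection
    sparse <- n_ied * (IED_DURATION_S + 2.5) < 0.7 * dur
    for (k in seq_len(n_ied)) {
      s <- if (sparse) place_span(IED_DURATION_S, edge, dur - edge,
                                  occupied, margin = 1.25, tries = 100,
                                  n_occ = n_occ)
           else NA_real_
      if (is.na(s)) s <- place_span(IED_DURATION_S, edge, dur - edge,
                                    occupied, n_occ = n_occ)
      if (is.na(s)) fail("an IED")
      push_span(s, s + IED_DURATION_S)
      ied_onsets[k] <- s
    }
  }

  spind <- list(onset = numeric(0), duration = numeric(0), freq = numeric(0))
  if (n_spindle > 0 && nrow(n2_iv) > 0) {
    m <- 0L
    spind <- list(onset = numeric(n_spindle), duration = numeric(n_spindle),
                  freq = numeric(n_spindle))
    for (k in seq_len(n_spindle)) {
      slen <- runif(1, 0.5, 3)
      slow <- runif(1) < params$spindle_slow_fraction
      f <- if (slow) runif(1, 10.3, 11.7) else runif(1, 12.3, 15.5)
      # pick an N2 run able to hold the spindle, weighted by spare length
      spare <- pmax(0, (n2_iv[, 2] - n2_iv[, 1]) - slen - 0.2)
      if (all(spare <= 0)) next
      run <- sample.int(nrow(n2_iv), 1, prob = spare)
      s <- place_span(slen, n2_iv[run, 1] + 0.1, n2_iv[run, 2] - 0.1,
                      occupied, n_occ = n_occ)
      if (is.na(s)) next                 # spindle collisions are tolerable
      push_span(s, s + slen)
      m <- m + 1L
      spind$onset[m] <- s
      spind$duration[m] <- slen
      spind$freq[m] <- f
    }
    spind <- lapply(spind, function(x) x[seq_len(m)])
  }

  # channel attribution: a per-recording focal set for IEDs/bursts
  focal <- sample(chans, min(5, length(chans)))
  draw_ied_channels <- function() {
    k <- 1 + rbinom(1, length(focal) - 1, 0.4)
    join_channels(sort(sample(focal, k)))
  }
  ied_ch <- vapply(seq_along(ied_onsets), function(k) draw_ied_channels(),
                   character(1))
  burst_ch <- vapply(seq_along(bursts$onset), function(k) draw_ied_channels(),
                     character(1))
  spin_pool <- intersect(SPINDLE_CHANNELS, chans)
  if (!length(spin_pool)) spin_pool <- chans
  spin_ch <- vapply(seq_along(spind$onset), function(k) {
    join_channels(sort(sample(spin_pool, min(length(spin_pool),
                                             sample(3:6, 1)))))
  }, character(1))
  gamma <- if (length(ied_onsets)) {
    runif(length(ied_onsets)) < params$gamma_precursor_fraction
  } else logical(0)

  ev <- event_set(
    onset = c(ied_onsets - IED_DURATION_S / 2, bursts$onset, spind$onset),
    duration = c(rep(IED_DURATION_S, length(ied_onsets)), bursts$duration,
                 spind$duration),
    type = c(rep("IED", length(ied_onsets)),
             rep("burst", length(bursts$onset)),
             rep("spindle", length(spind$onset))),
    channels = c(ied_ch, burst_ch, spin_ch),
    source = "manual",
    freq_hz = c(rep(NA_real_, length(ied_onsets) + length(bursts$onset)),
                spind$freq)
  )
  # gamma flag, re-aligned after the constructor's onset sort
  g <- rep(NA, nrow(ev))
  if (length(ied_onsets)) {
    key <- round(ied_onsets - IED_DURATION_S / 2, 9)
    g[ev$type == "IED"] <- gamma[match(round(ev$onset[ev$type == "IED"], 9), key)]
  }
  ev$gamma <- g
  ev
}

#' Draw ground-truth events without rendering signal
#'
#' Runs the seeded Poisson/rejection event draw only (seed offset +1 from the
#' background seed), so that event times are identical whether or not the
#' waveforms are rendered into a signal.
#'
#' @param params a `synth_params`.
#' @param hyp optional `hypnogram`; generated from `params` if missing.
#' @return list with `events` (an `event_set`, with a logical `gamma` column
#'   on IED rows) and `hypnogram`.
#' @export
draw_ground_truth <- function(params, hyp = NULL) {
  validate_synth_params(params)
  if (is.null(hyp)) hyp <- generate_hypnogram(params)
  ev <- withr::with_seed(params$seed + 1L, draw_events_impl(params, hyp))
  list(events = ev, hypnogram = hyp)
}

# ---- rendering -------------------------------------------------------------

# Triphasic spike (70-ms core) plus optional 300-ms slow wave; peak (max
# absolute deflection, negative) at time 0 of the template axis.
ied_template <- function(sfreq, amp, slow_wave = TRUE) {
  tt <- seq(-0.1, 0.4, by = 1 / sfreq)
  w <- -amp * exp(-tt^2 / (2 * 0.008^2)) +
    0.35 * amp * exp(-(tt + 0.022)^2 / (2 * 0.010^2)) +
    0.30 * amp * exp(-(tt - 0.026)^2 / (2 * 0.012^2))
  if (slow_wave) {
    sw <- ifelse(tt >= 0.05 & tt <= 0.35,
                 0.45 * amp * sin(pi * (tt - 0.05) / 0.30), 0)
    w <- w + sw
  }
  list(wave = w, peak = which.min(abs(tt)))
}

add_wave <- function(sig, ch_idx, center_idx, wave, peak, gains) {
  n <- ncol(sig)
  i0 <- center_idx - peak + 1
  idx <- seq_along(wave) + i0 - 1
  keep <- idx >= 1 & idx <= n
  for (j in seq_along(ch_idx)) {
    sig[ch_idx[j], idx[keep]] <- sig[ch_idx[j], idx[keep]] + gains[j] * wave[keep]
  }
  sig
}

render_events_impl <- function(rec, params, ev) {
  sig <- rec$signal
  sf <- rec$sfreq
  chans <- rec$channels
  ch_sd <- apply(sig, 1, sd)
  band_sd_spindle <- vapply(seq_len(nrow(sig)), function(i) {
    sd(fft_bandpass(sig[i, ], sf, 10, 16))
  }, numeric(1))
  band_sd_gamma <- vapply(seq_len(nrow(sig)), function(i) {
    sd(fft_bandpass(sig[i, ], sf, 30, 70))
  }, numeric(1))

  for (r in seq_len(nrow(ev))) {
    ch <- match(event_channels(ev[r, , drop = FALSE])[[1]], chans)
    ch <- ch[!is.na(ch)]
    if (!length(ch)) next
    gains <- c(1, runif(length(ch) - 1, 0.5, 1))
    type <- ev$type[r]
    if (type == "IED") {
      center <- round((ev$onset[r] + IED_DURATION_S / 2) * sf)
      tpl <- ied_template(sf, params$ied_snr * ch_sd[ch[1]])
      sig <- add_wave(sig, ch, center, tpl$wave, tpl$peak, gains)
      if (isTRUE(ev$gamma[r])) {
        glen <- round(0.2 * sf)
        gb <- fft_bandpass(rnorm(glen * 3), sf, 30, 70)[glen + seq_len(glen)]
        gb <- gb / sd(gb) * hann_window(glen)
        g0 <- round(ev$onset[r] * sf) - glen
        if (g0 >= 1) {
          idx <- g0 + seq_len(glen) - 1
          for (j in seq_along(ch)) {
            sig[ch[j], idx] <- sig[ch[j], idx] +
              params$gamma_snr * band_sd_gamma[ch[j]] * gb * gains[j]
          }
        }
      }
    } else if (type == "burst") {
      peaks <- seq(ev$onset[r] + 0.15, ev$onset[r] + ev$duration[r] - 0.15,
                   by = IED_DURATION_S)
      tpl <- ied_template(sf, params$ied_snr * ch_sd[ch[1]], slow_wave = FALSE)
      for (pk in peaks) {
        sig <- add_wave(sig, ch, round(pk * sf), tpl$wave, tpl$peak, gains)
      }
    } else if (type == "spindle") {
      slen <- round(ev$duration[r] * sf)
      tt <- seq_len(slen) / sf
      phase <- runif(1, 0, 2 * pi)
      env <- tukey_window(slen)
      i0 <- round(ev$onset[r] * sf) + 1
      idx <- i0 + seq_len(slen) - 1
      idx <- idx[idx <= ncol(sig)]
      for (j in seq_along(ch)) {
        w <- params$spindle_snr * band_sd_spindle[ch[j]] *
          sin(2 * pi * ev$freq_hz[r] * tt + phase) * env
        sig[ch[j], idx] <- sig[ch[j], idx] + w[seq_along(idx)] * gains[j]
      }
    }
  }
  new_recording(sig, sf, chans, montage = rec$montage)
}

#' Inject ground-truth events into a background recording
#'
#' Draws event times (seed offset +1) and renders the waveforms (seed offset
#' +2), so the returned ground truth matches [draw_ground_truth()] exactly.
#'
#' @param rec background `eeg_recording` from [generate_background()].
#' @param params the same `synth_params` used for the background.
#' @param hyp optional `hypnogram`; generated from `params` if missing.
#' @return list with `recording` (events rendered in), `events` (ground
#'   truth) and `hypnogram`.
#' @export
inject_events <- function(rec, params, hyp = NULL) {
  validate_synth_params(params)
  truth <- draw_ground_truth(params, hyp)
  rec2 <- withr::with_seed(params$seed + 2L,
                           render_events_impl(rec, params, truth$events))
  list(recording = rec2, events = truth$events, hypnogram = truth$hypnogram)
}

#' Simulate one complete synthetic recording
#'
#' Convenience wrapper: background plus injected events.
#'
#' @inheritParams inject_events
#' @return as [inject_events()].
#' @export
simulate_recording <- function(params, hyp = NULL) {
  inject_events(generate_background(params), params, hyp)
}

#' Generate a paired pre/post synthetic cohort
#'
#' Each subject gets a baseline and a post-treatment recording. Between- and
#' within-subject heterogeneity is multiplicative log-normal on the event
#' rates: a shared per-subject factor (`sdlog = between_sd`) models the wide
#' burden spread across patients, and an independent per-arm factor
#' (`sdlog = within_sd`) models occasion-to-occasion variability -- applied
#' to both arms so a null cohort (`post` rates equal to `pre`) has exactly
#' exchangeable arms. The treatment effect is carried entirely by the
#' `pre`/`post` rate presets.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param pre,post `synth_params` for the two arms; defaults are the
#'   calibrated baseline/post presets.
#' @param seed cohort seed (also drives per-subject seeds).
#' @param signals render full signals (`TRUE`) or ground-truth events and
#'   hypnograms only (`FALSE`, much faster; sufficient for burden/rate
#'   statistics computed from event times).
#' @param between_sd,within_sd log-normal sdlog for IED/burst rate factors.
#' @param spindle_between_sd,spindle_within_sd same for spindle rates.
#' @param burden_cap_percent nominal per-subject burden is capped here to
#'   keep rejection sampling feasible.
#' @return object of class `paired_cohort`: list of subjects, each with
#'   `pre`/`post` elements (`recording` or `NULL`, `hypnogram`, `events`).
#' @export
generate_paired_cohort <- function(n_subjects, pre = synth_params("baseline"),
                                   post = synth_params("post"), seed = 1L,
                                   signals = TRUE,
                                   between_sd = 1.0, within_sd = 0.35,
                                   spindle_between_sd = 0.5,
                                   spindle_within_sd = 0.2,
                                   burden_cap_percent = 35) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  validate_synth_params(pre)
  validate_synth_params(post)
  seed <- as.integer(seed)
  fac <- withr::with_seed(derive_seed(seed, 999983), {
    list(rate = rlnorm(n_subjects, 0, between_sd),
         arm = matrix(rlnorm(2 * n_subjects, 0, within_sd), ncol = 2),
         spin = rlnorm(n_subjects, 0, spindle_between_sd),
         spin_arm = matrix(rlnorm(2 * n_subjects, 0, spindle_within_sd),
                           ncol = 2))
  })
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    arms <- list(pre = pre, post = post)
    out <- list()
    for (a in c(1, 2)) {
      p <- arms[[a]]
      cap <- burden_cap_percent / max(nominal_burden_percent(p), 1e-9)
      f <- min(fac$rate[i] * fac$arm[i, a], cap)
      p$ied_rate <- p$ied_rate * f
      p$burst_rate <- p$burst_rate * f
      p$spindle_rate_n2 <- p$spindle_rate_n2 * fac$spin[i] * fac$spin_arm[i, a]
      p$seed <- derive_seed(seed, 2L * i + (a - 1L))
      if (signals) {
        sim <- simulate_recording(p)
        out[[a]] <- list(recording = sim$recording, hypnogram = sim$hypnogram,
                         events = sim$events, params = p)
      } else {
        truth <- draw_ground_truth(p)
        out[[a]] <- list(recording = NULL, hypnogram = truth$hypnogram,
                         events = truth$events, params = p)
      }
    }
    subjects[[i]] <- list(id = sprintf("S%02d", i), pre = out[[1]],
                          post = out[[2]])
  }
  structure(list(subjects = subjects, pre_params = pre, post_params = post,
                 seed = seed),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("<paired_cohort> ", length(x$subjects), " subjects, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}
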