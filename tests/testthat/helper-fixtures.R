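# shared fixture: 300-s background with N2 = [120, 240) and three injected
# oscillations on Cz: a 1-s spindle (detectable), a 0.3-s burst (too short)
# and a 4-s constant-amplitude oscillation (too long)
make_spindle_fixture <- function(seed = 31) {
  p <- synth_params(duration = 300, ied_rate = 0, burst_rate = 0,
                    spindle_rate_n2 = 0, seed = seed)
  rec <- generate_background(p)
  hyp <- generate_hypnogram(p)
  sf <- rec$sfreq
  i_cz <- match("Cz", rec$channels)
  amp <- 8 * sd(iedburden:::fft_bandpass(rec$signal[i_cz, ], sf, 10, 16))
  add_osc <- function(rec, t0, dur, f, taper = TRUE) {
    n <- round(dur * sf)
    tt <- seq_len(n) / sf
    env <- if (taper) iedburden:::hann_window(n) else 1
    idx <- round(t0 * sf) + seq_len(n)
    rec$signal[i_cz, idx] <- rec$signal[i_cz, idx] +
      amp * sin(2 * pi * f * tt) * env
    rec
  }
  rec <- add_osc(rec, 150, 1, 13)
  rec <- add_osc(rec, 170, 0.3, 13)
  rec <- add_osc(rec, 190, 4, 13, taper = FALSE)
  list(rec = rec, hyp = hyp)
}
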