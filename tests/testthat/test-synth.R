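test_that("background generation is deterministic, named and 1/f-shaped", {
  p <- synth_params(duration = 60, seed = 1, background_exponent = 1)
  r1 <- generate_background(p)
  r2 <- generate_background(p)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$channels, CHANNELS_1020)
  expect_equal(ncol(r1$signal), 60 * 256)

  # log-log PSD slope ~ -1 for background_exponent = 1 (fit 2-40 Hz on a
  # channel without the alpha component)
  ps <- welch_psd(r1$signal["Fp1", ], p$sampling_rate)
  sel <- ps$freq >= 2 & ps$freq <= 40
  slope <- unname(coef(lm(log(ps$psd[sel]) ~ log(ps$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.35)

  expect_error(synth_params(duration = -5), "duration")
  expect_error(synth_params(spindle_freq = 9), "spindle_freq")
  expect_error(synth_params(ied_rate = -1), "rates")
})

test_that("event injection: zero rates, seeded replay, bands, containment", {
  p0 <- synth_params(duration = 120, ied_rate = 0, burst_rate = 0,
                     spindle_rate_n2 = 0, seed = 4)
  truth0 <- draw_ground_truth(p0)
  expect_equal(nrow(truth0$events), 0)

  p <- synth_params(duration = 600, ied_rate = 6, burst_rate = 0.3,
                    seed = 7)
  truth <- draw_ground_truth(p)
  ev <- truth$events

  # replay oracle: documented draw order, first draw = IED count
  n_ied_replay <- withr::with_seed(p$seed + 1L, rpois(1, 6 * 10))
  expect_equal(sum(ev$type == "IED"), n_ied_replay)

  # all events inside the recording, spindles confined to N2
  expect_true(all(ev$onset >= 0 & ev$onset + ev$duration <= p$duration))
  sp <- ev[ev$type == "spindle", ]
  n2 <- stage_intervals(truth$hypnogram, "N2")
  for (k in seq_len(nrow(sp))) {
    expect_true(any(sp$onset[k] >= n2[, 1] &
                      sp$onset[k] + sp$duration[k] <= n2[, 2]))
  }
  expect_true(all(sp$freq_hz >= 10 & sp$freq_hz <= 16))
  expect_true(all(sp$duration >= 0.5 & sp$duration <= 3))
  # a 13-Hz spindle is fast-band by the 12-16 Hz definition
  expect_identical(classify_spindle(13), "fast")

  # ground-truth burden equals the event-time arithmetic exactly
  br <- compute_burden(ev, p$duration)
  manual <- 100 * (IED_DURATION_S * sum(ev$type == "IED") +
                     sum(ev$duration[ev$type == "burst"])) / p$duration
  expect_equal(br$burden_percent, manual, tolerance = 1e-12)

  # rendering leaves the ground truth unchanged (seed separation)
  sim <- simulate_recording(p)
  expect_identical(sim$events, truth$events)
})

test_that("hypnogram synthesis: blocks, collapse, coverage", {
  p <- synth_params(duration = 900)
  hyp <- generate_hypnogram(p)
  expect_gte(length(hyp$stages) * hyp$epoch_length, 900)
  expect_identical(unique(hyp$stages), c("W", "N1", "N2", "N3"))
  pc <- synth_params(duration = 900, collapse_nrem = TRUE)
  expect_identical(sort(unique(generate_hypnogram(pc)$stages)),
                   c("NREM", "W"))
})

test_that("paired cohorts: structure, determinism, null symmetry", {
  pre <- synth_params("baseline", duration = 600)
  cohort <- generate_paired_cohort(6, pre = pre, seed = 3, signals = FALSE)
  expect_length(cohort$subjects, 6)
  for (su in cohort$subjects) {
    n2 <- stage_seconds(su$pre$hypnogram)[["N2"]]
    expect_gte(n2, 60)   # spindle analysis needs >= 1 min of N2
  }
  cohort2 <- generate_paired_cohort(6, pre = pre, seed = 3, signals = FALSE)
  expect_identical(cohort$subjects[[1]]$pre$events,
                   cohort2$subjects[[1]]$pre$events)

  # null effect: pre == post parameters => median paired difference near 0
  null_c <- generate_paired_cohort(40, pre = pre, post = pre, seed = 11,
                                   signals = FALSE)
  m <- cohort_metrics(null_c)
  expect_lt(abs(median(m$burden_post - m$burden_pre)),
            0.2 * median(m$burden_pre))
})
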