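
test_that("detection finds the 1-s spindle and applies the duration gates", {
  fx <- make_spindle_fixture()
  det <- detect_spindles(fx$rec, fx$hyp)
  cz <- det[det$channels == "Cz", ]
  covers <- cz$onset < 151 & cz$onset + cz$duration > 150.2
  expect_equal(sum(covers), 1)
  expect_lt(abs(cz$freq_hz[covers] - 13), 0.3)
  # 0.3-s burst (below min_dur) and 4-s oscillation (above max_dur) rejected
  expect_false(any(cz$onset > 169 & cz$onset < 171))
  expect_false(any(cz$onset + cz$duration > 190.5 & cz$onset < 193.5))
  expect_true(all(det$duration >= 0.5 & det$duration <= 3))
})

test_that("detection is scale-invariant and bit-stable", {
  fx <- make_spindle_fixture()
  det1 <- detect_spindles(fx$rec, fx$hyp)
  det1b <- detect_spindles(fx$rec, fx$hyp)
  expect_identical(det1, det1b)
  scaled <- new_recording(fx$rec$signal * 3.7, fx$rec$sfreq,
                          fx$rec$channels)
  det2 <- detect_spindles(scaled, fx$hyp)
  expect_equal(det1$onset, det2$onset)
  expect_equal(det1$duration, det2$duration)
  expect_equal(det1$freq_hz, det2$freq_hz)
})

test_that("no-N2 recordings are skipped explicitly", {
  fx <- make_spindle_fixture()
  det <- detect_spindles(fx$rec, hyp_of(W = 10))
  expect_equal(nrow(det), 0)
  expect_identical(attr(det, "status"), "skipped_no_n2")
  bip <- to_montage(fx$rec, "bipolar")
  expect_error(detect_spindles(bip, fx$hyp), "montage")
})

test_that("fast/slow classification and frequency estimation", {
  expect_identical(classify_spindle(c(13, 11, 12)),
                   c("fast", "slow", "fast"))
  fx <- make_spindle_fixture()
  ev <- event_set(onset = 150, duration = 1, type = "spindle",
                  channels = "Cz")
  expect_lt(abs(spindle_frequency(fx$rec, ev) - 13), 0.3)
})

test_that("IED-overlapping detections are excluded", {
  sp <- event_set(onset = 10, duration = 1, type = "spindle",
                  channels = "Cz", source = "detected", score = 1,
                  freq_hz = 13)
  hit <- event_set(onset = 10.5 - IED_DURATION_S / 2,
                   duration = IED_DURATION_S, type = "IED")
  expect_equal(nrow(exclude_ied_overlap(sp, hit)), 0)
  far <- event_set(onset = 12 - IED_DURATION_S / 2,
                   duration = IED_DURATION_S, type = "IED")
  expect_equal(nrow(exclude_ied_overlap(sp, far)), 1)
  expect_identical(exclude_ied_overlap(sp, event_set()), sp)
})

test_that("rates: arithmetic, eligibility, cross-channel merging", {
  hyp10 <- hyp_of(N2 = 20)                       # 10 min of N2
  freqs <- c(rep(13, 12), rep(11, 3))
  ev <- event_set(onset = seq(5, 580, length.out = 15), duration = 1,
                  type = "spindle", channels = "Cz", source = "detected",
                  score = 1, freq_hz = freqs)
  rep10 <- spindle_rates(ev, hyp10)
  expect_true(rep10$eligible)
  expect_equal(rep10$rate_all, 1.5)
  expect_equal(rep10$rate_fast, 1.2)
  expect_equal(rep10$rate_slow, 0.3)
  expect_equal(rep10$rate_all, rep10$rate_fast + rep10$rate_slow)

  # 50 s of N2 is below the 1-min eligibility rule
  short <- spindle_rates(ev, hypnogram(c("N2", "N2"), epoch_length = 25))
  expect_false(short$eligible)
  expect_true(is.na(short$rate_all))

  # no detections but enough N2: all rates zero
  none <- spindle_rates(event_set(), hyp10)
  expect_equal(none$rate_all, 0)

  # same spindle seen on two channels within 0.5 s counts once
  two <- event_set(onset = c(100, 100.2), duration = 1, type = "spindle",
                   channels = c("C3", "C4"), source = "detected",
                   score = 1, freq_hz = 13)
  expect_equal(spindle_rates(two, hyp10)$rate_all, 0.1)
})
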