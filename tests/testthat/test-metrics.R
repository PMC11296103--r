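test_that("common-state selection prefers sleep and max-min duration", {
  # sleep beats wake regardless of duration
  expect_identical(select_common_state(hyp_of(W = 20, N2 = 16),
                                       hyp_of(W = 4, N2 = 18)), "N2")
  # wake-only recordings fall back to W
  expect_identical(select_common_state(hyp_of(W = 5), hyp_of(W = 9)), "W")
  # max-min among sleep states: N1 {5,4} min beats N2 {1,6} min
  expect_identical(select_common_state(hyp_of(N1 = 10, N2 = 2),
                                       hyp_of(N1 = 8, N2 = 12)), "N1")
  expect_error(select_common_state(hyp_of(W = 3), hyp_of(N2 = 3)),
               "common")
})

test_that("burden arithmetic matches the printed examples", {
  ev <- event_set(onset = seq(1, 56, by = 5)[1:12], duration = IED_DURATION_S,
                  type = "IED")
  expect_equal(compute_burden(ev, 60)$burden_percent, 5.0)
  expect_equal(compute_burden(event_set(), 60)$burden_percent, 0)
  mix <- event_set(onset = c(1, 3, 8), duration = c(0.25, 0.25, 3.5),
                   type = c("IED", "IED", "burst"))
  expect_equal(compute_burden(mix, 20)$burden_percent, 20.0)
  expect_error(compute_burden(ev, 0), "total_duration")
})

test_that("burden properties: union, ordering, splitting, monotonicity", {
  withr::with_seed(14, {
    for (rep in 1:20) {
      n <- sample(3:25, 1)
      type <- sample(c("IED", "burst"), n, replace = TRUE)
      ev <- event_set(onset = runif(n, 0, 50),
                      duration = ifelse(type == "IED", IED_DURATION_S,
                                        runif(n, 0.5, 6)),
                      type = type)
      got <- compute_burden(ev, 60)$burden_percent
      want <- 100 * union_length_oracle(iedburden:::event_spans(ev)) / 60
      expect_equal(got, want, tolerance = 1e-12)

      # order invariance
      perm <- iedburden:::filter_events(ev, sample(nrow(ev)))
      expect_equal(compute_burden(perm, 60)$burden_percent, got)

      # adding an event never decreases burden
      more <- iedburden:::bind_events(
        ev, event_set(onset = runif(1, 0, 55), duration = 1, type = "burst"))
      expect_gte(compute_burden(more, 60)$burden_percent, got - 1e-12)
    }
  })

  # splitting a burst into contiguous sub-bursts changes nothing
  whole <- event_set(onset = 5, duration = 4, type = "burst")
  halves <- event_set(onset = c(5, 7), duration = c(2, 2), type = "burst")
  expect_equal(compute_burden(whole, 30)$burden_percent,
               compute_burden(halves, 30)$burden_percent)

  # burden of disjoint segments = duration-weighted mean of segment burdens
  seg1 <- event_set(onset = c(2, 9), duration = c(1, 2), type = "burst")
  seg2 <- event_set(onset = 25, duration = 3, type = "burst")
  b1 <- compute_burden(seg1, 20)$burden_percent
  b2 <- compute_burden(seg2, 40)$burden_percent
  all_ev <- iedburden:::bind_events(seg1, seg2)
  expect_equal(compute_burden(all_ev, 60)$burden_percent,
               (20 * b1 + 40 * b2) / 60)
})

test_that("channel involvement summarises with the 95th percentile", {
  one <- event_set(onset = 1:5, duration = IED_DURATION_S, type = "IED",
                   channels = "Cz")
  expect_equal(channel_involvement(one)$p95, 1)

  counts <- 1:20
  ev <- event_set(onset = seq(1, 100, length.out = 20),
                  duration = IED_DURATION_S, type = "IED",
                  channels = vapply(counts, function(k) {
                    paste(CHANNELS_1020[seq_len(k)], collapse = ";")
                  }, character(1)))
  got <- channel_involvement(ev)
  expect_equal(got$per_event, counts)
  # sort-based linear-interpolation oracle: h = (n-1)p + 1
  h <- (20 - 1) * 0.95 + 1
  oracle <- counts[floor(h)] + (h - floor(h)) * (counts[ceiling(h)] -
                                                   counts[floor(h)])
  expect_equal(got$p95, oracle)

  expect_true(is.na(channel_involvement(event_set())$p95))
})

test_that("gamma precursor proportion recovers the injected fraction", {
  p0 <- synth_params(duration = 150, ied_rate = 6, burst_rate = 0,
                     spindle_rate_n2 = 0, gamma_precursor_fraction = 0,
                     gamma_snr = 6, seed = 19)
  sim0 <- simulate_recording(p0)
  g0 <- gamma_proportion(sim0$recording, sim0$events)
  expect_lt(g0, 15)                      # null case, small FP allowance

  p5 <- synth_params(duration = 150, ied_rate = 6, burst_rate = 0,
                     spindle_rate_n2 = 0, gamma_precursor_fraction = 0.5,
                     gamma_snr = 6, seed = 20)
  sim5 <- simulate_recording(p5)
  truth_frac <- mean(sim5$events$gamma[sim5$events$type == "IED"])
  g5 <- gamma_proportion(sim5$recording, sim5$events)
  expect_lt(abs(g5 / 100 - truth_frac), 0.25)
  expect_gt(g5, g0)

  expect_warning(out <- gamma_proportion(sim0$recording, event_set()),
                 "no IEDs")
  expect_true(is.na(out))
  lowfs <- new_recording(matrix(0, 19, 100,
                                dimnames = list(CHANNELS_1020, NULL)),
                         100, CHANNELS_1020)
  expect_error(gamma_proportion(lowfs, sim0$events), "sampling rate")
})

test_that("percent change follows the median arithmetic", {
  expect_equal(percent_change(5.4, 1.5), 100 * (1.5 - 5.4) / 5.4)
  expect_equal(round(percent_change(5.4, 1.5), 1), -72.2)
  expect_equal(percent_change(2, 2), 0)
  expect_warning(out <- percent_change(0, 3), "undefined")
  expect_true(is.na(out))
})
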