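# mock prediction object: single channel, 125-ms hop over `duration` s;
# windows overlapping each listed event time get the given score
mock_pred <- function(duration, times = numeric(), scores = numeric(),
                      base = 0.01) {
  start_s <- seq(0, duration - 0.5, by = 0.125)
  global <- rep(base, length(start_s))
  for (k in seq_along(times)) {
    on <- times[k]
    idx <- which(start_s < on + 0.25 & start_s + 0.5 > on)
    global[idx] <- pmax(global[idx], scores[k])
  }
  structure(list(start_s = start_s, window_s = 0.5, hop_s = 0.125,
                 global = global, channel = matrix(global, nrow = 1),
                 channels = "Cz", rec_id = NULL, fold = "__all__",
                 duration = duration),
            class = "ied_prediction")
}

test_that("DTW distance matches a full-table oracle and is a pseudometric", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      x <- rnorm(20); y <- rnorm(25)
      expect_equal(iedburden:::dtw_distance(x, y), dtw_oracle(x, y))
      expect_equal(iedburden:::dtw_distance(x, y),
                   iedburden:::dtw_distance(y, x))
      expect_equal(iedburden:::dtw_distance(x, x), 0)
    }
  })
  # banded distance never undercuts the unconstrained one
  x <- cumsum(rnorm(40)); y <- cumsum(rnorm(40))
  expect_gte(iedburden:::dtw_distance(x, y, band = 4), dtw_oracle(x, y) - 1e-9)
})

test_that("channel-level annotation extraction labels the event channels", {
  sf <- 256
  withr::with_seed(8, {
    sig <- matrix(rnorm(19 * 2 * sf), nrow = 19)
  })
  rownames(sig) <- CHANNELS_1020
  bump <- 60 * exp(-(seq(-0.05, 0.05, by = 1 / sf))^2 / (2 * 0.008^2))
  hot <- c("F3", "C3", "Cz")
  idx <- round(1 * sf) + seq_along(bump) - round(length(bump) / 2)
  for (ch in hot) sig[ch, idx] <- sig[ch, idx] + bump
  rec <- new_recording(sig, sf, CHANNELS_1020)
  ev <- event_set(onset = 1 - IED_DURATION_S / 2, duration = IED_DURATION_S,
                  type = "IED")
  ext <- extract_channel_annotations(rec, ev)
  expect_identical(sort(ext$meta$channel[ext$meta$label == 1]), sort(hot))

  # identical waveform everywhere: no separation possible -> all positive
  same <- new_recording(matrix(rep(sig[1, ], 19), nrow = 19, byrow = TRUE),
                        sf, CHANNELS_1020)
  ext2 <- extract_channel_annotations(same, ev)
  expect_true(all(ext2$meta$label == 1))
})

test_that("training enforces annotation minimums and is deterministic", {
  ts <- iedburden:::build_training_set(2, seed = 21, duration = 60)
  m1 <- train_detector(ts$recordings, ts$annotations, seed = 21)
  m2 <- train_detector(ts$recordings, ts$annotations, seed = 21)
  expect_identical(m1$folds[["R01"]]$beta, m2$folds[["R01"]]$beta)

  thin <- ts$annotations
  thin[["R01"]] <- iedburden:::filter_events(
    thin[["R01"]], !duplicated(thin[["R01"]]$type))    # 1 IED only
  expect_error(train_detector(ts$recordings, thin), "R01")

  # prediction: global score is the channel-wise maximum; LOPO is enforced
  pred <- predict_global(m1, ts$recordings[["R01"]], rec_id = "R01")
  expect_equal(pred$global, apply(pred$channel, 2, max))
  expect_identical(pred$fold, "R01")
  expect_error(predict_global(m1, ts$recordings[["R01"]], rec_id = "R01",
                              fold = "R02"), "LOPO")
})

test_that("flat input scores near-constant and low; IED-free FP rate is bounded", {
  ts <- iedburden:::build_training_set(3, seed = 55, duration = 90)
  model <- train_detector(ts$recordings, ts$annotations, seed = 55)
  flat <- new_recording(matrix(0, 19, 10 * 256,
                               dimnames = list(CHANNELS_1020, NULL)),
                        256, CHANNELS_1020)
  pf <- predict_global(model, flat)
  expect_lt(sd(pf$global), 1e-6)
  expect_lt(mean(pf$global), 0.5)

  # calibrate on one recording, apply its threshold to an event-free one
  pred1 <- predict_global(model, ts$recordings[["R01"]], rec_id = "R01")
  thr <- calibrate_threshold(pred1, ts$annotations[["R01"]], model$params)
  quiet <- simulate_recording(synth_params(duration = 120, ied_rate = 0,
                                           burst_rate = 0,
                                           spindle_rate_n2 = 0, seed = 91))
  predq <- predict_global(model, quiet$recording)
  fp <- nrow(detect_ieds(pred = predq, threshold = thr)) / 2   # per minute
  expect_lte(fp, 2)        # config bound; the real-data 0.24/min is a
                           # reference figure, not an acceptance value
})

test_that("window arithmetic: 10 s at 125-ms hop gives 77 windows", {
  clf <- list(beta = rep(0, 12), center = rep(0, 11), scale = rep(1, 11),
              train_ids = character(0))
  model <- structure(list(classifier = "logistic",
                          folds = list("__all__" = clf),
                          manifest = data.frame(recording = character(0)),
                          params = detection_params(), window_samples = 128,
                          sfreq = 256, thresholds = numeric(0)),
                     class = "ied_detector")
  rec <- new_recording(matrix(rnorm(2 * 2560), nrow = 2,
                              dimnames = list(c("Cz", "Pz"), NULL)), 256,
                       c("Cz", "Pz"))
  pred <- predict_global(model, rec)
  expect_length(pred$global, 77)
  expect_equal(pred$start_s[2] - pred$start_s[1], 0.125)
})

test_that("threshold calibration honors the order statistics and the floor", {
  times <- seq(3, 57, by = 6)[1:10]
  scores <- c(rep(0.9, 8), rep(0.6, 2))
  pred <- mock_pred(60, times, scores)
  ann <- event_set(onset = times - IED_DURATION_S / 2,
                   duration = IED_DURATION_S, type = "IED")
  ann <- iedburden:::bind_events(
    ann, event_set(onset = 58, duration = 12, type = "background"))

  thr <- calibrate_threshold(pred, ann)
  expect_lte(thr, 0.9)
  expect_gte(detection_sensitivity(pred, ann, thr), 0.75)

  # floor = 1 forces the threshold down to the weakest annotated IED
  p1 <- detection_params(min_calibration_sensitivity = 1)
  thr1 <- calibrate_threshold(pred, ann, p1)
  expect_lte(thr1, 0.6)
  expect_equal(detection_sensitivity(pred, ann, thr1), 1)

  # randomized sweep against an exhaustive threshold oracle
  withr::with_seed(33, {
    for (rep in 1:25) {
      s <- round(runif(20, 0.2, 1), 3)
      t20 <- seq(1.5, 58, length.out = 20)
      pr <- mock_pred(60, t20, s)
      an <- iedburden:::bind_events(
        event_set(onset = t20 - IED_DURATION_S / 2,
                  duration = IED_DURATION_S, type = "IED"),
        event_set(onset = 59, duration = 12, type = "background"))
      got <- calibrate_threshold(pr, an)
      sens <- function(t) mean(s >= t)
      oracle <- max(s[vapply(s, function(t) sens(t) >= 0.75, logical(1))])
      expect_gte(sens(got), 0.75)
      expect_lte(got, oracle + 1e-9)
    }
  })
})

test_that("event extraction merges runs and attributes channels", {
  # 4 consecutive supra-threshold windows -> one merged event
  pred <- mock_pred(20, times = 5, scores = 0.9)
  ev <- detect_ieds(pred = pred, threshold = 0.5)
  expect_equal(nrow(ev), 1)
  expect_lt(abs((ev$onset[1] + IED_DURATION_S / 2) - 5.1), 0.3)

  # two runs separated by 2 s stay distinct
  pred2 <- mock_pred(20, times = c(5, 7), scores = c(0.9, 0.8))
  expect_equal(nrow(detect_ieds(pred = pred2, threshold = 0.5)), 2)

  # monotonicity of counts over a threshold grid on spike-like bumps
  pred3 <- mock_pred(60, times = seq(2, 58, by = 4),
                     scores = withr::with_seed(2, runif(15, 0.3, 1)))
  counts <- vapply(seq(0.05, 0.99, by = 0.02), function(t) {
    nrow(detect_ieds(pred = pred3, threshold = t))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  expect_equal(nrow(detect_ieds(pred = pred, threshold = 0.95)), 0)
})
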