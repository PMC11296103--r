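# Reproducible benchmark runners on fully synthetic data.  These back both
# the acceptance tests and scripts/acceptance.R, so the reported operating
# characteristics are always recomputed from scratch by the same code path
# a user would run.

#' Derive a manual annotation set from ground truth
#'
#' Emulates the marking protocol: up to `n_ieds` injected IEDs are "marked"
#' (taken in onset order) and event-free 1-s background segments are
#' annotated until `background_s` seconds are collected.
#'
#' @param sim result of [simulate_recording()].
#' @param n_ieds maximum number of IEDs to mark.
#' @param background_s seconds of background to mark.
#' @return an `event_set` with IED and background rows.
#' @export
annotate_from_truth <- function(sim, n_ieds = 15, background_s = 12) {
  ev <- sim$events
  ieds <- filter_events(ev, ev$type == "IED")
  ieds <- filter_events(ieds, seq_len(nrow(ieds)) <= n_ieds)
  spans <- event_spans(ev)
  dur <- recording_duration(sim$recording)
  grid <- seq(0.5, dur - 1.5, by = 1)
  free <- grid[vapply(grid, function(s) {
    !overlaps_any(s, s + 1, spans, margin = 0.3)
  }, logical(1))]
  free <- head(free, ceiling(background_s))
  if (length(free) * 1 < background_s) {
    stop("not enough event-free time to annotate background", call. = FALSE)
  }
  event_set(
    onset = c(ieds$onset, free),
    duration = c(ieds$duration, rep(1, length(free))),
    type = c(rep("IED", nrow(ieds)), rep("background", length(free))),
    channels = c(ieds$channels, rep("", length(free))),
    source = "manual"
  )
}

# shared builder: n annotated synthetic recordings for detector work
build_training_set <- function(n_recordings, seed, duration = 120,
                               ied_rate = 8, burst_rate = 0.2,
                               ied_snr = 6) {
  recordings <- list()
  annotations <- list()
  truths <- list()
  for (r in seq_len(n_recordings)) {
    p <- synth_params(duration = duration, ied_rate = ied_rate,
                      burst_rate = burst_rate, spindle_rate_n2 = 0,
                      gamma_precursor_fraction = 0, ied_snr = ied_snr,
                      seed = derive_seed(seed, r))
    sim <- simulate_recording(p)
    tries <- 0
    while (sum(sim$events$type == "IED") < 10 && tries < 5) {
      p$seed <- derive_seed(p$seed, 777)
      sim <- simulate_recording(p)
      tries <- tries + 1
    }
    if (sum(sim$events$type == "IED") < 10) {
      stop("could not draw >= 10 IEDs for a benchmark recording")
    }
    id <- sprintf("R%02d", r)
    recordings[[id]] <- sim$recording
    annotations[[id]] <- annotate_from_truth(sim)
    truths[[id]] <- sim
  }
  list(recordings = recordings, annotations = annotations, truths = truths)
}

#' Threshold-calibration benchmark (sensitivity floor)
#'
#' Generates seeded synthetic recordings each carrying >= 10 annotated IEDs
#' and >= 10 s annotated background, trains the window classifier under
#' LOPO folds, calibrates the per-recording threshold on each held-out
#' recording, and recomputes the sensitivity of the returned threshold on
#' that recording's annotated IED set.
#'
#' @param n_recordings number of recordings (>= 20 for the protocol check).
#' @param seed integer seed.
#' @param duration per-recording duration, seconds.
#' @return list with `sensitivities` (per recording, fractions),
#'   `min_sensitivity_percent`, `thresholds`, `n`.
#' @export
run_calibration_benchmark <- function(n_recordings = 20, seed = 1,
                                      duration = 120) {
  ts <- build_training_set(n_recordings, seed, duration = duration)
  model <- train_detector(ts$recordings, ts$annotations, seed = seed)
  ids <- names(ts$recordings)
  sens <- setNames(numeric(length(ids)), ids)
  thr <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    pred <- predict_global(model, ts$recordings[[id]], rec_id = id)
    thr[id] <- calibrate_threshold(pred, ts$annotations[[id]], model$params)
    sens[id] <- detection_sensitivity(pred, ts$annotations[[id]], thr[id])
  }
  list(sensitivities = sens, thresholds = thr,
       min_sensitivity_percent = 100 * min(sens), n = length(ids))
}

#' Held-out window-classification AUC benchmark
#'
#' Pooled AUC over annotated windows, each recording scored by its own
#' held-out LOPO fold. With `shuffle = TRUE` the training labels are
#' permuted and the held-out scores are evaluated against the permuted
#' labels -- the standard permutation control, whose AUC concentrates at
#' chance. (Evaluating a shuffle-trained model against the *true* labels
#' is bimodal around chance: a no-signal fit still aligns, with arbitrary
#' sign, to the dominant feature direction.)
#'
#' @param n_recordings,seed,duration as in [run_calibration_benchmark()].
#' @param shuffle permute training labels.
#' @param ied_snr IED amplitude in background-SD units (raise for the
#'   high-SNR operating point).
#' @return list with `auc`, `n_windows`.
#' @export
run_detector_benchmark <- function(n_recordings = 8, seed = 1,
                                   duration = 120, shuffle = FALSE,
                                   ied_snr = 8) {
  ts <- build_training_set(n_recordings, seed, duration = duration,
                           ied_snr = ied_snr)
  model <- train_detector(ts$recordings, ts$annotations, seed = seed,
                          shuffle_labels = shuffle, keep_design = TRUE)
  d <- model$design
  scores <- numeric(length(d$y))
  for (id in names(ts$recordings)) {
    sel <- d$rec == id
    scores[sel] <- score_logistic(model$folds[[id]],
                                  d$X[sel, , drop = FALSE])
  }
  list(auc = auc_score(scores, d$y), n_windows = length(d$y))
}

#' Spindle detection benchmark against injected ground truth
#'
#' IED-free synthetic recording with injected spindles at the default SNR;
#' reports recall and precision of merged detections against ground truth
#' plus fast/slow classification accuracy for spindles at least 1 Hz from
#' the 12-Hz boundary.
#'
#' @param seed integer seed.
#' @param duration recording duration, seconds.
#' @param spindle_rate injected spindles per minute of N2.
#' @return list with `recall`, `precision`, `class_accuracy`, `n_truth`,
#'   `n_detected`.
#' @export
run_spindle_benchmark <- function(seed = 1, duration = 1200,
                                  spindle_rate = 4) {
  p <- synth_params(duration = duration, ied_rate = 0, burst_rate = 0,
                    spindle_rate_n2 = spindle_rate,
                    gamma_precursor_fraction = 0, seed = derive_seed(seed, 0))
  sim <- simulate_recording(p)
  sp <- spindle_params()
  det <- detect_spindles(sim$recording, sim$hypnogram, sp)
  det <- exclude_ied_overlap(det, sim$events)
  merged <- merge_spindles(det, sp$merge_window)
  truth <- filter_events(sim$events, sim$events$type == "spindle")
  t_span <- event_spans(truth)
  d_span <- event_spans(merged)
  overlap_any <- function(a, B) {
    nrow(B) > 0 && any(a[1] < B[, 2] & B[, 1] < a[2])
  }
  recall <- if (nrow(truth)) {
    mean(vapply(seq_len(nrow(truth)), function(k) {
      overlap_any(t_span[k, ], d_span)
    }, logical(1)))
  } else NA_real_
  precision <- if (nrow(merged)) {
    mean(vapply(seq_len(nrow(merged)), function(k) {
      overlap_any(d_span[k, ], t_span)
    }, logical(1)))
  } else NA_real_
  # band classification, matched pairs with truth >= 1 Hz off the boundary
  acc <- NA_real_
  if (nrow(merged) && nrow(truth)) {
    hits <- list()
    for (k in seq_len(nrow(merged))) {
      j <- which(t_span[, 1] < d_span[k, 2] & d_span[k, 1] < t_span[, 2])
      if (length(j)) hits[[length(hits) + 1]] <- c(k, j[1])
    }
    if (length(hits)) {
      hits <- do.call(rbind, hits)
      tf <- truth$freq_hz[hits[, 2]]
      off <- abs(tf - sp$fast_lo) >= 1
      if (any(off)) {
        acc <- mean(classify_spindle(merged$freq_hz[hits[, 1]], sp)[off] ==
                      classify_spindle(tf, sp)[off])
      }
    }
  }
  list(recall = recall, precision = precision, class_accuracy = acc,
       n_truth = nrow(truth), n_detected = nrow(merged))
}

#' Cohort-level power / type-I-error simulation
#'
#' Simulates paired cohorts from the calibrated generator (event times only;
#' burden and rates are functions of event times) and tests the burden
#' endpoint with the Wilcoxon signed-rank test. With `null = TRUE` the post
#' arm uses the baseline parameters, so rejections estimate the type-I
#' error.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param n_subjects subjects per cohort.
#' @param seed integer seed.
#' @param null simulate under the null (post == pre parameters).
#' @param duration per-recording duration, seconds.
#' @param alpha significance level.
#' @return list with `rejection_fraction`, `p_values`, `median_pre`,
#'   `median_post` (medians of the per-cohort median burdens).
#' @export
run_power_simulation <- function(n_cohorts = 100, n_subjects = 24, seed = 1,
                                 null = FALSE, duration = 1200,
                                 alpha = 0.05) {
  pre <- synth_params("baseline", duration = duration)
  post <- if (null) pre else synth_params("post", duration = duration)
  pv <- numeric(n_cohorts)
  med_pre <- numeric(n_cohorts)
  med_post <- numeric(n_cohorts)
  for (c in seq_len(n_cohorts)) {
    cohort <- generate_paired_cohort(n_subjects, pre, post,
                                     seed = derive_seed(seed, c),
                                     signals = FALSE)
    m <- cohort_metrics(cohort)
    w <- wilcoxon_signed_rank(m$burden_pre, m$burden_post)
    pv[c] <- w$p_value
    med_pre[c] <- median(m$burden_pre)
    med_post[c] <- median(m$burden_post)
  }
  list(rejection_fraction = mean(pv < alpha), p_values = pv,
       median_pre = median(med_pre), median_post = median(med_post))
}
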