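#' Fixed analysis duration of a point IED event (seconds)
#'
#' Every interictal epileptiform discharge is assigned a fixed 250-ms span for
#' burden computation and overlap logic; the stored onset is the start of the
#' span, which is centered on the spike peak.
#' @export
IED_DURATION_S <- 0.25

EVENT_TYPES <- c("IED", "burst", "spindle", "background")

#' Construct a typed, timed event set
#'
#' The central event container: a `data.frame` with one row per event and
#' columns `onset` (s, 0-based), `duration` (s, half-open span
#' `[onset, onset + duration)`), `type` (`IED`, `burst`, `spindle`, or
#' `background` for annotated background training segments), `channels`
#' (`;`-joined 10-20 labels, `""` for global events), `source` (`manual` or
#' `detected`), `score` (detector probability, `NA` for manual events) and
#' `freq_hz` (spindle frequency, `NA` otherwise).
#'
#' IED rows are forced to the fixed [IED_DURATION_S] span.
#'
#' @param onset,duration numeric vectors (seconds).
#' @param type character vector over the event vocabulary.
#' @param channels character vector of `;`-joined channel labels.
#' @param source `"manual"` or `"detected"`, recycled.
#' @param score,freq_hz numeric vectors, recycled; `NA` allowed.
#' @return `data.frame` of class `event_set`, sorted by onset.
#' @export
event_set <- function(onset = numeric(), duration = numeric(),
                      type = character(), channels = "",
                      source = "manual", score = NA_real_,
                      freq_hz = NA_real_) {
  n <- length(onset)
  ev <- data.frame(
    onset = as.numeric(onset),
    duration = as.numeric(rep_len(duration, n)),
    type = as.character(rep_len(type, max(n, 0))),
    channels = as.character(rep_len(channels, n)),
    source = as.character(rep_len(source, n)),
    score = as.numeric(rep_len(score, n)),
    freq_hz = as.numeric(rep_len(freq_hz, n)),
    stringsAsFactors = FALSE
  )
  if (n > 0) ev$duration[ev$type == "IED"] <- IED_DURATION_S
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_set", "data.frame")
  validate_event_set(ev)
  ev
}

validate_event_set <- function(ev) {
  if (nrow(ev) == 0) return(invisible(ev))
  bad <- which(!ev$type %in% EVENT_TYPES)
  if (length(bad)) {
    stop("event_set: unknown event type '", ev$type[bad[1]],
         "' in row ", bad[1], call. = FALSE)
  }
  if (any(ev$onset < 0)) stop("event_set: negative onset", call. = FALSE)
  span_types <- ev$type %in% c("burst", "spindle", "background")
  if (any(ev$duration[span_types] <= 0)) {
    stop("event_set: non-positive duration for a burst/spindle/background event",
         call. = FALSE)
  }
  det <- ev$source == "detected"
  if (any(det & is.nan(ev$score))) {
    stop("event_set: NaN score on a detected event", call. = FALSE)
  }
  invisible(ev)
}

empty_event_set <- function() event_set()

# [start, end) spans; IEDs already carry their fixed duration.
event_spans <- function(ev) {
  cbind(start = ev$onset, end = ev$onset + ev$duration)
}

# list of character vectors of channel labels
event_channels <- function(ev) {
  lapply(strsplit(ev$channels, ";", fixed = TRUE),
         function(x) x[nzchar(x)])
}

join_channels <- function(ch) paste(ch, collapse = ";")

EVENT_COLUMNS <- c("onset", "duration", "type", "channels", "source",
                   "score", "freq_hz")

# combine event sets on the standard columns (extra columns like the
# ground-truth gamma flag are dropped), re-sorted by onset
bind_events <- function(...) {
  parts <- lapply(list(...), function(x) as.data.frame(x)[EVENT_COLUMNS])
  out <- do.call(rbind, parts)
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_set", "data.frame")
  out
}

# subset rows, keeping the class
filter_events <- function(ev, keep) {
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_set", "data.frame")
  out
}

# events whose span midpoint lies inside any of the [start,end) intervals
restrict_events_to_intervals <- function(ev, intervals) {
  if (nrow(ev) == 0 || nrow(intervals) == 0) return(filter_events(ev, FALSE))
  mid <- ev$onset + ev$duration / 2
  keep <- vapply(mid, function(m) {
    any(m >= intervals[, 1] & m < intervals[, 2])
  }, logical(1))
  filter_events(ev, keep)
}

#' @export
print.event_set <- function(x, ...) {
  cat("<event_set> ", nrow(x), " events",
      if (nrow(x)) paste0(" (", paste(sprintf("%s: %d",
        names(table(x$type)), as.integer(table(x$type))), collapse = ", "), ")"),
      "\n", sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}
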