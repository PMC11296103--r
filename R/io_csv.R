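# CSV dialects for annotations and hypnograms.
#
# Annotations: comma-separated with header
#   recording_id,onset_s,duration_s,type,channels,source,score,freq_hz
# channels are `;`-joined 10-20 labels; `source`, `score`, `freq_hz` are
# optional on input (defaults: manual, NA, NA).  Times are 0-based seconds,
# spans half-open [onset, onset + duration).
#
# Hypnograms: comma-separated with header `epoch_index,stage`, 0-based
# consecutive epoch indices, stages in {W, N1, N2, N3, NREM}.

#' Write an event set to an annotations CSV
#'
#' @param events an `event_set`.
#' @param path output path.
#' @param recording_id identifier written on every row.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path, recording_id = "rec") {
  df <- data.frame(
    recording_id = recording_id,
    onset_s = events$onset,
    duration_s = events$duration,
    type = events$type,
    channels = events$channels,
    source = events$source,
    score = events$score,
    freq_hz = events$freq_hz,
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an annotations CSV into an event set
#'
#' @param path CSV path in the documented dialect.
#' @return an `event_set`; parse/validation errors report the offending row.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "type", "channels")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotations CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!trimws(df$type) %in% EVENT_TYPES)
  if (length(bad)) {
    stop("annotations CSV: unknown event type '", df$type[bad[1]],
         "' at row ", bad[1], call. = FALSE)
  }
  event_set(
    onset = df$onset_s,
    duration = df$duration_s,
    type = trimws(df$type),
    channels = trimws(if ("channels" %in% names(df)) df$channels else ""),
    source = if ("source" %in% names(df)) trimws(df$source) else "manual",
    score = if ("score" %in% names(df)) df$score else NA_real_,
    freq_hz = if ("freq_hz" %in% names(df)) df$freq_hz else NA_real_
  )
}

#' Write a hypnogram to CSV
#'
#' @param hyp a `hypnogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  write.csv(data.frame(epoch_index = seq_along(hyp$stages) - 1,
                       stage = hyp$stages),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV
#'
#' @param path CSV path (`epoch_index,stage`).
#' @param epoch_length epoch length in seconds.
#' @return a `hypnogram`; unknown stage tokens error with their row number.
#' @export
read_hypnogram <- function(path, epoch_length = 30) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_index,stage", call. = FALSE)
  }
  stages <- trimws(df$stage)
  bad <- which(!stages %in% HYPNO_STAGES)
  if (length(bad)) {
    stop("hypnogram CSV: unknown stage token '", stages[bad[1]], "' at row ",
         bad[1], call. = FALSE)
  }
  if (!identical(as.integer(df$epoch_index), seq_along(stages) - 1L)) {
    stop("hypnogram CSV: epoch_index must be 0-based and consecutive",
         call. = FALSE)
  }
  hypnogram(stages, epoch_length = epoch_length)
}
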