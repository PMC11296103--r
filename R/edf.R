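# European Data Format (EDF) input/output.
#
# Nothing in the installed stack reads EDF, so a minimal, spec-conforming
# reader/writer is implemented here: 256-byte fixed header + 256 bytes per
# signal, 16-bit little-endian samples, physical scaling from the per-signal
# physical/digital ranges.  Data records are 1 s when the sample count
# divides evenly, otherwise a single record spanning the whole signal.
# EDF+ annotations are out of scope.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to the EDF 16-bit integer range with a symmetric
#' per-channel physical range; the round-trip error is at most half a
#' quantization step. Header date/time default to fixed values so that the
#' output bytes are a pure function of the signal (reproducible pipelines).
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param patient,recording_id free-text header fields (<= 80 chars).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "iedburden") {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- rec$signal
  ns <- nrow(sig)
  n <- ncol(sig)
  sf <- rec$sfreq
  if (abs(sf - round(sf)) < 1e-9 && n %% round(sf) == 0) {
    spr <- as.integer(round(sf))
    nrec <- n %/% spr
    rec_dur <- 1
  } else {
    spr <- n
    nrec <- 1L
    rec_dur <- n / sf
  }
  # physical ranges: symmetric, written to header precision first so that
  # the scaling used for quantization equals what a reader will parse back;
  # the magnitude must fit 7 characters so the signed minimum fits 8
  pmax_raw <- apply(abs(sig), 1, max)
  pmax_raw[pmax_raw == 0] <- 1
  pmax_chr <- vapply(pmax_raw * 1.01, function(v) {
    for (d in c(6, 5, 4, 3)) {
      s <- formatC(v, format = "g", digits = d, width = 1)
      if (nchar(s) <= 7) return(s)
    }
    formatC(v, format = "e", digits = 1, width = 1)
  }, character(1))
  pmax <- as.numeric(pmax_chr)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording_id, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8), pad_field("", 44),
    pad_field(nrec, 8), num_field(rec_dur, 8), pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field_block <- function(values, width) {
    writeChar(paste(vapply(values, pad_field, character(1), width = width),
                    collapse = ""), con, eos = NULL)
  }
  field_block(rec$channels, 16)
  field_block(rep("", ns), 80)                       # transducer
  field_block(rep("uV", ns), 8)                      # physical dimension
  field_block(paste0("-", pmax_chr), 8)              # physical min
  field_block(pmax_chr, 8)                           # physical max
  field_block(rep(dmin, ns), 8)
  field_block(rep(dmax, ns), 8)
  field_block(rep("", ns), 80)                       # prefiltering
  field_block(rep(spr, ns), 8)
  field_block(rep("", ns), 32)                       # reserved
  # [-pmax, pmax] maps onto the asymmetric [-32768, 32767]: the reader
  # reconstructs value = dig*scale + scale/2, so digitize with that offset
  scale <- (2 * pmax) / (dmax - dmin)
  dig <- round(sweep(sig, 1, scale, "/") - 0.5)
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- t(dig[, cols, drop = FALSE])            # signal-major within record
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @return an `eeg_recording` in the referential montage.
#' @export
read_edf <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 256) {
    stop("malformed EDF: file too short for a header (", path, ")",
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF: bad version field", call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(nrec) || nrec < 1 || is.na(rec_dur) ||
      rec_dur <= 0 || sz < hdr_bytes) {
    stop("malformed EDF: inconsistent header", call. = FALSE)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  rd(80 * ns); rd(8 * ns)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)
  if (length(unique(spr)) != 1) {
    stop("unsupported EDF: signals with differing sampling rates", call. = FALSE)
  }
  spr1 <- spr[1]
  sfreq <- spr1 / rec_dur
  expected <- hdr_bytes + 2 * sum(spr) * nrec
  if (sz < expected) stop("malformed EDF: truncated data records", call. = FALSE)
  sig <- matrix(0, nrow = ns, ncol = spr1 * nrec)
  scale <- (pmax - pmin) / (dmax - dmin)
  offset <- pmin - scale * dmin
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr1, size = 2, endian = "little",
                   signed = TRUE)
      sig[i, ((r - 1) * spr1 + 1):(r * spr1)] <- d * scale[i] + offset[i]
    }
  }
  new_recording(sig, sfreq, labels, montage = "referential")
}
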