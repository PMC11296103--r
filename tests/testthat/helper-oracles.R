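# Independent oracles used across test files.  Each deliberately uses a
# different algorithm from the implementation it checks.

# Full-table DTW (no band, quadratic memory) - oracle for the banded C++ DP.
dtw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      D[i, j] <- abs(x[i - 1] - y[j - 1]) +
        min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
    }
  }
  D[n + 1, m + 1]
}

# Interval union length by endpoint sweep with coverage counting --
# different algorithm from the sort-and-merge in compute_burden.
union_length_oracle <- function(spans) {
  if (nrow(spans) == 0) return(0)
  pts <- rbind(cbind(spans[, 1], 1), cbind(spans[, 2], -1))
  pts <- pts[order(pts[, 1], -pts[, 2]), , drop = FALSE]
  depth <- cumsum(pts[, 2])
  total <- 0
  for (k in seq_len(nrow(pts) - 1)) {
    if (depth[k] > 0) total <- total + (pts[k + 1, 1] - pts[k, 1])
  }
  as.numeric(total)
}

# Exact two-sided signed-rank p by full 2^n enumeration (no ties assumed).
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  p_lo <- mean(Vs <= V_obs)
  p_hi <- mean(Vs >= V_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Cliff's delta by explicit double loop.
cliffs_oracle <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# tiny deterministic recording for io/montage tests
make_tiny_recording <- function(n_s = 2, sfreq = 128, constant = NULL) {
  n <- n_s * sfreq
  sig <- if (is.null(constant)) {
    matrix(sin(outer(seq_len(19), seq_len(n) / sfreq, "*")), nrow = 19) * 40
  } else {
    matrix(constant, nrow = 19, ncol = n)
  }
  new_recording(sig, sfreq, CHANNELS_1020)
}

# hypnogram from a compact stage spec like c(W = 2, N2 = 4) (epochs)
hyp_of <- function(...) {
  spec <- c(...)
  hypnogram(rep(names(spec), times = spec))
}
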