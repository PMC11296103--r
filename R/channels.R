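#' The 19-channel 10-20 scalp electrode set
#'
#' Channel labels of the standard 19-electrode international 10-20 montage
#' (old nomenclature, T3/T4/T5/T6), the fixed channel set of the pipeline.
#'
#' @format Character vector of length 19.
#' @export
CHANNELS_1020 <- c(
  "Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
  "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz"
)

# Longitudinal bipolar ("double banana") chain: temporal and parasagittal
# chains plus the midline.  Each row is anode minus cathode.
BIPOLAR_CHAIN <- matrix(c(
  "Fp1", "F7", "F7", "T3", "T3", "T5", "T5", "O1",
  "Fp2", "F8", "F8", "T4", "T4", "T6", "T6", "O2",
  "Fp1", "F3", "F3", "C3", "C3", "P3", "P3", "O1",
  "Fp2", "F4", "F4", "C4", "C4", "P4", "P4", "O2",
  "Fz", "Cz", "Cz", "Pz"
), ncol = 2, byrow = TRUE)

# posterior channels that carry the synthetic alpha rhythm
POSTERIOR_CHANNELS <- c("P3", "P4", "O1", "O2", "Pz")

# typical spindle-generating (fronto-centro-parietal) channels
SPINDLE_CHANNELS <- c("F3", "F4", "Fz", "C3", "C4", "Cz", "P3", "P4", "Pz")
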