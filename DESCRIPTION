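Package: iedburden
Title: Interictal Epileptiform Discharge Detection and Burden Analysis for Paired EEG Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A quantitative EEG pipeline for pre/post-treatment comparisons in
    epilepsy: windowed interictal epileptiform discharge (IED) detection with
    per-recording threshold calibration under leave-one-patient-out
    cross-validation, interictal epileptic activity (IEA) burden
    quantification, sleep-spindle detection in N2 sleep by percentile
    thresholding, and paired nonparametric statistics (Wilcoxon signed rank,
    Cliff's delta, false-discovery-rate adjustment). Includes a synthetic
    19-channel EEG cohort generator with known ground truth (1/f background,
    spike-wave templates, bursts, spindles, gamma precursors, hypnograms) and
    EDF/CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
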