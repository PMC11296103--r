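---
title: "Quantifying interictal epileptiform activity and sleep spindles in paired EEG recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interictal epileptiform activity and sleep spindles in paired EEG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In children with drug-resistant epilepsy, treatment response is often
judged from paired scalp EEG recordings taken before and after an
intervention. Two complementary readouts matter: the **interictal
epileptic activity (IEA) burden** — the percentage of recording time
occupied by interictal epileptiform discharges (IEDs) and epileptic
bursts — and **sleep physiology**, approximated by the rate of sleep
spindles in N2 sleep. `iedburden` implements the full quantitative chain:
automated IED detection with per-patient threshold calibration, burden
and channel/gamma metrics, spindle detection, and the paired
nonparametric statistics, plus a synthetic-EEG cohort generator with
exact ground truth that stands in for patient recordings, which are not
publicly available.

## The detection model

IEDs and background are treated as 500-ms single-channel waveforms.
Training annotations are *global* (an event time, no channel attribution);
channel-level labels are recovered per event by clustering the 19
per-channel windows into two groups with k-medoids (k = 2, exact search
over medoid pairs) under dynamic-time-warping distance with a Sakoe–Chiba
band of 10% of the window length. The DTW is computed on 40-ms
moving-average magnitude envelopes: between two *noisy* channels, raw
amplitude DTW is dominated by independent background noise and carries no
cluster structure, while the envelope concentrates the distance on
transient morphology. The cluster whose medoid has the larger
peak-to-peak amplitude is the IED-positive one; when all channels carry
essentially identical waveforms no separation is possible and all are
labeled positive.

The published detector is CNN-based; the classifier cited there is not
described in enough detail to reproduce, and this environment has no
GPU/torch stack, so the pluggable classifier interface defaults to
regularised-free logistic regression on eleven spectral/morphology window
features (log peak-to-peak, RMS, maximal slope, line length, kurtosis,
slope/RMS sharpness ratio, and five log relative band powers between 1
and 70 Hz). On synthetic cohorts this fallback reaches held-out AUC
> 0.99 at the default spike amplitude, so nothing in the downstream
protocol depends on the classifier family. Predictions are made per
channel over a 500-ms window sliding with 75% overlap (125-ms hop) and
combined into a global score by the channel-wise maximum.

**Threshold calibration** is per recording: the largest threshold whose
sensitivity on the annotated IEDs is at least 75%, followed by a
deterministic surrogate of the protocol's visual adjustment — while the
full-recording detection rate deviates from the annotated IED rate by
more than a factor of 3, the threshold moves in 0.05 steps, never
crossing the sensitivity floor. Supra-threshold windows merge into one
event when their window spans are separated by less than one hop; the
event time is the center of the maximum-scoring window, with a fixed
250-ms analysis span.

## Burden and IED features

Burden is a coverage measure:
`100 × |union of event spans| / analyzed duration`, with each IED
contributing a fixed 250-ms span and bursts their annotated durations;
overlaps are unioned first so burden cannot exceed 100%. Comparisons are
made in the vigilance state most prominent in *both* recordings of a
pair (maximising the minimum of the two stage durations), with any sleep
stage preferred over wake. Channel involvement is summarised per
recording by the 95th percentile (type-7 linear interpolation) of
per-event channel counts. The gamma precursor metric band-limits to
30–70 Hz over the 200 ms ending at the IED span onset; band power is
estimated from the Hann periodogram of the isolated window — a
deliberate choice, because any zero-phase band-pass of the continuous
signal smears the spike's own gamma energy backwards across > 100 ms and
saturates the criterion. Gamma is "present" when any attributed channel
exceeds mean + 2 SD of its event-free background windows.

## Spindle detection

Per channel in the common-average montage, exclusively in N2: band-pass
10–16 Hz, square, smooth with a 300-ms centered moving average, and
threshold at the 80th percentile of the smoothed envelope over N2
samples. Supra-threshold runs lasting 0.5–3 s are candidates; run length
is corrected by the smoothing width before the gate (a strong burst's
smoothed envelope crosses a low threshold for roughly its duration plus
the window). Detectors of this percentile family are dual-threshold in
practice, and for a reason this package makes explicit: percentile
thresholds are scale-adaptive, so stationary band noise yields a
scale-independent rate of 0.5–3-s supra-threshold runs that no single
80th-percentile criterion can reject. A candidate must therefore also
hold its envelope above 5× the boundary threshold for at least 150 ms.
Both criteria are percentiles/multiples of percentiles, so detection is
exactly invariant under amplitude rescaling of the recording — a tested
property. Each detection's dominant frequency is the zero-padded Hann
periodogram peak in 10–16 Hz; 12 Hz and above is fast (the fast band is
printed as 12–16 Hz), below is slow. Detections intersecting an IED span
are excluded. Rates are per minute of N2, eligible only when both
recordings of a pair have at least 1 min of N2; detections on different
channels within 0.5 s count once (earliest onset).

## Statistics

Endpoints are compared with the Wilcoxon signed-rank test for paired
samples (exact null distribution for n ≤ 25 without ties, normal
approximation with continuity and tie correction otherwise; zero
differences dropped by default, Pratt variant available). Effect sizes
are Cliff's delta computed between the post and pre arms as cross pairs,
so a decrease yields a negative delta — this reproduces the sign
convention of the source protocol, which does not state whether its
delta was paired or unpaired. Families of endpoints compared in one
invocation are adjusted by Benjamini–Hochberg; the protocol does not
enumerate its family, so the family is whatever one `compare_cohort()`
call spans. Normality is screened with a one-sample Kolmogorov–Smirnov
test against a normal with estimated parameters (a reporting screen, not
an inferential claim).

## The synthetic world

The generator's defaults are the stated operating point of the study it
emulates, fixed once:

* 19 channels (10–20 system) at 256 Hz (rate unstated in the protocol;
  256 Hz is typical clinical practice), 20-min recordings.
* `1/f^2` Gaussian background at 15 µV SD per channel — NREM scalp EEG
  falls off at roughly `1/f^2`–`1/f^3` above 1 Hz; a `1/f^1` slope (the
  initial stab) leaves a physiologically implausible 10–16 Hz noise
  floor. A 10-Hz posterior alpha rhythm plays during wake epochs only
  (alpha attenuates at sleep onset; rendering it in sleep would bleed a
  common 10-Hz component into every common-average channel).
* IEDs: 70-ms triphasic spike + 300-ms slow wave, peak amplitude 6× the
  channel SD, on 1–5 channels of a per-recording focal set; isolated
  spikes keep ≥ 1.25-s clearance (denser runs are what the burst type
  models — this also makes detected-event counts provably monotone in
  the threshold). Bursts: 4-Hz spike runs of ~3.6 s on the same focal
  channels.
* Baseline rates: 6.5 IEDs/min + 0.45 bursts/min × 3.6 s ⇒ nominal
  burden 5.4%; post-treatment rates scaled by 1.5/5.4 ⇒ 1.5%. These are
  the published cohort medians.
* Spindles: Tukey-windowed 10–16 Hz oscillations, 0.5–3 s, only in N2,
  on 3–6 fronto-centro-parietal channels, amplitude 8× the channel's
  10–16 Hz band SD (≈ 35–40 µV peak-to-peak — a spindle a scorer would
  call obvious). Baseline 0.8 fast + 0.3 slow per N2 minute; post 1.5 +
  0.3 — the published medians.
* Gamma precursors: 30–70 Hz bursts in the 200 ms before a fraction of
  IEDs (14.3% baseline / 28.6% post, the published medians).
* Cohort heterogeneity: a shared per-subject log-normal rate factor
  (sdlog 1.0, matching the order-of-magnitude spread of published burden
  ranges) and an independent per-arm factor (sdlog 0.35) applied to
  *both* arms, so a null cohort has exactly exchangeable arms; nominal
  per-subject burden is capped at 35% because overlap-free placement
  cannot realise the printed 97.3% extreme, which corresponds to
  near-continuous activity outside this event model.

What a green test does **not** establish: the background is Gaussian and
stationary (no artifacts, no EMG/eye movements, no REM), spindles are
pure amplitude-modulated tones, and IED morphology is a single template
family. Detector operating characteristics on real EEG will be worse and
the published real-data figures (sensitivity 80.2%, FPR 0.24/min, AUC
0.995) are reference points, not reproducible targets.

## Numerical choices

FFT brick-wall filtering with raised-cosine transition bands (2 Hz
default) — no DSP dependency is available, and zero-phase FFT masking is
adequate for band power and envelopes. Quantile convention is R type 7
everywhere. The 12-Hz fast/slow boundary is assigned to fast,
configurable. EDF output uses symmetric per-channel physical ranges
written at header precision before digitisation, so a round trip is
exact to half a quantisation step; header date/time are fixed constants
so that output bytes are a pure function of the data (manifest-level
reproducibility). Every stochastic operation takes an explicit seed; all
derived seeds stay below 2^31.

Cohort-level operating characteristics (power of the burden comparison,
type-I error under the null) are computed on event-time-only cohorts
(`signals = FALSE`): burden is a function of event times, the metric
code path is identical, and rendering 4800 full recordings would add
only CPU time.

## Known limitations

Montage support covers referential, common-average and one fixed
longitudinal bipolar chain (the protocol does not name its chain). The
collapsed `NREM` hypnogram label is carried through state selection but
spindle analysis requires explicit N2. The semi-automated visual
re-thresholding and visual cross-checks of the original protocol are
replaced by deterministic rules; patient-level published results are
therefore out of reach by design, and only protocol-level properties
(sensitivity floors, oracle arithmetic, operating characteristics on the
calibrated generator) are asserted.
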