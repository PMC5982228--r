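---
title: "Beat detection for long-term multilead ECG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat detection for long-term multilead ECG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltmbeat)
```

## The problem

Long-term monitoring (LTM) stretches ambulatory ECG recording from 24
hours to a week or more. Two things change relative to conventional
Holter analysis. First, scale: a 7-day, 3-lead recording holds over half
a million beats, so the detector must run in bounded memory with
near-linear cost. Second, signal quality: patients care less for the
electrodes as days pass, so muscle artifact, motion transients, and
outright electrode decoupling dominate the error budget. `ltmbeat`
addresses both with segmented processing and simultaneous multilead
detection fused by majority polling — a voting scheme that, like a
median, shrugs off a single misbehaving lead.

## Pipeline and assumptions

Each 300-s segment passes through three stages.

**Preprocessing.** A cubic spline through per-second median knots
removes baseline wander; second-order notches (2 Hz bandwidth) remove
mains interference and its harmonics; a fourth-order 25 Hz zero-phase
Butterworth low-pass removes muscle artifact; and a time-local-variance
filter clips motion bursts (below). All filters are applied
forward-backward, so they are zero-phase: R-peak positions shift by at
most one sample, which matters because every downstream tolerance is
expressed in milliseconds. Filters are designed at the record's native
sampling rate — no resampling anywhere — because the supported databases
span 128–360 Hz and resampling would blur fiducials.

**Feature extraction.** The per-lead chain is the Pan–Tompkins cascade:
band-pass 5–15 Hz (third-order Butterworth equivalents of the original
integer filters, which assumed 200 Hz), five-point derivative scaled by
fs/8, squaring, and 150-ms moving-window integration (the canonical
window). Multilead reductions are available as alternatives: the
squared-lead sum, the combinational per-lead product, PCA, and ICA.
The combinational product is implemented exactly as its defining
expression reads — each lead's feature is the product over *all* leads,
so the per-lead columns coincide; users should be aware the rule is
degenerate in this sense. ICA is an in-package symmetric FastICA (tanh
contrast) on whitened leads; components are ranked by descending
kurtosis because the sparse QRS train is strongly super-Gaussian, and
the selected component is squared, which also disposes of the sign
ambiguity. ICA is the only stochastic element in the pipeline and is
deterministic given `seed`.

**Detection.** On each (per-lead) feature signal a threshold
`alpha * mean(y) + beta * sd(y)` is computed over disjoint 3-s windows
and held constant within each; an all-zero window (signal loss) inherits
the previous window's threshold, so dropouts do not create zero
thresholds that would fire on noise when the signal returns.
Supra-threshold runs are widened by 75 ms on both sides and merged;
coarse localization takes the earliest argmax of the absolute filtered
lead within each region; fine localization re-centers each peak on the
argmax of a 40 Hz low-passed copy of the preprocessed signal within a
100-ms window, landing on the actual R apex rather than the feature
hump. A 250-ms refractory period (greedy by amplitude) suppresses
T-wave double-detections. Finally the per-lead peak lists are clustered
within a 10-ms tolerance (at least one sample at low rates) and a fused
peak — the median of the cluster — is emitted when enough leads agree:
all leads (AND), a majority (POLL), at least two (SC), or any (OR).
With two leads a majority is both of them, so POLL coincides with AND;
with three leads POLL and SC coincide. These containments (AND ⊆ POLL ⊆
OR, AND ⊆ SC ⊆ OR) are verified against a brute-force clustering oracle
in the tests.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha`, `beta` | 3, 0.5 | — | threshold multipliers of window mean and SD; the K=12-fold tuned operating point for the transversal settings |
| `update_s` | 3 | s | threshold refresh; short enough to track beat-to-beat amplitude swings |
| `lowpass_hz` | 25 | Hz | removes EMG while keeping the QRS band |
| `widen_ms` | 75 | ms | region widening, applied symmetrically |
| `tolerance_ms` | 10 | ms | inter-lead clustering tolerance (clinical alignment of leads) |
| `refractory_ms` | 250 | ms | above the shortest physiologic RR at maximal sinus rates |
| `segment_length_s` / `overlap_s` | 300 / 2 | s | processing-time optimum / full filter context at boundaries |
| `match_tol_ms` | 150 | ms | beat-by-beat scoring tolerance (AAMI EC57 convention) |
| `var_win_s`, `var_k`, `clip_k` | 0.2, 8, 4 | s, —, — | motion-artifact variance window, ratio threshold, clip multiple |

## Numerical and degenerate-input choices

*Coordinates.* Sample indices are 0-based and ranges half-open
throughout, matching the WFDB convention.

*Filter edges.* R's `signal::filtfilt` pads with only a handful of
zeros, so narrow filters ring visibly at record ends. All filtering goes
through an odd-reflection pad sized to the inverse bandwidth of the
filter. Steady-state filter properties are therefore asserted on record
interiors in the tests; the residual edge transient is harmless to
detection because segments overlap by 2 s and each segment contributes
only its core (non-overlap) zone to the stitched result. A final
segment shorter than half the segment length is folded into its
predecessor: a stub tail gives the 3-s threshold windows too little
context and can turn a T-wave into a false positive at the record end.

*Motion clipping.* A window is artifactual when its 0.2-s variance
exceeds 8 times the rolling-median variance (10-s median window). The
clip level is 4 times the 99.9th percentile of the *unflagged* absolute
samples. An amplitude-quantile scale — rather than an RMS scale — is
used deliberately: on a clean record the isoelectric baseline makes
every QRS window exceed the variance ratio, and an RMS-based level would
clip genuine R-waves; the quantile level sits above them, so clean
regions pass bit-identical while high-amplitude bursts are still
reduced several-fold. Clipping rather than blanking keeps the adaptive
threshold estimate free of dead zones.

*Idempotence.* Applying the notch + low-pass twice is a no-op for
passband content, and the tests assert exactly that. It is *not* a
no-op for wide-band QRS energy near the 25 Hz band edge — any realizable
low-pass attenuates there on every pass — so the property is stated for
in-band tones.

*Tie-breaks.* Coarse search returns the earliest maximum; refractory
pruning prefers the higher amplitude, earliest on ties; fused cluster
positions use the floor of the median.

*Matching.* Detections are matched to references by a two-pointer sweep
(each detection takes the earliest unmatched reference within
tolerance). For a uniform tolerance on a line this attains the maximum
number of matches — verified against an exhaustive assignment oracle —
and runs in linear time, which a nearest-pair greedy would not
guarantee. The TN convention counts inter-beat gaps free of false
positives, and the decision total is defined as B = TP+FP+FN+TN, the
only convention under which Acc ≤ 100 and Acc + Error = 100 hold
identically (asserted on every evaluation in the tests). With B defined
as the annotated-beat count instead, Acc could exceed 100; published
figures using an unstated B may therefore differ slightly.

*Threshold tuning.* `tune_threshold` evaluates the full detector on every
record × grid point, then performs K-fold selection; the reported
parameters minimize the mean held-out error. Tied errors resolve to the
first grid point in row-major order.

## The synthetic generator

`synth_ecg` places a five-Gaussian P-QRS-T template (R-wave σ = 11 ms,
amplitude 1 mV on lead 1; secondary leads scaled 0.7, 0.55, …) at RR
intervals drawn with configurable mean heart rate and relative jitter
(default 60 bpm, 3%). The annotated sample is the R-Gaussian center,
which is the per-beat signal maximum — ground truth is exact by
construction. Noise types mirror ambulatory reality: sub-0.5 Hz
baseline wander, mains sinusoids with harmonics, 20 Hz-to-Nyquist
band-passed EMG, sparse high-amplitude motion transients, and per-lead
flat-line disconnections; stationary types are scaled to the requested
per-lead SNR exactly. `synth_ltm` varies noise severity per simulated
day (days compressible to seconds for testing), emulating the mid-test
quality dip typical of week-long recordings.

What passing tests on this generator do show: the pipeline's logic —
thresholding, localization, fusion, segmentation stitching, scoring —
is correct, noise-robust within the modeled noise classes, and
scale-invariant. What they do not show: performance on pathological
morphologies (bundle-branch blocks, ectopy runs, atrial fibrillation),
on paced rhythms, or under real electrode chatter, none of which the
Gaussian template models. Benchmarking against annotated clinical
databases (e.g., via `benchmark_database()` on a local PhysioNet copy)
remains the arbiter for those.

## Problem sizes

The test suite and the acceptance script run on records of 30 s to 20
min at 200 Hz (up to ~1,200 beats), 3×3 tuning grids over four 45-s
records, and 100 randomized fusion configurations per property check —
sizes chosen so the full suite completes in a few minutes while every
code path, including segmentation stitching across ten segments, is
exercised.

## Known limitations

- Batch only; no streaming or real-time operation.
- EDF/ISHNE Holter containers are not read (WFDB and a CSV dialect are).
- The combinational product rule is degenerate as printed (identical
  per-lead columns); polling over per-lead Pan–Tompkins features is the
  recommended and default configuration.
- Specificity rests on the gap-based TN convention above; it is not the
  epidemiological specificity and should be compared across detectors
  only under the same convention.
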