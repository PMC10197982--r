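---
title: "Predicting hyperkalemia from ECG morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hyperkalemia from ECG morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Serum potassium above 5.0 mmol/L (hyperkalemia) is common and dangerous in
end-stage renal disease, and laboratory confirmation takes time that an
arrhythmia may not grant. Potassium reshapes the ECG in characteristic ways
— a tall, narrow, "tented" T wave first, then P-wave flattening, PR
prolongation and QRS widening as the concentration rises — so the ECG can be
used as an instant, non-invasive potassium screen. `hyperkECG` implements a
complete, testable version of that idea: preprocess a raw 12-lead ECG,
extract 48 morphological features from chest leads V2–V5, train five model
families to classify hyperkalemia at the 5.0 / 5.5 / 6.0 / 6.5 mmol/L
diagnostic thresholds, and compare them with ROC/AUC machinery including
DeLong confidence intervals and paired DeLong tests. Because no patient data
ship with the package, a potassium-modulated synthetic ECG generator with
fully known ground truth stands in for the cohort; every stage is validated
against that truth.

## Preprocessing cascade

`preprocess_record()` applies, per lead:

1. **Baseline correction, pass 1** — subtract a least-squares polynomial
   (default order 5 over the 30 s sweep). Time is rescaled to [-1, 1] before
   fitting so high orders stay well conditioned.
2. **Smoothest-window selection** — every candidate 10 s window (stride
   0.5 s) is scored by the RMS residual about an OLS line; the minimum wins,
   ties to the earliest start. The window is chosen once, on a reference
   lead (default V2), and applied to all leads so beats stay time-aligned
   across the chest leads; features must come from the same beats.
3. **Baseline correction, pass 2** — polynomial order 3 inside the window.
4. **Wavelet denoising** — a multilevel periodized orthonormal DWT
   (Daubechies db6, level 6, implemented in the package) with soft
   thresholding of all detail levels at the universal threshold
   `sigma * sqrt(2 log N)`, `sigma = median(|d1|)/0.6745`. The transform is
   exactly orthogonal, which the tests exploit as a perfect-reconstruction
   oracle.
5. **Band-pass filtering** — zero-phase (forward–backward) Butterworth,
   0.5–40 Hz. The default order is 5: the measured zero-phase response of
   the order-4 design attenuates 50 Hz mains by only ~8x, while order 5
   gives ~12x and remains numerically stable at fs = 500 Hz
   (transfer-function band-passes of order 6 and above are not stable at
   this sampling rate; an SOS implementation would be required).

All parameters sit in `preprocess_config()` and in the pipeline YAML.

## Delineation and the 48 features

R peaks are local maxima above an adaptive threshold (half the median of
2-s block maxima — scale-invariant by construction) with a 0.2 s refractory
period. Per beat, `delineate_beat()` finds QRS onset/offset by a sustained
slope-threshold search around R, the S trough as the post-R minimum, the T
peak as the largest absolute deviation from the isoelectric level in
[J + 60 ms, 60% of the preceding RR], and T onset/offset by intersecting
the tangent at the steepest flank with the isoelectric line (for a Gaussian
wave this lands at center ± 2 widths, which is the analytic oracle used in
the tests). The isoelectric reference is the median of the 40 ms PR segment
ending 20 ms before QRS onset.

The 12 features per lead are three slope-class (T right slope, T left
slope, ST-segment OLS slope), three amplitude-class (T, R, S amplitude
relative to the isoelectric level — **signed**, so an inverted T stays
negative and is never silently rectified), and six area-class features
(T/R/S trapezoidal areas of |v - iso|, QRS split into its positive and
negative lobes, plus each area divided by the preceding RR interval, making
it heart-rate invariant). Across the beats of the 10 s window the
per-feature **median** is taken, robust to one mis-delineated beat. Four
leads (V2–V5) x 12 features = 48, in a fixed lead-major order
(`feature_names()`).

## The synthetic cohort

`generate_record()` builds each beat as a sum of five Gaussian waves
(P, Q, R, S, T) — ECGSYN-style morphology without the dynamical system — so
every fiducial, amplitude and area has a closed form. Serum potassium is
drawn from Normal(4.83, 1.01) truncated to [2.5, 8.0] mmol/L, matching the
dialysis cohort the pipeline emulates; 30 s records at 500 Hz, 70 bpm with
±3% RR jitter.

The potassium effect model (`k_effect_model()`) is continuous and strictly
monotone: above the 4.0 mmol/L reference the T amplitude grows and its base
narrows through a saturating excess `k_sat * (1 - exp(-dk/k_sat))`
(k_sat = 2 mmol/L); above 5.5 mmol/L the P wave flattens, PR prolongs and
QRS widens. Below the reference the T flattens mildly (30% of the upward
gain). Saturation is deliberate: each further mmol/L buys a smaller
morphology increment, which is one reason severe hyperkalemia is the harder
classification target.

The noise model carries both measurement noise (0.3 mV baseline wander at
0.25 Hz, 0.05 mV of 50 Hz mains, 0.03 mV white noise) and **between-record
physiological variability**, which is what makes the classification task
non-trivial: log-normal jitter on wave amplitudes (SD 0.12) and widths
(SD 0.12), log-normal jitter on the potassium effect magnitude (SD 0.3),
heart-rate spread (SD 5 bpm), all of it inflating by 40% per mmol/L above
5.5, plus a stochastic *atypical repolarization* component: with
probability 0.15 per mmol/L above 5.5 a record expresses a flattened or
inverted, broadened T instead of the classic tent. Atypical responses
(including frank T inversion) are well described in severe hyperkalemia;
without them — and this is a structural fact, not a tuning accident — every
monotone feature map with potassium-independent noise makes the *severe*
thresholds easier than 5.0, because the tail positives sit far from the
bulk of the distribution. The three tail mechanisms (saturation, inflating
jitter, atypia) were calibrated once so that held-out AUC at the
5.0 mmol/L threshold lands in the 0.85–0.95 range with AUC degrading
monotonically toward 6.5 mmol/L, then frozen as package defaults.

Everything stochastic lives in the noise model: with `noise_model_none()`
records are exactly periodic and analytically clean, so tests can demand
T-amplitude recovery within 5% and rank correlation 1 with true potassium.

What the generator does **not** emulate: real conduction physiology
(it is a morphology model, not an electrophysiological one), respiratory
modulation and HRV spectra, ectopy, electrode artifacts, intra-patient
correlation between repeated sessions, and lead-field geometry (non-chest
leads are scaled copies). Passing tests therefore demonstrate that the
pipeline correctly recovers and uses the morphological potassium signal it
is pointed at — not that the trained models would transfer to patients.

## Classification protocol

Labels are `k >= threshold` (the guideline convention). One random 8:2
train/test split is made up front and shared by all thresholds, mirroring
the single-split study design; stratification is available behind a flag
(`stratify_split`), and splitting is by record (the emulated cohort has no
subject structure; with real paired pre/post-dialysis data, subject-level
splitting would be required to avoid leakage). On the training split each
family is tuned by stratified 5-fold cross-validation maximizing mean
validation AUC, with per-feature standardization refitted inside every fold
— the scaler of the final model is provably train-only, and a test asserts
it. Ties in CV AUC resolve to the earliest grid point.

Families and default grids (all overridable via `model_spec()`):

* **LR** — ridge logistic regression fitted by IRLS (implemented in the
  package; with ridge curvature the Newton system is positive definite, so
  the fit is stable even on separable folds), inverse-regularization
  C in {0.01, 0.1, 1, 10}.
* **SVM** — RBF (e1071), C in {0.1, 1, 10}, gamma in {scale, 0.01, 0.1};
  scored by the logistic transform of the decision value (rank-equivalent
  to the margin; 0.5 corresponds to the decision boundary).
* **XGB** — gradient-boosted trees, 100/300 rounds, depth 2–4, learning
  rate 0.05/0.1.
* **AdaBoost** — discrete AdaBoost over exhaustively searched decision
  stumps (implemented in the package; weighted stump search is vectorized
  via sorted cumulative sums), 100/300 rounds, shrinkage 0.5/1.0.
* **CNN** — a small 1-D convolutional network over the 4-lead x 12-feature
  grid: two same-padded convolutions (kernel 3; 8 then 16 channels, ReLU)
  and a dense sigmoid head, trained with full-batch Adam and early stopping
  on a stratified 15% validation split. Implemented in plain matrix
  algebra, deterministic given the seed; backpropagation is verified
  against finite differences in the test suite.

No resampling or class weighting is applied by default — the degradation of
the severe thresholds under their 5–13% prevalence is part of the
phenomenon under study.

## Evaluation

Scores are dichotomized at 0.5 (a calibrated probability for LR/XGB/CNN;
the decision boundary for the margin families). The report carries
accuracy, precision, sensitivity, specificity (zero-denominator ratios
reported as missing, never as 0), F1, and AUC with a DeLong 95% CI: the
variance comes from the placement-value components `S10/n+ + S01/n-`, the
normal interval is clipped to [0, 1]. Ties in AUC get Mann–Whitney half
credit, consistent with the DeLong framework. Pairs of models on the same
test records are compared with the paired DeLong test; p-values are
reported raw, with a clearly labelled Holm-adjusted column as a non-study
extra. Whether such headline metrics should be cross-validated rather than
single-split is a real concern at the severe thresholds, where the test set
holds only ~11 positives; this package reports test-set values and labels
them so.

## Numerical choices and degenerate inputs

* Format 212 packing validates the 12-bit range sample-by-sample and pads
  odd-length input with one zero (recorded, trimmed on read).
* The DWT pads to a multiple of `2^level` by tail reflection; perfect
  reconstruction and trimming are exact, and a zero signal passes through
  denoising unchanged (the universal threshold is then 0).
* `filtfilt` edge transients are accepted (windows are 10 s, features come
  from interior beats); spectral and residual-baseline assertions in the
  tests therefore measure interior samples, outside the first and last
  second of the window.
* Beats whose search windows touch the record edge, or whose |T| deviation
  stays under 0.05 mV, raise a typed skip condition and are excluded from
  the median; a record is dropped only if a required lead has no usable
  beat (the drop count is reported, and under default noise it stays below
  ~1%).
* Degenerate classifier inputs fail fast: single-class training data,
  mismatched feature columns, empty grids and empty family lists are errors
  before any compute.

## Problem sizes

The default experiment simulates 1024 records (~2 min), extracts features
on the fly, and tunes all five families (~4 min for four thresholds). The
test suite uses the same defaults for the end-to-end trend check and small
sizes (40–400 records) elsewhere; the acceptance script re-runs the full
default experiment from scratch.

## Reproducibility

Every stochastic step is seeded: the dataset seed fixes the potassium draws
and per-record generator seeds; the experiment seed fixes the split, fold
assignment and stochastic fits; `run_pipeline()` writes a manifest with
MD5 checksums, and re-running an identical config reproduces identical
feature tables bit for bit.
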