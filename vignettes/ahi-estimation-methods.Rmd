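---
title: "Detecting sleep apnea events and estimating the AHI from home-measurable signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep apnea events and estimating the AHI from home-measurable signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driven)
```

## The problem

The Apnea-Hypopnea Index (AHI) — the number of apneas and qualifying
hypopneas per hour of sleep — is the clinical quantity behind the four
AASM severity classes: healthy (AHI < 5), mild (5–15), moderate
(15–30), severe (> 30). Scoring it normally requires a full
polysomnogram. This package estimates the AHI from the small set of
channels a patient could wear at home — abdominal and thoracic
respiratory effort, pulse oximetry (SpO₂), optionally nasal airflow and
an ECG-derived R–R interval series — and segments the night into awake,
normal-sleep and event periods.

The event vocabulary follows the AASM scoring rules: an *apnea* is a
nasal-airflow reduction of more than 90% lasting at least 10 s; a
*hypopnea* is a reduction of more than 30% for at least 10 s. Only two
hypopnea subtypes count toward the AHI: type 1, accompanied by an
oxygen desaturation of at least 3% starting within 45 s of event
onset, and type 2, followed by an arousal within 5 s of event end.
Type-3 hypopneas (neither association) are excluded everywhere.

## The estimator

The pipeline never tries to count events directly. Instead:

1. **Windowing.** Each preprocessed night is cut into 30 s windows at a
   15 s stride (consecutive windows overlap by half).
2. **Per-channel deep features.** A 1-D convolutional network per
   channel is trained to classify windows as AHI-event vs normal; its
   classification head is then discarded and the global-average-pooled
   activations serve as features (1280 per channel in the full
   profile).
3. **Stacking.** The concatenated features from all channels feed a
   gradient-boosted tree classifier that outputs the event probability
   of each window. An identical second model stack, trained on the
   sleep/awake label with a fixed 0.5 threshold, classifies each window
   as sleep or awake.
4. **Calibration.** The event threshold is chosen on validation
   windows as the point where precision equals recall — the natural
   operating point on imbalanced window labels. For each validation
   patient the *positive ratio* (event-positive sleep windows over all
   sleep windows) is computed, and a weighted linear regression maps
   ratio to AHI. Weights are inverse severity-class counts so that rare
   classes are not swamped.
5. **Estimation.** For a new night: classify sleep, compute the
   positive ratio, apply the regression (clipped at zero), and assign
   the severity class. The per-window states also yield a
   timeline — awake / normal / event — with consecutive event windows
   merged into intervals.

Total sleep time is the count of sleep-classified stride steps times
the stride: with overlapping windows there is no unique mapping from
window decisions to time, and one step per stride is the convention
that makes the ratio denominator and the timeline consistent.

## Preprocessing

* **Trimming.** The first and last 30 min of a recording are treated
  as sensor set-up time and removed; annotations shift with the new
  time base, and boundary events are clipped.
* **Robust normalisation.** Mean and SD are computed over the central
  95% of samples (percentiles 2.5–97.5), values are clipped to that
  band, z-scored and min-max mapped to [0, 1]. A single extreme
  artefact therefore cannot distort the scaling; a constant signal
  maps to 0.5. The operation is idempotent up to quantile
  interpolation.
* **Resampling.** All channels are brought to a common 64 Hz by
  natural cubic spline interpolation, which preserves high-frequency
  content better than linear interpolation. Its accuracy is limited by
  knot density: a 0.25 Hz sine sampled at 1 Hz (four knots per period)
  has an irreducible interpolation error of about 0.02 in amplitude —
  this is a property of cubic interpolation itself, not of the
  implementation, and the package's acceptance suite records that
  floor.
* **SpO₂ delays.** The oximetry response lags an obstruction, so
  delayed copies of the SpO₂ channel (10/15/20/25 s look-ahead) can be
  appended as extra channels: a window anchored at *t* then sees the
  saturation response that follows the event. Look-ahead (rather than
  lag) is used because it is the direction that brings the delayed
  physiological response into the window's view.
* **R–R intervals.** The ECG channel is reduced to an RRI series with
  the Pan-Tompkins chain — zero-phase 5–15 Hz band-pass, five-point
  derivative, squaring, 150 ms moving-window integration, adaptive
  dual thresholds with search-back and a 200 ms refractory period —
  with constants derived from the working sampling rate. The RRI value
  is held constant between beats (step interpolation) by default;
  spline interpolation is available. Zero-phase filtering means
  detected peaks need no group-delay correction; each detection is
  refined to the raw-signal maximum within ±100 ms.

Normalisation runs after resampling by default; the order is
configurable and both orders are exercised by the tests.

## The synthetic study generator

Real sleep studies cannot ship with a package, so every stage is
validated against a generator that plants exactly known ground truth:

* Respiratory effort and airflow are amplitude-modulated ~0.25 Hz
  sinusoids with Gaussian noise. During apneas the airflow amplitude
  drops to 5% of baseline (> 90% reduction) and effort to 20%; during
  hypopneas airflow drops to 50% (a 30–90% reduction). Awake periods
  have larger, noisier movements.
* SpO₂ sits at a 97% baseline with piecewise-linear desaturations of
  configurable depth (default 4%) starting a configurable delay
  (default 20 s) after each apnea or type-1 hypopnea onset.
* The ECG is a train of Gaussian R-wave templates at a constant heart
  rate, so R-peak times are known exactly.
* Sleep/awake stages form contiguous blocks (sleep onset, a mid-night
  awakening, final waking) totalling the requested sleep fraction;
  events are planted only inside sleep, separated by at least 30 s of
  normal breathing. The separation, combined with the validated
  constraint `desat_delay < min event duration + gap`, guarantees that
  a desaturation can never be attributed to the wrong event, keeping
  hypopnea subtype labels unambiguous.
* Type-2 hypopneas get an arousal 1–3 s after the event end; type-3
  hypopneas get neither association and are planted on top of the AHI
  events in the configured mixture proportion.

Defaults describe a plausible home sleep study: 8 h in bed, 75%
asleep, event durations 10–30 s, effort/airflow at 10 Hz, SpO₂ at
1 Hz, ECG at 125 Hz. Cohorts draw each patient's target AHI uniformly
within its severity band (severe capped at 45 events/h, the highest
rate the night can physically host at the default spacing).

What the generator does **not** emulate: realistic cardiorespiratory
coupling, central-vs-obstructive morphology, motion artefacts, sensor
dropout, or the inter-patient variability of real populations. Tests
passing on synthetic cohorts therefore demonstrate that the machinery
is correct and well-calibrated on signals obeying the scoring
definitions — not clinical performance on real data, which requires
real PSG corpora.

## Network architecture and training

The feature extractor adapts the EfficientNetV2 stage structure to one
dimension: a strided stem convolution, fused-MBConv blocks (k3
expansion convolution + 1×1 projection) in the early stages, MBConv
blocks (1×1 expansion + depthwise k3 + 1×1 projection) later,
residuals on stride-1 shape-preserving blocks, SiLU activations, a 1×1
head convolution into the feature width, global average pooling and a
2-logit head. Kernel size is 3 throughout with the 2-D architecture's
stride schedule applied along time. Squeeze-and-excitation and batch
normalisation are omitted: inputs are already normalised to [0, 1] and
the desk-scale profiles train stably without them. Three profiles are
provided:

| profile | stages (width × repeats)            | features | third-last |
|---------|-------------------------------------|----------|------------|
| tiny    | 16×1 fused, 32×1 MB                 | 64       | 32         |
| small   | 16×1, 32×2 fused, 64×2 MB           | 256      | 64         |
| full    | 24×2, 48×4, 64×4 fused; 128×6, 160×9, 256×15 MB | 1280 | 256 |

"third-last" is the width of the alternative feature tap: the pooled
activation entering the head convolution, i.e. three layers before the
logits.

Training uses categorical cross-entropy with Adam on a class-balanced
window set (negatives downsampled to match positives). Training stops
when the validation loss has not decreased for eight consecutive
epochs (configurable) and the best-validation weights are restored.
The implementation is native R (im2col convolutions with manual
backpropagation), verified against finite-difference gradients in the
test suite; all randomness — initialisation, batch order, balancing,
hyperparameter search — derives from one configuration seed.

The stacker grows trees leaf-wise with a leaf budget, the growth
strategy that converges fastest on wide feature matrices, and tunes
`num_leaves`, `learning_rate`, `min_child_samples`,
`feature_fraction` and `n_estimators` by seeded random search scored
on validation AUPRC.

## Numerical and design choices

* **Window positivity**: a window is event-positive when it overlaps
  an apnea or type-1/2 hypopnea by at least 1 s (configurable). The
  minimal rule keeps labels consistent with the event definitions;
  completeness under it is property-tested.
* **Sleep label**: a window is sleep when at least half of it lies in
  sleep-staged epochs.
* **Hypopnea subtype precedence**: when both the desaturation and the
  arousal rule hold, the desaturation (type 1) wins. The 45 s
  desaturation association is measured from event onset.
* **Threshold ties**: among thresholds with equal |precision −
  recall|, the higher precision (lower positive-call rate) wins.
* **Severity boundaries** are left-closed at 5/15/30, so AHI = 15 is
  moderate.
* **AHI clipping**: the regression may extrapolate below zero for very
  clean nights; estimates are clipped at 0.
* **Degenerate inputs** fail loudly: one-class labels, all-identical
  ratios, empty validation sets, constant signals (which normalise to
  0.5), zero predicted sleep (reported as severity "undetermined").
* **0/0 metrics** are returned as 0 with a flag rather than NaN.
* **Exclusion rules**: a recording is dropped when unsure/noise labels
  cover strictly more than a third of sleep time (ties keep), a
  required channel is constant, or a required channel is missing.

## Problem sizes used in the shipped checks

The test and acceptance runs use deliberately scaled-down study
conditions chosen to exercise every code path on a single CPU: the
learned-path check trains tiny-profile extractors on a 60-patient
cohort (40 train / 20 held-out) of 1.25 h nights at a 16 Hz working
rate — effort and oximetry carry no content above 8 Hz, so nothing is
lost at that rate — while the oracle-path check (ground-truth labels
driving the calibrated estimator) uses 60 patients with 6 h nights.
Under those conditions the held-out window AUROC exceeds 0.95 with
≥ 95% exact severity agreement (mean absolute AHI error around
2 events/h), and the oracle path recovers every planted AHI within
1.2 events/h. These figures are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* Bursts of short events separated by less than a window can merge
  into one detected interval; the 30 s smoothing window under-counts
  events in severe bursty nights. The ratio-regression estimator is
  less sensitive to this than direct event counting, which is why the
  count-based AHI exists only as a diagnostic.
* Type-2 hypopneas are defined by an EEG arousal, which none of the
  home channels observes directly; on real data they are the hardest
  event class.
* The native R network trains comfortably at the tiny/small profiles;
  the full profile is provided for the architecture contract and
  inference-scale use, not for desk-scale training.
* EDF support covers the plain 16-bit format with 1 s records; EDF+
  embedded annotations and BDF are out of scope.
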