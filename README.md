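# driven

Sleep apnea/hypopnea event detection and Apnea-Hypopnea Index (AHI)
estimation from home-measurable physiological channels: abdominal and
thoracic respiratory effort, pulse oximetry (SpO₂), and optionally
nasal airflow and ECG-derived R–R intervals.

The AHI — apneas plus qualifying hypopneas per hour of sleep — defines
the four AASM severity classes (healthy < 5, mild 5–15, moderate
15–30, severe > 30 events/h). Scoring it normally needs a full
polysomnogram; this package estimates it from sensors a patient can
wear at home. Whole nights are cut into 30 s windows at a 15 s stride;
a per-channel 1-D convolutional network (an EfficientNetV2-style stage
structure adapted to one dimension) extracts features from each raw
signal; a leaf-wise gradient-boosted tree classifier stacks the
concatenated features into a per-window event probability, and an
identical model stack classifies sleep vs awake. A patient's AHI is
then estimated from the *positive ratio*

    r = (event-positive sleep windows) / (sleep windows)

through a weighted linear regression `AHI ≈ a·r + b` calibrated on
validation patients (weights inverse to severity-class counts), with
the event threshold chosen where precision = recall. The same window
decisions yield a night segmentation into awake / normal / event
periods.

The package is usable end to end without any external data: a
synthetic polysomnography generator plants apneas, subtyped hypopneas
(≥3% desaturations within 45 s for type 1, arousals within 5 s of
event end for type 2), sleep stages and exact R-peak times, and every
stage is tested against that ground truth. EDF and profusion-style XML
readers/writers, AASM window labelling, Pan-Tompkins QRS detection,
and the full metric set (ROC/PR curves, macro F1 over severity
classes) are included.

## Worked example

Simulate a small cohort, train the desk-scale pipeline, and estimate a
held-out patient:

```r
library(driven)

base <- sim_params(duration_h = 1.25, sleep_fraction = 0.8,
                   channel_rates = c(abdominal = 10, spo2 = 1))
cohort <- simulate_cohort(60, seed = 101, base_params = base)
idx <- order(rep(1:15, 4))            # interleave severities

res <- run_pipeline(
  cohort[idx[1:40]], cohort[idx[41:60]],
  channels = c("abdominal", "spo2"),
  extractor_cfg = extractor_config("tiny", input_samples = 480,
                                   learning_rate = 3e-3, batch_size = 64,
                                   max_epochs = 10, seed = 11),
  pcfg = preprocess_config(trim_min = 0, target_rate = 16,
                           spo2_delays = numeric(0)),
  stacker_budget = 4, windows_per_patient = 40, seed = 11)

res$metrics$window_auroc              # 0.9803424
res$metrics$severity$exact_agreement  # 0.95
res$calib$event_threshold             # 0.7528594
res$reports[[1]]
#> AHI report for patient P0011
#>   estimated sleep time: 1.01 h (242 windows)
#>   positive windows: 14 (ratio 0.0579)
#>   AHI estimate: 3.35 events/h  [healthy]
#>   detected event intervals: 5
```

The report's positive ratio is the fraction of sleep windows whose
event probability cleared the calibrated threshold; the AHI estimate
is that ratio through the fitted regression, and the severity class
follows the AASM bands. `res$reports[[i]]$timeline` holds the
per-15 s awake/normal/event track for the night.

The ground-truth ("oracle") path — substituting planted window labels
for model probabilities — recovers the planted AHI of a 60-patient
synthetic cohort within ~1.2 events/h with 100% exact severity
agreement, which bounds the error introduced by windowing and the
ratio regression themselves.

A thin command-line front end ships in `inst/cli/driven.R`
(`simulate` writes a cohort as EDF + XML pairs with a ground-truth
manifest; `check` applies the exclusion criteria to a recording).

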