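---
title: "Short-term seizure prediction from two EEG channels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-term seizure prediction from two EEG channels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A few seconds before an epileptic seizure (the ictal state), many patients
with temporal-lobe epilepsy enter a brief pre-seizure state — the
*Intervention Time* (IT) — marked by weak, quasi-periodic activity of lower
amplitude and frequency than the seizure itself. Detecting the IT state from
non-invasive scalp EEG, without manual artifact removal, gives a short-term
warning that can trigger protective interventions. `itcast` implements a
patient-specific thresholding pipeline for this task, using only two
channels: the seizure-focus channel ("main") and the channel opposite the
focus ("contralateral"). It also provides a generative model of adult
epileptic EEG so the whole pipeline can be exercised, trained, and evaluated
without access to clinical recordings.

## The pipeline

Each record passes through these stages (`pipeline_features()`), and the
trained detector is an `"it_model"` returned by `it_fit()`:

1. **Preprocessing** (`preprocess_record()`). Linear detrending followed by a
   linear-phase FIR band-pass, 6–20 Hz, order 220, Hamming-window design,
   applied with group-delay compensation (reflection padding, delay removed)
   so the output is time-aligned with the input. The band keeps the
   harmonic-rich part of seizure activity and rejects slow drift and
   higher-frequency artifacts. Epoching utilities (5 s windows, 80% overlap)
   are provided for streaming delivery, but the analysis stages below run on
   the continuous filtered signal: the later 500-sample windows with 75%
   overlap could not be cut from short epochs on a consistent clock.

2. **Wavelet detail decomposition** (`detail_bank()`). A 6-level orthogonal
   Daubechies-4 DWT per channel. Each level's detail signal is reconstructed
   back to the input length (single-branch inverse with all other
   coefficients zeroed), so all 12 detail series — main D1..D6, then
   contralateral D1..D6 — share one time base. At 256 Hz the detail bands
   are D1 64–128 Hz down to D6 2–4 Hz. The six detail reconstructions plus
   the level-6 approximation sum to the input exactly, and energy is
   conserved; both properties are asserted in the tests. Approximation
   coefficients are discarded downstream.

3. **Recursive-least-squares AR estimation** (`estimate_bank()`). Each detail
   series is cut into 500-sample windows (75% overlap, hop 125) and an AR(8)
   model is estimated per window by exponentially weighted RLS (forgetting
   factor λ = 0.99, fresh state per window, `a0 = 0`, `P0 = δI` with
   δ = 0.01). The stage output is the one-step-ahead estimated signal. For
   unpredictable broadband background the predictor captures little energy;
   for quasi-periodic IT activity it locks on, so the estimate amplifies the
   periodicity contrast.

4. **First cepstrum coefficient** (`first_coefficient_series()`). Per window,
   the real cepstrum is the inverse DFT of the log magnitude spectrum, with
   a 1/N forward normalization. The first coefficient `C(0)` is the mean log
   magnitude over bins — the log *geometric mean* of the spectrum — a
   single scalar per window that rises with in-band energy. This yields 12
   scalar series on the window clock (fs/125 ≈ 2.05 Hz).

5. **Foreground/background ratios** (`ratio_bank()`). The series is squared
   and passed through a causal 1-s median (`foreground()`); the background
   (`background()`) is an exponentially forgotten (λ = 0.99) stride-sampled
   median of the foreground, updated every 0.5 s and held between updates.
   Per level, two dimensionless ratios compare current to background energy:
   main/main (outputs 1–6) and main/contralateral (outputs 7–12). Artifacts
   tend to hit one channel at a time, and genuine seizure activity is
   focal: the cross-channel ratio family exploits that asymmetry.

6. **Averaging and positive envelope** (`moving_average()`,
   `positive_envelope()`). A 2-s mean with 1-s overlap removes bursts and
   down-samples; the positive envelope interpolates a monotone
   (shape-preserving) piecewise cubic through local maxima at least 30
   samples apart, giving a smooth curve a single threshold can cut.

7. **Thresholding and voting** (`train_thresholds()`, `predict_alarms()`).
   For each of the 12 envelope outputs, candidate thresholds sweep a
   200-point quantile grid of the output's interictal values; a candidate is
   kept only if it produces *zero* interictal crossings on the training
   records, and among those the one detecting the IT period inside its
   seizure-occurrence window with the earliest latency wins. Outputs with no
   such threshold are *rejected* — expected for detail levels outside the
   6–20 Hz analysis band. At test time the record is tiled into 100-s SOP
   (Seizure Occurrence Period) windows, anchored so a boundary coincides
   with the annotated ictal onset when present; a window is flagged when at
   least `ceil(K/2)` of the K accepted outputs cross their thresholds, and
   the alarm time is the instant the quorum is met.

8. **Evaluation** (`confusion()`, `eval_metrics()`, `aggregate_reports()`,
   `prediction_time()`). SOP windows overlapping the IT-to-ictal interval
   are positive; sensitivity, specificity and accuracy are percentages of
   the confusion counts, and FPR is false predictions per interictal hour.
   Because "prediction time" admits two readings, both are reported:
   time from alarm to ictal onset, and latency from IT onset to alarm.

## The synthetic adult model

`generate_record()` follows the Celka/Roessgen lineage: interictal
background is white Gaussian noise shaped by an order-2 all-pole filter
`1/H1(z)`; seizure activity is a zero-mean periodic pulse train shaped by a
second order-2 all-pole filter `1/H2(z)` and added to the background. The
adult parameterization uses a 1.5 Hz fundamental in the ictal state and a
1 Hz fundamental at lower amplitude in the IT state (adult seizure
fundamentals lie in 0.5–10 Hz). The contralateral channel carries an
independent background realization plus the seizure component attenuated by
`contralateral_gain` (default 0.3), producing the inter-channel asymmetry
stage 5 exploits.

Defaults, chosen once:

* `h1_coeffs = c(1, -1.831, 0.846)`: complex poles, modulus 0.92, resonance
  near 4 Hz — a plausibly colored low-frequency background.
* `h2_coeffs = c(1, -1.2, 0.36)`: a double real pole at 0.6. The monotone
  low-pass response keeps the pulse-train *fundamental* the dominant
  spectral peak (a resonant H2 could promote a harmonic above it).
* Pulse shape: rectangular, 10% duty cycle, zero-mean (impulse and sawtooth
  selectable). The exact excitation waveform of the source model is not
  published; a short-duty pulse through an all-pole filter produces the
  spike-and-wave-like morphology expected of scalp seizure activity.
* Amplitudes as RMS targets: ictal = 3x background RMS, IT = 1.5x — the
  qualitative interictal < IT < ictal ordering.
* `noise_sigma = 1000`, interpreting sample units as nanovolts: background
  RMS ≈ 14.7 µV, a realistic scalp-EEG magnitude. This scale is
  load-bearing, see below.
* State transitions are cross-faded with a 0.25-s raised-cosine ramp to
  avoid switching transients that the edge-sensitive stages would amplify.

What the generator does *not* emulate: real interictal epileptiform
discharges, eye-blink/muscle artifacts, electrode pops, sleep-stage
nonstationarity, or patient-to-patient spectral diversity. A green
end-to-end test therefore establishes that the pipeline detects a
quasi-periodic amplitude-and-rhythm change against stationary colored
noise with realistic geometry — not clinical performance.

## Numerical and design choices

**Units and the sign of the squared-cepstrum response.** `C(0)` is the log
geometric mean of the spectrum, so a gain `g` on the signal shifts it by
`log g`: the feature is scale-*dependent*, and the subsequent squaring makes
the direction of its response depend on the operating point. When the
in-band log magnitudes sit above zero (µV-scale data), more seizure energy
pushes `C(0)` further from zero and the squared feature — hence the
foreground/background ratio — rises; at a much smaller scale the same
physics drives the ratio *down* and upward thresholding fails. The
generator's nanovolt units place the in-band detail levels (D2–D5) in the
rising regime, matching clinical amplitude conventions. The scale-free
index-1 coefficient is available via `cepstrum.coeff_index` for sensitivity
studies.

**Wavelet boundary handling.** Periodized extension (after reflect-padding
to a multiple of `2^levels`) keeps the transform exactly orthogonal, which
is what makes perfect reconstruction and energy conservation testable to
float tolerance. Symmetric half-point extension was considered and set
aside: its reconstruction identities are only approximate at the edges.

**Estimate vs residual.** The RLS stage forwards the one-step-ahead
estimate; the residual is available (`ar.residual_mode`) but rejected as
the default because the residual of a well-tracked periodic signal is
nearly white and erases the contrast the cepstrum needs.

**Clock conversion in the morphology stage.** The 1-s/0.5-s windows of the
foreground/background filters are converted at the *feature* rate
(≈ 2.05 Hz), with a 3-sample floor per median window — the stage consumes
the window-rate cepstrum series, where "one second at the raw sampling
rate" (256 samples) would be meaningless.

**Warm-up.** Ratios within the first 60 s of a record are emitted as `NA`
and excluded from thresholding and voting. The background needs about
`1/(1-λ)` updates (≈ 50 s) to forget its initialization, and the filter and
RLS edge transients live in the same prefix; without the mask, start-of-
record transients on a test record can cross thresholds trained on another
record's (different) transient.

**Threshold objective.** "Least error with the most appropriate delay" is
implemented lexicographically: zero interictal false crossings, then
maximal IT detections, then minimal latency. The grid sweep keeps the
search faithful to a threshold *selection* procedure rather than an
analytic maximum, at negligible cost.

**Quorum rounding.** "Half the outputs" with the worked 7-to-4 example
fixes `ceil(K/2)`.

**Degenerate inputs.** All-zero cepstrum windows (undefined log spectrum)
yield `NA` with a warning; near-zero background denominators (< 1e-12)
yield `NA`; spectral magnitudes are floored at `1e-12 x max` before the
log; an envelope with fewer than two peaks falls back to the series itself
with a warning; RLS aborts with a diagnostic if the inverse-correlation
update loses positive definiteness.

**AIC on white noise.** The order-selection table reports
`AIC = N log σ² + 2p` and `FPE = σ²(N+p)/(N−p)` from Burg fits. On white
noise the AIC-minimizing order is 1–2 in most, but not ≥ 90%, of trials
(AIC's overfitting tendency is well documented); the test suite asserts
the distributional fact actually observed (median ≤ 2, ≥ 70% of trials).

## Worked example

```{r}
library(itcast)

params <- seizure_model_params(seed = 1)
schedule <- default_schedule()           # IT at 1000 s, ictal at 1030 s
train <- generate_record(params, schedule)
test <- generate_record(seizure_model_params(seed = 2), schedule)

model <- it_fit(train)
model                     # accepted outputs, thresholds, quorum
pred <- predict(model, test)
pred$alarm_times          # first alarm should precede 1030 s
it_evaluate(pred)
```

## Known limitations

* Detection rests on a max-type statistic (training-interictal envelope
  maximum); on an independent record, correlated outputs occasionally
  exceed their thresholds jointly during interictal data, producing an
  early false alarm in a minority of seeds. More training records tighten
  the thresholds (`it_fit()` accepts a list).
* The two channels must be chosen manually; no seizure-focus localization
  is attempted.
* EDF files are not read or written; records move through the documented
  CSV dialect with JSON/CSV sidecars.
* The evaluation counts a flagged all-ictal window as a false positive,
  following the strict "positive = overlaps the IT-to-ictal interval"
  definition; with long post-onset data this understates specificity.
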