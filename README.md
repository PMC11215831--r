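# itcast

Patient-specific short-term prediction of epileptic seizures from two scalp
EEG channels. The package detects the brief pre-seizure *Intervention Time*
(IT) state — weak quasi-periodic activity appearing seconds before ictal
onset in temporal-lobe epilepsy — so that a warning can be raised before the
seizure itself, using non-invasive recordings with artifacts left in.

## Who it is for

Researchers in biomedical signal processing and epileptology who want a
self-contained, testable implementation of a threshold-based (rather than
classifier-based) seizure prediction pipeline, together with a generative
model of adult epileptic EEG for experiments without clinical data.

## Method

Two channels are analyzed: the seizure focus (main) and the channel opposite
it (contralateral). For each record:

1. linear detrend + linear-phase FIR band-pass 6–20 Hz (order 220, Hamming);
2. 6-level Daubechies-4 wavelet decomposition per channel; the 12 detail
   signals D1..D6 x {main, contra} are reconstructed to the full time base;
3. each detail series is windowed (500 samples, 75% overlap) and an AR(8)
   model is tracked per window by recursive least squares
   (forgetting factor 0.99): `x_k = phi_k' a + e_k`, with the one-step-ahead
   estimate as the stage output;
4. per window, the first real-cepstrum coefficient
   `C(0) = mean_k log|X(k)|` (inverse DFT of the log magnitude spectrum at
   quefrency 0) compresses each window to one scalar;
5. the squared series is compared against its own history:
   foreground `FG_k = median(y_k^2, ..., y_{k-q+1}^2)` (causal 1-s median)
   and background `BG_k = (1-lambda) median(FG_k, FG_{k-s}, ...) +
   lambda BG_{k-1}` (exponentially forgotten, lambda = 0.99), giving 12
   dimensionless ratios `FG(main)/BG(main)` and `FG(main)/BG(contra)` per
   wavelet level;
6. a 2-s moving average and a positive envelope (monotone cubic through
   local peaks) prepare each ratio for thresholding;
7. per output, a patient-specific threshold is accepted only if it crosses
   during the IT period with *zero* interictal crossings on training data;
   at test time, 100-s Seizure Occurrence Period (SOP) windows are flagged
   when at least `ceil(K/2)` of the K accepted outputs cross, and the alarm
   is the instant the quorum is met.

Performance is reported as sensitivity, specificity, accuracy (percent over
SOP windows) and false predictions per interictal hour, plus per-seizure
prediction times.

The bundled generative model (Celka/Roessgen lineage, adult
parameterization) sums colored background noise (white noise through an
order-2 all-pole filter `1/H1(z)`) with a shaped periodic pulse train
(through `1/H2(z)`): fundamental 1.5 Hz in the ictal state, 1 Hz at lower
amplitude in the IT state, attenuated on the contralateral channel.

## Worked example

```r
library(itcast)

params <- seizure_model_params(seed = 1)        # adult model, nanovolt units
schedule <- default_schedule()                  # interictal 0-1000 s, IT to 1030 s, ictal to 1100 s
train <- generate_record(params, schedule)
test  <- generate_record(seizure_model_params(seed = 2), schedule)

model <- it_fit(train)
model
#> <it_model> patient synthetic: 8/12 outputs accepted, quorum 4, SOP 100 s
#>   thresholds: r1_D2=5.37, r1_D3=1.57, r1_D4=1.46, r1_D5=1.58, r2_D2=4.42,
#>   r2_D3=1.6, r2_D4=1.56, r2_D5=1.68

pred <- predict(model, test)
min(pred$alarm_times)
#> [1] 1007.812
```

The eight accepted outputs are the ratio series built on detail levels
D2–D5 — the levels whose bands intersect the 6–20 Hz analysis band — for
both the main/main and main/contralateral comparisons; levels D1 and D6
carry no usable in-band contrast and are rejected by training. On the
independent test record the first alarm fires at 1007.8 s: 7.8 s after the
true IT onset (1000 s) and 22.2 s before ictal onset (1030 s).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script regenerates synthetic records from scratch (schedule above),
trains on one seeded record and predicts on an independent one, repeats
over 10 seed pairs, and writes the median first-alarm time in seconds as a
JSON report.
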