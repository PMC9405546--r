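---
title: "Estimating blood pressure from PPG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood pressure from PPG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bpnet)
```

## The problem

Invasive arterial blood pressure (ABP) monitoring gives a continuous pressure
waveform, and each cardiac cycle's maximum and minimum are the systolic (SBP)
and diastolic (DBP) pressures. A fingertip photoplethysmogram (PPG) measures
the same pulse wave optically and non-invasively, but in arbitrary optical
units with no absolute pressure level. `bpnet` implements a signal-to-signal
approach to cuffless blood pressure estimation: a one-dimensional
encoder-decoder network is trained to map a 256-sample PPG window (about 2 s
at 125 Hz) to the concurrent ABP window, and SBP/DBP are then read off the
predicted waveform by ordinary peak detection, with the mean arterial
pressure defined as

$$\mathrm{MAP} = \tfrac13\,\mathrm{SBP} + \tfrac23\,\mathrm{DBP}.$$

The network is a *Squeeze U-net*: a U-net whose convolutional blocks are
SqueezeNet fire modules. A fire module squeezes the channel dimension with a
1-wide convolution ($s_{1\times1}$ filters), then expands it with parallel
1-wide and 3-wide convolutions ($e_{1\times1}$ and $e_{3\times1}$ filters,
concatenated; the squeeze width is kept strictly below
$e_{1\times1}+e_{3\times1}$). This keeps the parameter count an order of
magnitude below a plain U-net, which is what makes per-second streaming
inference on modest hardware realistic.

## Pipeline assumptions

The method assumes (i) paired PPG/ABP training data sampled at 125 Hz,
(ii) a quasi-constant transit delay between the two channels within a
record, removable by a single integer-lag cross-correlation alignment,
(iii) pulsatile information in 0.5–8 Hz, everything outside being noise for
the PPG channel, and (iv) min–max normalization with *cohort-wide* constants
so that absolute pressure level is learnable from amplitude cues. The
shipped deployment constants are PPG $-2.4$ / $2.9$ mV and ABP $50.33$ /
$192.24$ mmHg; a training run fits its own constants from the accepted
training segments and persists them with the model, since denormalizing
predictions with anything else would silently re-scale pressures.

## The synthetic cohort

There is no clinical data in this package; every stage is exercised on a
generator whose output carries exact per-beat ground truth:

* **ABP**: each beat is $\mathrm{DBP} + (\mathrm{SBP}-\mathrm{DBP})\,s(t)$
  with $s(t)$ a fixed unit-peak pulse shape — a systolic lobe (peak at 30 %
  of the beat) plus a dicrotic bump (relative amplitude `dicrotic_frac`,
  default range 0.1–0.35 across subjects). The shape has an exact unit
  maximum and zero baseline, so the per-beat extrema equal the requested
  pressures by construction. Beat intervals are jittered by ±5 % (uniform)
  to emulate heart-rate variability; this also removes the exact
  periodicity that would otherwise make cross-correlation lags ambiguous at
  multiples of the beat period.
* **PPG**: a fixed cohort-wide affine map of ABP into the $[-2.4, 2.9]$ mV
  convention, smoothed by a symmetric (zero-phase) Gaussian kernel of 20 ms,
  delayed by `ppg_lag_samples` (default 25 samples = 200 ms, emulating the
  brachial-to-digital transit delay) and corrupted by additive white noise
  (default SD 0.05 mV).
* **Cohort**: subjects are apportioned across four hypertension stages
  (largest-remainder rounding of the stage mix) and draw SBP/DBP uniformly
  from JNC7-style stage ranges — normal 95–119/60–79, prehypertension
  120–139/80–89, stage 1 140–159/90–99, stage 2 160–190/100–110 mmHg.

What this emulates well: sampling rate, amplitude conventions, inter-channel
lag, beat-to-beat timing variability, the full SBP/DBP range. What it does
not emulate: real PPG morphology variation between subjects, motion
artifacts beyond additive noise, baseline wander, arrhythmias, or any
physiological decoupling between waveform shape and pressure. Passing tests
on this cohort therefore validate the *pipeline mechanics* (alignment,
normalization bookkeeping, architecture, optimization, estimation,
grading), not clinical accuracy; the DBP level in particular is only
recoverable here because pulse amplitude and pressure are correlated by
construction, a much easier situation than real data.

## Preprocessing choices

* **Filter**: the PPG (only) is bandpass filtered to 0.5–8 Hz. The filter is
  a symmetric linear-phase FIR with transition bands 0.25→0.5 Hz and
  8→10 Hz, ≥40 dB stopband attenuation and ≤1 dB passband ripple. At these
  transition widths the required order is ≈1900 taps; the Parks–McClellan
  exchange is numerically degenerate at such orders in double precision, so
  the design uses a Kaiser window at the order implied by the narrowest
  transition, *measures* the realized response on a dense grid, and grows
  the order until the template is met (an error reports the achieved
  attenuation if it cannot be). The design's group delay is exactly
  $(n_\mathrm{taps}-1)/2$ samples.
* **Phase handling**: filtering is causal (forward-only) in both the offline
  and streaming paths, so train-time and deploy-time filtering are the same
  operator. Offline, the known integer group delay is compensated before
  alignment; the remaining transit delay is estimated once per record as the
  argmax of the normalized cross-correlation over ±125 samples (ties break
  toward zero lag; an estimate at the search bound is flagged
  low-confidence). Per-record rather than per-segment alignment reflects the
  quasi-constant transit delay.
* **Segmentation**: non-overlapping 256-sample windows, tail dropped.
* **Quality screening**: a pluggable rule-based screen stands in for a
  trained artifact classifier: reject flat windows (SD below 0.01), clipped
  windows (≥25 consecutive samples at the window extreme), and windows whose
  prominent-pulse count implies a rate outside 30–180 beats/min. Prominent
  pulses are counted in the upper half of the window's range with ≥0.25 s
  spacing so that sub-mmHg noise ripples do not inflate the rate.
* **Shuffling** is seeded and happens at segment level before the
  70/15/15 split, so segments of one subject can appear in different
  partitions; `train_config(subject_split = TRUE)` provides the
  leakage-free alternative and is the mode a clinical evaluation should use.

## The network, exactly

For a 256-sample window (lengths, channels after each stage):

| Stage | Operation | Output |
|---|---|---|
| CB1 | conv k3 stride 2, 64 filters | 128 × 64 |
| CB2 | max-pool 2 | 64 × 64 |
| CB3 | fire(16,64,64) ×2, max-pool | 32 × 128 |
| CB4 | fire(32,128,128) ×2, max-pool | 16 × 256 |
| CB5 | fire(48,192,192) ×2, fire(64,256,256) ×2, dropout | 16 × 512 |
| neck | tconv k2 s1 ×192, concat(16×384), fire(48,192,192); tconv k2 s1 ×128, concat(16×256), fire(32,128,128) | 16 × 256 |
| EB1 | tconv k2 s2 ×64, concat(32×128), fire(16,64,64) | 32 × 128 |
| EB2 | tconv k2 s2 ×32, concat(64×64), fire(16,32,32) | 64 × 64 |
| EB3 | upsample ×2, concat(128×64), conv k3 ×64 | 128 × 64 |
| EB4 | upsample ×2, conv k3 ×1 | 256 × 1 |

Leaky-rectifier activation (negative slope 0.3, configurable) follows every
convolution, including the output; same-padding everywhere; all
convolutions carry biases. Total downsampling is ×16 (one stride-2
convolution, three pools), matched by ×16 upsampling, so the decoder
restores any window divisible by 16 — this length closure is asserted at
build time.

Design points that were genuinely open, and how they were settled:

* **Pooling placement.** A reading with a fourth max-pool in front of CB5
  cannot return to 256 samples given stride-1 bottleneck transposes and four
  ×2 decoder upsamplings; the three-pool layout above is the unique wiring
  consistent with the printed per-block lengths and channel totals
  (128 → 64 → 32 → 16, and concatenation totals 576/384/192/96).
* **Transposed-convolution filter counts** (192, 128, 64, 32) are implied by
  the printed post-concatenation channel totals and the known skip sources.
* **EB3 filter count** is not printed; 64 keeps the decoder symmetric with
  CB1 and is the default here.
* **Upsampling mode** in EB3/EB4 is parameter-free nearest-neighbour,
  distinct from the learned transposed convolutions of EB1/EB2.
* **Parameter-count reconciliation.** The layout above, with biases, counts
  818,321 trainable parameters, reproduced independently in the tests by
  per-layer enumeration. The published total for this architecture is
  819,921 — 1,600 more, which no combination of kernel-width, filter-count
  or bias conventions reaches exactly. 1,600 equals one scale and one offset
  per channel over 800 channels, so the shipped `variant = "reconciled"`
  closes the gap with trainable per-channel scale-and-offset (affine
  normalization) layers at three decoder-entry points: after the deepest
  encoder fire stack (512 channels), after the decoder-junction fire (256)
  and after the EB2 transposed convolution (32). They initialize to the
  identity and do not change the forward function at initialization.
  `variant = "canonical"` builds the plain layout; both totals are asserted
  in the test suite.
* **Dropout rate** (0.5) and **leaky slope** (0.3) are unstated upstream;
  both are config-exposed and have no effect on the parameter count.

The forward pass, backpropagation and Adam are implemented in-package on
dense BLAS matrix operations (im2col convolutions); analytic gradients are
verified against central finite differences on a mixed-layer graph in the
test suite.

## Training protocol

Segment-level 70/15/15 split after a seeded shuffle; Adam with learning rate
$10^{-4}$, moment decays 0.9/0.999, epsilon $10^{-7}$; batch size 10; mean
squared error on normalized windows; early stopping after 6 consecutive
epochs without validation improvement (min-delta 0, i.e. any strict decrease
counts — the natural reading when no threshold is given); the best-epoch
weights are checkpointed and restored. Everything is driven by one global
seed that fans out to per-stage seeds, so stages are independently
reproducible; two runs with the same configuration produce identical loss
traces.

Desk scale: the bundled experiments train on a 24-subject × 180 s synthetic
cohort (≈2,000 accepted segments) for at most 10 epochs, which takes a few
minutes on one CPU and reaches a synthetic test-set SBP mean absolute error
under 10 mmHg. Cohort-scale accuracy figures (clinical MAE near 4–5 mmHg)
require real multi-subject waveform data and longer training, and are
explicitly not something the synthetic pipeline claims to reproduce.

## Estimation and grading

Predicted windows are denormalized with the stored constants, then systolic
peaks and diastolic troughs are detected: plateau-aware local extrema, a
minimum spacing of 42 samples (180 beats/min at 125 Hz), a minimum
prominence of 10 mmHg, a mid-range height gate (peaks in the upper half of
the window's range, troughs in the lower half — this keeps large dicrotic
bumps out of the systolic set when pulse pressure exceeds about 50 mmHg),
and an alternation pass that drops the lesser of two adjacent same-kind
extrema. A window's SBP/DBP aggregate the peak/trough values by mean
(configurable to max/min); windows with no usable beat are flagged invalid
rather than erroring. Feeding reference ABP windows through this stage
recovers the generator's truth within ±1 mmHg.

Evaluation implements the field's standard battery: ME/MAE/STD/RMSE and
Pearson's r (population-SD convention, so
$\mathrm{RMSE}^2=\mathrm{ME}^2+\mathrm{STD}^2$ holds exactly); BHS grading
(A = 60/85/95 % of absolute errors within 5/10/15 mmHg, B = 50/75/90,
C = 40/65/85, else D); the AAMI criterion ($|\mathrm{ME}|\le5$,
$\mathrm{STD}\le8$ mmHg, ≥85 subjects — the absolute-value reading is
required for a negative printed mean error to pass, and the subject count
refers to people, not windows, so evaluation carries subject ids);
four-stage hypertension classification with the JNC7-style thresholds
above; and Bland–Altman bias with $\pm1.96$ population-SD limits of
agreement.

## Streaming

Deployment consumes a PPG stream only. A 30 Hz feed (the rate of a phone
camera) is linearly interpolated onto the 125 Hz grid (sample $k$ at time
$k/\mathrm{rate}$; $n$ input samples yield $\lfloor 125n/30\rfloor$ outputs,
never past the last received sample). Each 125 Hz sample passes through a
persistent FIR delay line holding the training-phase coefficients — the
streaming output equals causal batch filtering sample-for-sample — into a
256-sample ring buffer. Once the buffer first fills (≈2 s plus the filter's
group delay of warm-up), and then after every 125 accepted samples, the
current window is normalized, forwarded, denormalized and summarized, giving
one SBP/DBP/MAP triple per second on overlapping windows. No alignment and
no ABP are involved at deployment; values outside $[0,1]$ after
normalization pass through unclipped, consistent with the offline path.

## Numerical notes and limitations

* Offline filtering uses FFT convolution; streaming uses direct dot
  products. They agree to well below $10^{-9}$, which the tests assert on
  $10^4$-sample inputs.
* Normalization maps outside values outside the constants' range outside
  $[0,1]$ without clipping; degenerate constants error out.
* Cross-correlation lags are exact integers; sub-sample transit delays are
  not modelled (the generator injects integer lags).
* The in-package network trains single-threaded on CPU at roughly 0.2 s per
  batch of ten windows; it is a faithful, test-covered implementation, not a
  performance-tuned framework.
* `fit_constants` is deliberately strict: a constant training channel is an
  error, since min–max normalization is undefined there.
* Bundled experiment sizes (cohort of 24 × 180 s, ≤10 epochs, ~2,000
  segments) were chosen as the smallest configuration on which the training
  signal is unambiguous (validation MSE falls by an order of magnitude and
  SBP MAE comfortably clears 10 mmHg); they are the package's reference
  conditions for the bundled checks.
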