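# bpnet — cuffless blood pressure estimation from PPG with a 1D Squeeze U-net

Continuous blood pressure is normally measured invasively, as an arterial
blood pressure (ABP) waveform whose per-beat maxima and minima are the
systolic (SBP) and diastolic (DBP) pressures. A fingertip photoplethysmogram
(PPG) carries the same pulse wave optically and non-invasively. `bpnet`
implements, end to end, a signal-to-signal approach to estimating blood
pressure from the PPG alone:

1. **Preprocess**: bandpass the PPG to 0.5–8 Hz with a linear-phase FIR,
   phase-match PPG and ABP by cross-correlation, cut non-overlapping
   256-sample windows (≈2 s at 125 Hz), screen for artifacts, and min–max
   normalize with cohort-wide constants
   (x_norm = (x − x_min) / (x_max − x_min)).
2. **Regress**: map each normalized PPG window to an ABP-like window with a
   1D *Squeeze U-net* — a U-net encoder–decoder whose convolutional blocks
   are SqueezeNet *fire modules* (1-wide squeeze convolution of s₁ₓ₁
   filters feeding parallel 1-wide and 3-wide expands of e₁ₓ₁ and e₃ₓ₁
   filters, concatenated). The reconciled build has exactly **819,921**
   trainable parameters; training uses Adam (lr 10⁻⁴, batch 10, MSE) with
   early stopping on validation loss.
3. **Estimate**: denormalize the prediction with the constants stored at
   training time, detect systolic peaks and diastolic troughs, and compute
   MAP = ⅓ SBP + ⅔ DBP.
4. **Grade**: ME/MAE/STD/RMSE/Pearson-r error statistics, British
   Hypertension Society cumulative-error grades, the AAMI
   (|ME| ≤ 5, STD ≤ 8 mmHg, ≥ 85 subjects) criterion, four-stage
   hypertension classification and Bland–Altman agreement.
5. **Stream**: a real-time loop takes 30 Hz samples (a phone-camera rate),
   interpolates to 125 Hz, filters through a persistent delay line with the
   training-phase coefficients, and emits one SBP/DBP/MAP triple per second
   from a sliding 256-sample queue.

No clinical data ship with the package: a seeded waveform simulator
generates paired PPG/ABP cohorts spanning the four hypertension stages with
exact per-beat ground truth, so the whole pipeline is reproducible and
testable on one CPU. It targets signal-processing and digital-health
researchers who want a transparent, dependency-light reference
implementation of this estimation pipeline.

## Worked example

The default configuration is the package's reference experiment: a
24-subject × 180 s synthetic cohort (≈2,000 accepted segments), at most 10
training epochs. It runs in a few minutes on one CPU:

```r
library(bpnet)

model <- build_network(network_spec())
model
#> <1D Squeeze U-net: window 256, reconciled variant, 819,921 parameters>

res <- run_pipeline(load_config(NULL), verbose = TRUE)
#> simulating 24 subjects x 180s
#> preprocessed: 2003 accepted segments
#> training 819,921 parameters
#> test SBP MAE: 7.86 mmHg

res$report
#> <training report: 10 epochs (best 8, val MSE 0.00329)>
res$evaluation
#> <evaluation: 301 windows, 24 subjects>
#>   SBP: MAE 7.86, ME -4.40, STD 9.82, RMSE 10.77, r 0.917 | BHS C | AAMI failed
#>   DBP: MAE 5.44, ME -2.80, STD 6.23, RMSE 6.83, r 0.866 | BHS B | AAMI failed
#>   MAP: MAE 5.72, ME -3.34, STD 6.60, RMSE 7.40, r 0.912 | BHS B | AAMI failed
```

Reading the output: validation MSE (on normalized windows) fell from 0.0078
at epoch 1 to 0.0033 at the checkpointed epoch 8; on held-out windows the
predicted systolic pressure is off by 7.9 mmHg on average with r = 0.92
against the reference. A desk-scale run like this demonstrates that the
pipeline learns and by how much — clinical-grade accuracy (BHS grade A,
AAMI pass) is a property of cohort-scale training on real waveforms, not
something a 10-epoch synthetic run claims.

Streaming with the trained model (first emissions during the ≈9.5 s filter
and buffer warm-up are flagged invalid):

```r
fir <- design_bandpass(preprocess_config())
st  <- stream_init(res$model, fir)
rec <- generate_cohort(1, cfg = sim_config(duration_s = 40, seed = 123))[[1]]
round(rec$truth$sbp[1], 1); round(rec$truth$dbp[1], 1)
#> 103.3
#> 68
tail(round(run_stream(st, rec$ppg), 1), 3)
#>    t_s   sbp  dbp  map n_beats valid
#> 36  37 106.4 70.4 82.4       2     1
#> 37  38 105.3 71.0 82.4       2     1
#> 38  39 105.6 71.4 82.8       2     1
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/bpnet.R simulate --subjects 4 --duration 60 --seed 1 --out waves
Rscript inst/cli/bpnet.R model-summary
```

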