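---
title: "Prolonged S-ICD screening from PSR images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prolonged S-ICD screening from PSR images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicdscreen)
```

## The screening problem

Eligibility for a subcutaneous implantable cardioverter-defibrillator
(S-ICD) hinges on the surface-ECG morphology sensed along the device's
three subcutaneous vectors (primary, alternate, secondary). The leading
cause of screening failure — and of inappropriate shocks after implant —
is a large T:R ratio, the T-wave amplitude divided by the R-wave amplitude
within a beat: when T approaches R in size, the device can double-count
T waves as R waves (T-wave oversensing). Conventional screening samples a
few 10-second strips on a single day, but the T:R ratio is dynamic; a
vector that passes at the clinic can fail hours later.

`sicdscreen` implements a prolonged screening pipeline: a 24-hour,
three-channel Holter recording (channels positioned as surrogates of the
three S-ICD vectors) is split into 10-s segments, each segment is
conditioned and converted into a 32×32 phase-space-reconstruction (PSR)
image, a compact convolutional regressor maps each image to a T:R
estimate, and the per-vector T:R series is summarized into eligibility
statistics: the fraction of segments with unfavourable T:R (> 1:3), the
mean/median/SD of T:R, and Welch comparisons between groups.

## Pipeline stages and their parameters

### Segmentation

Recordings are sampled at 500 Hz and cut into contiguous, non-overlapping
10-s windows; a trailing partial window is discarded, so a 24-h recording
yields exactly 8640 segments per channel — the denominator of the failure
probability. Padding the last window would silently alter that
denominator, which is why truncation was chosen.

### Conditioning

Three deterministic, length-preserving stages per segment, in order:

1. **Baseline drift.** The baseline is estimated by a two-stage running
   median (200 ms then 600 ms windows) and subtracted. The 200 ms stage is
   longer than a QRS complex, the 600 ms stage longer than a T wave, so
   the estimate tracks wander (respiration, electrode motion, ~< 0.5 Hz)
   while leaving R and T amplitudes essentially untouched (< 5% change on
   clean beats). Median filtering was preferred to a high-pass filter
   because it introduces no ringing around the QRS.
2. **Mains interference.** The interference frequency is located as the
   periodogram peak within a 45–55 Hz search band (the "adaptive" part —
   mains and recorder clocks drift), and a second-order IIR notch
   (Q = 30, ~1.7 Hz bandwidth at 50 Hz) is placed there and run
   forward-backward. A 10-s segment gives 0.1 Hz spectral resolution, far
   finer than the notch bandwidth. When the band holds no distinct peak
   the notch sits at the nominal 50 Hz; it passes DC and changes the
   ≤ 40 Hz passband by less than 1 dB.
3. **Residual high-frequency noise.** A 4th-order Butterworth low-pass at
   40 Hz, forward-backward (zero phase, 8th-order magnitude). R- and
   T-wave energy lies below 40 Hz (a Gaussian R wave of 12 ms width has
   its spectral mass below ~30 Hz), so fiducial amplitudes move by well
   under 2%.

All forward-backward filters use reflection padding (1 s) so segment edges
carry no transients. All cutoffs, orders and windows are configurable via
`filter_config()`.

### Phase-space reconstruction

Each conditioned segment `x` is delay-embedded in two dimensions as the
trajectory `(x[t], x[t + τ])` and rasterized into a 32×32 occupancy grid —
one image per segment. Choices that were genuinely open, and how they were
fixed:

- **Delay τ = 10 samples (20 ms).** Short enough that the fast QRS limb
  opens into a wide loop, long enough that the slow T loop separates from
  the baseline cluster; within the range commonly used for ECG delay maps.
  It is a `psr_config()` knob, not a constant.
- **Per-segment min-max amplitude bounds before binning.** The quantity to
  be learned is a *ratio*, which is invariant to overall gain; per-segment
  bounds make the image exactly invariant to amplitude scaling (tested as
  a property), so the regressor cannot shortcut via absolute voltage.
- **Binning:** half-open bins with the top edge closed; in counts mode the
  grid total equals the number of embedded pairs exactly (conservation is
  a test oracle).
- **Normalization:** sum-to-one for model input (segments of different
  heart rates produce comparable mass), counts retained for the
  conservation tests; max-to-one offered for visualization.
- **Degenerate (flat) segments** have no amplitude range: all mass is
  assigned to cell (1,1) and the segment is flagged low-quality; it is
  excluded from training and carries a missing prediction downstream
  rather than a fabricated ratio.

### The two T:R estimators

**Rule-based oracle.** A fiducial-peak measurement standing in for manual
calipers, used to label and validate the image model. R peaks come from an
energy detector (5–25 Hz band-pass, squaring, 150 ms integration, adaptive
threshold at a quarter of the 99th envelope percentile, 300 ms
refractory). Amplitudes are measured from a local isoelectric baseline —
the median of the 80 ms window ending 50 ms before the R peak — because a
fixed global zero is meaningless after any filtering. The T peak is the
largest absolute deflection from that baseline in the window from 80 ms
after R to `min(400 ms, 0.6·RR)`; the segment T:R is the **median** of
per-beat ratios (robust to one mis-detected T wave). Segments with fewer
than five acceptable beats are flagged invalid, not errored. On zero-noise
synthetic data the oracle recovers the programmed T:R within ±0.02
essentially everywhere (a tested property).

**Convolutional regressor.** Two 3×3 convolution blocks (16 then 32
feature maps, ReLU, 2× average pooling), a 64-unit dense ReLU layer, and a
scalar linear output clamped at zero at prediction time. This is the
smallest architecture we found that learns the ratio to well under the
0.046 MAE working point while remaining CPU-trainable in minutes. The
network is implemented directly in vectorized R (im2col gathers feeding
BLAS matrix multiplies); its gradients are verified against finite
differences in the test suite, and the forward pass against a naive loop
convolution. Training uses squared-error loss and Adam (learning rate
1e-3, batch 128, 10 epochs by default); inputs are standardized by the
global pixel mean/SD of the training set, stored in the model. Given the
seed, fitting is bit-reproducible.

**Cross-validation.** 10-fold, with fold assignment stratified by label
quantile under a fixed seed: consecutive rank blocks of 10 each scatter
one segment into every fold, so each fold spans the label range. Metrics
(MSE, RMSE, MAE) are reported per fold and pooled over all held-out
predictions; `RMSE = sqrt(MSE)` per evaluation call by construction. The
pooled MAE is the headline accuracy figure; at the package's default
operating point (2000 clean synthetic segments with T:R uniform on
0.05–0.8, 10 epochs) it sits near 0.02–0.03, comfortably under the 0.046
working ceiling asserted in the acceptance tests.

### Screening statistics

A segment is unfavourable when its T:R **strictly exceeds** 1/3 (a value
exactly at the cut-off passes, mirroring the "> 1:3" rule). The failure
probability divides the unfavourable count by the **total** segment count
of the recording (8640 for 24 h): that is the published formula's
denominator, so invalid segments count in the denominator but never in the
numerator; a valid-only denominator is available behind
`denominator = "valid"` for sensitivity analyses. Probabilities are
printed rounded half-away-from-zero to two decimals, with raw values below
0.005 shown as `"<0.01"` but retained unrounded internally. Summaries use
the sample (n−1) SD. Group contrasts use the Welch unequal-variance
t-test with Satterthwaite degrees of freedom (two-sided, 95% CI), the
conventional choice when cohort variances differ — as they do here, since
distorted-waveform cohorts both shift and spread the T:R distribution.
The unit of analysis for cohort contrasts is the vector (three rows per
subject), matching how per-vector summaries are tabulated; per-subject
aggregation is a one-line `aggregate` away from the tidy outputs.

## The synthetic generator: what it emulates, and what it does not

No Holter data are distributed, so validation rests on a generator with
exact ground truth. Beats are sums of five Gaussian waves (P, Q, R, S, T);
the analytic form makes the programmed T:R exact: the T-wave amplitude is
set beat-by-beat to `T:R × R amplitude`. Defaults: R = 1.0 mV (width
12 ms), T centred 300 ms after R (width 60 ms), P/Q/S at conventional
small amplitudes; 60 bpm mean heart rate with i.i.d. Gaussian inter-beat
jitter (SD 40 ms) clipped at 300 ms so beats never overlap. The T:R
trajectory is programmed per 10-s segment — constant, piecewise, or
diurnal-sinusoidal plus AR(1) jitter (φ = 0.9) to emulate slow
fluctuation, the phenomenon prolonged screening exists to catch. Noise
terms: sinusoidal baseline wander (0.15 mV at 0.25 Hz, respiration-like),
50 Hz mains (0.05 mV), and white noise (0.02 mV SD). Per-channel gains
(1.0, 0.8, 0.9) differentiate the three vector surrogates without
changing their T:R; optional per-channel T-wave gains let vectors disagree
on eligibility, as real vectors do.

These defaults were chosen once for testability and plausibility — the
source cohort's waveform statistics beyond T:R summaries are unknown — and
the generator deliberately omits: arrhythmia, ectopy and conduction
abnormalities; posture- and activity-driven morphology shifts; electrode
motion artifacts and disconnects; QRS-morphology screening criteria other
than T:R. Consequently, passing tests demonstrate that the pipeline
measures what it claims on signals whose truth is known — not that the
trained regressor transfers to real patients. Real-cohort group statistics
are therefore exercised as *capability* (a seeded two-cohort synthetic
experiment — six high/fluctuating-T:R subjects vs seven low/stable ones,
one hour each — must separate at p < 0.05), not reproduced numerically.
In that experiment the regressor is trained on segments generated under
the same noise conditions as the cohort recordings; training on noiseless
segments and deploying on noisy ones is a domain shift the small model
does not survive, which is worth remembering before applying any model of
this kind across acquisition conditions.

## Numerical and edge-case policy

- Filters are deterministic and length-preserving; zero in, zero out.
- A segment shorter than the largest drift window, or not longer than the
  embedding delay, is a degenerate-input error; a record shorter than one
  window segments to an empty list (not an error).
- Too few beats → invalid flag, never an exception; invalid segments are
  excluded from training, gapped in plots, and counted only in the failure
  probability's denominator.
- Rounding of reported probabilities is half-away-from-zero (base R's
  `round` is half-to-even, which does not match how such tables are
  printed).
- All stochastic steps (generator, fold assignment, weight initialization,
  batch order) consume explicit integer seeds; identical seeds give
  bit-identical recordings, folds and fits.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on synthetic
data at sizes chosen to exercise every published operating point while
staying desk-scale: the regressor's cross-validated accuracy is measured
on 2000 clean segments (≈ 5.6 h of signal) at 10 epochs; the two-cohort
experiment uses thirteen 1-h recordings; segmentation arithmetic is
checked on a full 24-h, three-channel recording. Larger runs change
nothing structurally — a 24-h screening of one subject is 8640 segments
per vector through exactly the same functions.

## Known limitations

- The regressor is validated on the generator's beat family; morphologies
  far outside it (bundle-branch block, paced rhythms, deep negative T
  waves larger than R) are unrepresented.
- The oracle measures the largest absolute T deflection; biphasic T waves
  are summarized by their dominant limb.
- The adaptive notch assumes a single dominant interference line within
  45–55 Hz; 60 Hz mains requires reconfiguring `filter_config()`.
- Screening considers T:R only — the major, but not the only, determinant
  of S-ICD eligibility.
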