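---
title: "Methods: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cvautonomics` re-implements, as a tested pipeline, the cardiovascular
autonomic analysis of an anesthetized-rat doxorubicin dose-response study:
beat detection on ECG and arterial pressure, wavelet LF/HF variability,
pharmacologically provoked baroreflex and chemoreflex quantification,
picrosirius-red collagen quantification, and the group-statistics layer.
Because the original animal-level recordings are not deposited, the package
ships a synthetic-data generator calibrated to the published group
statistics; every analysis stage is validated by recovering the generator's
known ground truth. This vignette records the models, the calibrated
constants, and the choices made where the design was genuinely open.

## The synthetic world

Each study arm (CTL saline control; DOX8, DOX16, DOX20 cumulative
doxorubicin doses of 8/16/20 mg/kg) is parameterized by the published group
means: heart rate, systolic/diastolic pressure, baroreflex gain,
chemoreflex delta, LF/HF ratio, HF power, collagen fraction and urinary
catecholamines. Between-subject spread is reconstructed from the published
standard errors as `SD = SEM * sqrt(n)` (the study reports mean ± SEM at
n = 6 control, n = 8 per treated arm).

Three published values required decisions:

* The DOX8 arm's printed diastolic and mean pressures equal its systolic
  pressure (136/136/136), an evident copy error. The generator keeps the
  printed systolic 136 mmHg and interpolates diastolic at 97.5 mmHg, the
  midpoint of the neighbouring arms (CTL 111, DOX16 84).
* No DOX8 heart rate is printed (the comparison was "not significant").
  The generator uses 360 bpm — between CTL (379) and DOX16 (290), closer
  to CTL, consistent with a non-significant difference at SEM ≈ 22.
* Per-group HF power is printed only for CTL (1.13) and DOX20 (22.23).
  The other arms reuse the CTL value, and each arm's LF power is derived
  as `LF/HF target × HF power`. The printed per-group LF/HF means, the
  printed HF values, and the "LF unchanged" narrative are mutually
  inconsistent (means of ratios versus ratios of means); the generator
  privileges the printed HF and LF/HF values.

Basal respiratory frequency is not printed at all ("no changes in
respiratory rate"); 60 cycles/min is used for every arm — typical for a
pentobarbital-anesthetized rat — with the stimulated rate at basal plus the
arm's printed chemoreflex delta.

### Signal model

The ECG is a train of 1 mV Gaussian R waves (8 ms width) whose
instantaneous rate is `HR + A_HF sin(2π·1.2 Hz·t)` plus per-beat noise;
beat times come from inverting the integrated rate. Arterial pressure is a
train of beat-synchronous pulse waves: within each beat the shape is a
normalized Beta(2.5, 4.5) density-like curve (fast systolic upstroke
peaking 30% into the beat, diastolic runoff to the diastolic level). Its
time-average, 0.455 of pulse pressure above diastole, makes the generated
mean pressure reproduce the published CTL systolic/diastolic/mean triple
(150/111/129) — notably the study's mean pressures are the true waveform
time-average, not the `dBP + PP/3` rule (which would give 124). The
per-beat systolic level is `sBP + A_LF sin(2π·0.3 Hz·t)` plus noise.
Tracheal pressure is a unit sinusoid at the respiratory rate.

The LF and HF carriers (0.3 and 1.2 Hz) sit mid-band; the study specifies
the bands (LF 0.15–0.6 Hz on systolic pressure, HF 0.6–2.0 Hz on heart
rate) but not the carriers. Amplitudes follow the sinusoid band-power
identity `power = A²/2`, so `A_HF = sqrt(2·HF)` and
`A_LF = sqrt(2·(LF/HF target)·HF)`.

### Default noise levels and their error budget

Neither the study nor the band definitions fix noise magnitudes, so the
defaults were chosen once for a clean anesthetized preparation: 0.5 mmHg
per-beat systolic jitter, 0.2 bpm per-beat rate jitter, 0.02 mV additive
ECG noise, 0.5 mmHg additive pressure noise, 0.05 cmH2O tracheal noise.
The guiding constraint is the error budget of the LF/HF recovery contract:
white per-beat noise of variance σ² spreads over the ~3.2 Hz beat-series
Nyquist range, of which the LF band captures ~14% and the HF band ~44%.
At the defaults this inflates LF by ≈3% and HF by ≈2% of their programmed
CTL values — well inside the 10% recovery tolerance — while remaining
visible enough that the detector and resampling stages are genuinely
exercised.

### What the generator does not emulate

No pharmacokinetics, no baroreflex-loop dynamics, no QRS morphology beyond
a Gaussian R wave, no ectopy or artifacts, no breathing-mechanics coupling
between channels, and no slide-level staining variability. A green recovery
test therefore establishes that the estimators are unbiased on data with
the statistical structure the analysis assumes — not that they are robust
to arrhythmia, electrode noise, or stain batch effects.

## Beat detection and beat series

The R-peak detector is Pan–Tompkins-style: zero-phase FFT band-pass
(5–30 Hz), squared derivative, 30 ms moving-window integration, a threshold
at 25% of the top-percentile energy, and a refractory period of
`60 / max_rate` (default max 600 bpm). Detections are mapped back to the
raw-signal maximum and refined to sub-sample precision by a least-squares
quadratic fit to log-amplitude over ±6 ms (a Gaussian peak is exactly
parabolic in log-amplitude). The refinement matters: without it, peak times
quantized to the sample grid inject white noise into the RR-derived heart
rate, which the HF band integrates. At the default 500 Hz the residual
timing error is ≈0.17 ms RMS.

Per-beat pressures use half-open windows `[t_i, t_{i+1})`: systolic = max,
diastolic = min, mean = time-average; the final partial beat is dropped and
windows under 3 samples are skipped with a warning. Respiratory frequency
is counted per non-overlapping window (default 15 s) from peaks with
prominence ≥ 20% of the window range, as complete cycles over the
first-to-last peak span.

## Wavelet variability

Beat series are cubic-spline resampled at 10 Hz (≥ 5× the HF upper edge)
and mean-removed; interpolation never extrapolates beyond the beat span.
The transform is the analytic Morlet wavelet with centre-frequency
parameter 6, computed by FFT over reflection-padded data on 16 voices per
octave. Per-time band power integrates squared magnitude over the scales
mapped into the band. Because CWT power normalization conventions differ
across implementations, the scaling is fixed operationally: a
unit-amplitude sinusoid at the band's geometric mid-frequency is passed
through the identical code path and the output scaled so its mean power is
0.5 (`A²/2` with `A = 1`). Calibration ripple across the band is < 1%
at 16 voices. Samples inside the cone of influence of the band's largest
scale (`sqrt(2)·s_max` from each edge) are excluded from mean power. The
LF/HF ratio is undefined (flagged, not infinite) when HF power is below
1e-12.

Analysis windows default to 180 s (the study's 3-min convention); when no
explicit start is given the window is clamped to the available joint span
of the two series.

A known, quantified limitation: heart rate derived from RR intervals is a
beat-long average of the instantaneous rate, which attenuates a 1.2 Hz
modulation by ≈6% in amplitude at 380 bpm; together with detection timing
jitter this biases the full-pipeline LF/HF a few percent high relative to
the programmed target. The variability stage itself, fed the generator's
per-beat ground truth, recovers the target within the stated tolerances;
the end-to-end bias is inherent to RR-based HF estimation, not a defect of
the transform.

## Reflex quantification

The study gives the baroreflex formula (`|ΔHR/ΔBP|`, bpm/mmHg) but not the
windows. The package uses the common bolus-phenylephrine convention:
baseline = 30 s before injection, response = 60 s after; ΔBP is the peak
of the ±2 s-smoothed mean-pressure series minus the baseline mean, and ΔHR
the mean heart rate within ±2 s of that peak time minus baseline. Trials
with ΔBP ≤ 2 mmHg are rejected as failed provocations. A regression-slope
estimator (HR on BP over the response window) is provided for sensitivity
analysis but is off by default. The published result sections print
baroreflex and chemoreflex units as "bpm²/mmHg"; the methods-section
definitions (bpm/mmHg; cycles/min) are implemented and the printed units
treated as typographical.

The chemoreflex is `ΔRF = RF_stim − RF_basal` with the basal rate averaged
over the baseline window and the stimulated rate taken as the maximum
windowed respiratory frequency in the response window.

## Collagen quantification

Tissue is segmented as non-near-white pixels (value ≥ 0.92 and
saturation ≤ 0.15 defines background), keeping connected components at
least 5% the size of the largest and filling enclosed holes under 100 px.
Collagen pixels are tissue pixels inside a red HSV window (hue 0.90–0.08
wrapping through 0, saturation ≥ 0.3, value 0.10–0.95). The fibrotic-area
percent divides by total tissue area by default ("total area" read as
tissue, with a frame-denominator switch). The original study's macro is
unpublished and its printed control value (59.9%) far exceeds typical
interstitial collagen fractions, so on real slides only between-group
differences are meaningful; the thresholds here are calibrated on the
synthetic stain distributions (collagen hue ≈ 0.985 ± 0.012, myocardium
≈ 0.13 ± 0.012), where recovery is exact to within 0.1 percentage points.

## Statistics

Summaries are mean ± SEM (sample SD over sqrt(n)). Normality uses the
Kolmogorov–Smirnov statistic against a normal fitted to the sample mean
and SD with the Lilliefors/Dallal–Wilkinson p-value correction (required
because the parameters are estimated). Variance homogeneity is Levene's
test centred at group means. Dunnett's two-sided comparisons against
control use the multivariate-t distribution with the pooled-variance
correlation structure `rho_ij = sqrt(n_i n_j / ((n_i+n_0)(n_j+n_0)))`,
evaluated by `mvtnorm` quadrature (absolute tolerance 1e-5) under a
locally fixed RNG state so adjusted p-values are deterministic; with one
treatment group the computation reduces analytically to the pooled t-test.
Intergroup tests are Welch by default — the study does not state the
variant and the group sizes differ — with a pooled switch. No correction
is applied across different physiological variables, mirroring the
original analysis, which adjusts only within the ANOVA family. Monte-Carlo
calibration at the study's group sizes (6/8/8/8) puts the family-wise
error at the nominal 0.05 ± 0.01.

The headline claim — a cumulative-dose threshold of 16 mg/kg — is an
executable query: the lowest arm whose Dunnett comparisons against control
are significant for both systolic pressure and heart rate.

## Numerical conventions

* Waveform time is implicit (`index / rate`); events are absolute seconds.
* EDF output scales each channel onto the full 16-bit range (read-back
  exact to one quantization step); the codec is a minimal EDF subset
  written for this package because no EDF reader exists in the target
  library set.
* Cohort subject seeds are `cohort seed + subject index`; every generator
  consumes an explicitly seeded RNG, so all outputs are byte-reproducible.
* Parameter draws are truncated at physiological bounds by rejection
  (gain ≥ 0, collagen in [0, 100], pressures ordered). For the DOX20
  baroreflex arm the printed SEM (0.3 on a mean of 0.24 — itself a
  suspected misprint) makes truncation material: cohort means for that one
  variable sit above the printed mean, and the sampling-distribution
  checks deliberately exclude it.
* Pipeline defaults generate at 500 Hz rather than the 1 kHz acquisition
  rate of the original hardware; every recovery contract is met at 500 Hz
  and the halved data volume keeps the full 30-subject replica within
  test-time budgets. Pass `sampling_rate = 1000` for the stated
  acquisition rate.
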