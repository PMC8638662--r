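---
title: "Cross-nuclear calibration and kPL kinetics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-nuclear calibration and kPL kinetics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercal)
```

# The problem

Hyperpolarized [1-¹³C]pyruvate imaging needs its transmit chain calibrated
*before* the bolus arrives: the center frequency must sit inside the narrow
pass-band of a spectral–spatial excitation (~85 Hz wide, so errors beyond
~40 Hz fail outright), and the transmit gain must deliver the nominal flip
angle, since flip errors propagate quadratically into kinetic estimates.
Natural-abundance ¹³C provides no usable signal for this, so `hypercal`
transfers the calibration from ²³Na and ¹H, whose resonance frequencies
relate to ¹³C through fixed gyromagnetic-ratio ratios.

# Models

## Frequency and gain transfer

For two nuclei in the same magnet, `f0_ref / f0_C13` equals the ratio of
gyromagnetic ratios — a field-independent constant.  `hypercal` estimates it
as the mean of per-experiment ratios (`aggregate_scaling()`), with the
sample SD (n−1 denominator; the convention is a package choice, the source
of the estimate does not prescribe one).  Transmit gain is logarithmic, so
the cross-nucleus correction is the *difference* `TG(23Na) − TG(13C)` in dB.
Two dB conventions coexist in MR; this package uses the amplitude-domain
form throughout (`db_to_amplitude_factor(x) = 10^(x/20)`), matching the
equivalence between a ~12 dB power step and a quadrupled hard-pulse width at
fixed amplitude.  Raw scanner gain integers are interpreted as 0.1 dB per
unit — the convention under which typical raw readings of 260 vs 156 agree
with the ~10.4 dB correction measured in dB directly.

## Spectral processing

FIDs are zero-filled (default 1024 points), Fourier transformed with DC at
the transmit frequency, zero-order phased, and fitted with a Lorentzian
`A (w/2)^2 / ((f−c)^2 + (w/2)^2) + baseline` on the real part.  Design
choices a maintainer should know:

* **Peak detectability** is `max |S| > 5 × median |S|`.  A 3× threshold
  looks natural but fails on pure complex Gaussian noise: the max/median
  ratio of a Rayleigh sample at 1024 bins is typically 3.2–3.8, so 3×
  would "detect" a peak in a noise-only spectrum.  5× rejects noise with
  probability ≈ 1 while every usable resonance here sits 15–50× above the
  median.
* **Zero-order phase** maximizes the real integral over ±2 FWHM around the
  magnitude peak, *after subtracting a complex baseline* estimated from an
  annulus at 2–4 FWHM.  Without the baseline, the slowly varying dispersion
  tails of *neighbouring* resonances leak into the window and bias the
  phase (≈0.013 rad in a realistic pyruvate/lactate spectrum, enough to
  corrupt a 15% lactate amplitude by ~0.6%); with it the residual is
  ≈0.001 rad.  The estimator is exactly equivariant under global rotations,
  so constructed-rotation recovery is exact even when the absolute phase
  of a dispersive lineshape carries a small discretization residual.
* **Fitting** profiles amplitude and baseline linearly and optimizes
  (center, log-width) by Nelder–Mead plus a BFGS polish from a
  deterministic start (magnitude argmax, half-height width); window ±10
  initial FWHM; tolerance 1e-10 on the sum of squares.  Real-part fitting
  is the default; magnitude fitting is available (`use_magnitude`) but
  carries Rician bias at low SNR.

## Field maps

B0 maps are per-voxel fitted peak offsets over the inner region of the CSI
grid (margin 1 voxel: 8×8 → 6×6).  B1 maps use the double-angle method,
`flip = acos(S(2α) / (2 S(α)))` with `S` the *fitted Lorentzian amplitude*
(linewidth-robust, unlike raw peak height).  Out-of-domain arccos arguments
and unusable voxels are masked with a recorded reason and counted — never
clipped silently; the mask count is part of every map summary.  No T1
saturation correction is applied: the generating TRs are treated as fully
relaxed, a documented assumption.  Noise correlation uses the magnitude of
the complex Pearson correlation (an option concatenates real/imaginary
parts instead).

## Frequency predictors

All three predictors are evaluated retrospectively and in-sample by
default (each subject's correction uses the full cohort, including
itself), which reproduces a retrospective analysis and makes every
predictor unbiased by construction — the discriminating statistic is the
residual SD and the count of |residual| > 40 Hz (strict inequality at the
boundary).  A leave-one-out mode (`in_sample = FALSE`) gives the honest
prospective analogue.  Dates enter as days since the earliest study;
time-of-day is ignored.  The water method divides the water ¹H frequency by
the constant 3.97595 exactly — deliberately not replaced by a
physical-constants table, because the downstream offset (~2620 Hz) absorbs
any constant's imprecision while reproducibility requires the divisor be
fixed.

## Kinetics

The two-pool exchange model is

  dP/dt = −(kPL + R1P) P,    dL/dt = kPL P − R1L L,

integrated exactly between excitations (closed-form 2×2 matrix
exponential), with both longitudinal pools multiplied by cos(flip) at each
excitation and the recorded signal proportional to pool × sin(flip).
Back-exchange is fixed at zero ("apparent" unidirectional kPL).  The kPL
fit is *inputless*: the measured pyruvate curve drives the lactate
equation, so no arterial input function is modelled.  Between samples the
post-excitation pyruvate pool is interpolated exponentially at the rate
implied by consecutive samples; the lactate transfer integral then has a
closed form, and the predicted lactate is linear in kPL, making the fixed-
R1L fit a two-coefficient linear least squares (kPL response + a
homogeneous mode for pre-existing lactate).  Estimating the homogeneous
term jointly, rather than pinning it to the noisy first lactate sample,
removes an ~18% downward bias at low curve SNR.  Intervals where the
consecutive-sample ratio is unusable (noise, near-zero pyruvate) fall back
to trapezoidal driving.  R1L defaults to 1/25 s⁻¹ with a profile-fit
option; the effective rate also absorbs unmodelled losses.

Matching pursuit decomposes the real part of each phased spectrum over
unit-norm real Lorentzian atoms at fixed metabolite offsets (pyruvate 0,
lactate +392, bicarbonate −322, alanine +185, pyruvate hydrate +270 Hz;
20 Hz FWHM — standard 3 T values).  After the greedy selection loop stops
(residual energy fraction below tolerance or 20 iterations), coefficients
are re-solved by least squares over the selected atoms (the
orthogonal-matching-pursuit refinement); never-selected atoms stay at 0 and
negative coefficients are permitted at this stage.  When frames are
quantified for kinetic curves the stopping tolerance is tightened to 1e-8
(40 iterations): the default 1e-4 is *above* the squared energy fraction of
early-frame lactate (~0.3% of pyruvate in amplitude ⇒ ~1e-5 in energy), so
a loose tolerance silently drops exactly the frames that anchor kPL.
Negative amplitudes are rectified to zero only in reported curves, with the
rectification count logged.  Dynamic frames are phased with one global
phase estimated from the complex frame sum (late frames are individually
unphaseable noise), and the frequency-domain kPL estimate is the
time-domain estimator applied to matching-pursuit curves.

# The synthetic world

Generators are deterministic functions of `(config, seed)`; a root seed
expands into fixed per-stream sub-seeds by a counter scheme so adding a
generator never perturbs existing streams.  Truth defaults are the point
estimates of a well-calibrated clinical 3 T system: ²³Na/¹³C scale 1.05180
(ratio jitter SD 1e-5), gain offset 10.4 dB (jitter 0.6 dB), secular drift
0.36 Hz/day over a 940-day 17-subject cohort with 39 Hz subject jitter,
water offset 2620 ± 11 Hz, phantom offset 186 ± 43 Hz, over-flip 1.18
(¹³C) / 1.14 (²³Na), across-voxel B0 SD 18 Hz, kPL 0.007 s⁻¹, integrated
lactate:pyruvate 0.15, peak SNR 50 (CSI) and 20 (dynamic).

Two generator choices were genuinely open:

* **Drift sign.** The observed secular drift is downward but is quoted as
  an unsigned 0.36 Hz/day; the generator takes `drift_hz_per_day` as given
  (default +0.36) so the recovered slope is directly comparable to the
  quoted magnitude.
* **Dynamic pyruvate appearance.** The measured pyruvate curve is modelled
  directly as a gamma-variate envelope (shape 2, scale 8 s: peak ~8 s after
  injection start, tail time-constant 8 s ≈ combined T1 + RF losses), and
  lactate is generated as the *exact* exchange response to that curve under
  the same piecewise-exponential interpolation the estimator assumes.  An
  explicit continuous input term was rejected: the inputless estimator
  cannot represent intra-interval input arrival, so any continuous-input
  generator makes the noiseless pipeline identity unattainable at the 1e-3
  level by construction rather than by estimator fault.  The no-input case
  coincides with `simulate_two_site()`, which is itself validated against
  an independent fine-step Runge–Kutta integrator.  The bolus shape is a
  package choice, not an empirical claim.
* **Ratio mode.** For ratio-recovery studies (`mode = "ratio"`) lactate and
  bicarbonate are exact fixed fractions of the pyruvate curve, so the
  integrated ratios equal the configured targets by construction; the
  kinetic mode leaves the ratio an emergent quantity (~0.11 at the default
  parameters).

What a green test on this world does establish: the estimators invert their
own forward models exactly at zero noise, remain consistent at the stated
noise levels, and the full pipelines (spectra → curves → kPL; grids → maps)
are self-consistent end to end.  What it does not establish: robustness to
baseline roll, first-order phase, lineshape departures from Lorentzian,
motion, B0 drift within an acquisition, or coil-profile structure — none of
which the generators emulate.

# Numerical conventions and degenerate inputs

* Frequencies are Hz offsets from the transmit frequency, axes strictly
  increasing; serialized frequencies are written at full precision in JSON.
* The spectral containers mirror an HDF5-style layout (datasets +
  attributes) in plain JSON; complex arrays are split into real/imaginary
  datasets.
* Voxel failures mask voxels (counted, with reasons); they are never fatal
  to a map.  Unphaseable spectra, degenerate dates, all-equal abscissae,
  empty pair lists, zero pyruvate amplitudes, and out-of-range config keys
  all raise immediate errors naming the offending input.
* `fit_linear_trend` accepts two distinct points (returning the
  interpolating line with R² = 1); the drift predictor keeps its own
  stricter ≥3-record precondition.

# Known limitations

* The double-angle B1 map inherits the method's insensitivity near 90° and
  its domain restriction `|S(2α)| ≤ 2|S(α)|`; heavily over-flipped voxels
  mask out rather than extrapolate.
* kPL estimation fixes back-exchange at zero and treats R1L as known unless
  profiled; reported kPL is therefore an apparent rate.
* The matching-pursuit dictionary uses fixed offsets and linewidths; B0
  errors larger than ~half a linewidth would require a shift-tolerant
  dictionary, which is out of scope.
* In-sample predictor statistics understate prospective error; use
  leave-one-out mode for a prospective claim.
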