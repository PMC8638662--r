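# hypercal

Calibration and kinetic-analysis toolkit for hyperpolarized ¹³C-MRI, built
around one practical problem: natural-abundance ¹³C gives almost no signal,
so the transmit calibration (center frequency f₀, RF transmit gain, flip-angle
map) for a hyperpolarized [1-¹³C]pyruvate study cannot be derived from the
¹³C signal itself before the short-lived bolus arrives. The package
implements calibration transfer from the two nuclei the body does provide in
abundance — ²³Na (resonating ~5% above ¹³C at clinical field) and ¹H — plus
the downstream spectral and kinetic analysis of the dynamic ¹³C data.

## What it computes

* **Cross-nuclear scaling** — frequency scaling factors
  `f0(ref)/f0(13C)` (≈1.0518 for ²³Na/¹³C, ≈3.976 for ¹H/¹³C) and the
  logarithmic transmit-gain correction `TG(23Na) − TG(13C)` in dB, with
  aggregation (mean ± SD) over repeated prescan experiments.
* **Spectral processing** — zero-fill → FFT → zero-order phase → Lorentzian
  least-squares fit of pulse-acquire FIDs and CSI voxel spectra.
* **Field maps** — voxel-wise B0 maps (resonance offset in Hz) and
  double-angle B1 maps (achieved/nominal flip from
  `acos(S(2α)/(2 S(α)))`), with percent and dB cross-nucleus comparison maps
  and multichannel noise-correlation matrices.
* **Frequency predictors** — three estimators of the in-vivo
  ¹³C-pyruvate frequency (temporal drift, external phantom, scaled water ¹H)
  evaluated by Bland–Altman bias/limits-of-agreement and a
  spectral–spatial failure count (|error| > 40 Hz).
* **Kinetics** — matching-pursuit quantification of dynamic spectra over a
  fixed metabolite dictionary, two-site exchange modelling
  (`dP/dt = −(kPL+R1P)P`, `dL/dt = kPL·P − R1L·L`, cos(flip) RF depletion per
  excitation), inputless kPL estimation in the time and frequency domains,
  and complex-summed lactate:pyruvate / bicarbonate:pyruvate ratios.
* **Synthetic data** — seeded generators reproducing the statistical
  structure each stage assumes (drift 0.36 Hz/day, water offset 2620 ± 11 Hz,
  over-flip 1.14–1.18, kPL 0.007 s⁻¹, lac:pyr 0.15, …), so the full pipeline
  tests without any scanner data.

## Worked example

```r
library(hypercal)

# cross-nuclear calibration from a prescan table
cal <- aggregate_scaling(read_prescan_csv(
  system.file("extdata", "tg_saline_loading.csv", package = "hypercal")))
round(cal$tg_correction_db, 1)
#> [1] 10.4

# 23Na/13C frequency scaling factor from one matched pair
frequency_scaling_factor(33794497, 32130000)
#> [1] 1.051805

# a full synthetic dynamic study and its kinetic analysis
cfg <- synth_config(seed = 1)
study <- gen_dynamic_study(cfg)            # TR 1 s, 128 frames, flip 12 deg
fit <- fit_kpl_frequency_domain(study$dyn, r1l = 1/25)
fit
#> kPL = 0.00753 1/s (frequency domain, r1l = 0.0400 1/s, residual 40.3)

# frequency predictors on a synthetic 17-subject cohort
log <- gen_subject_log(cfg)
compare_predictors(log)$comparison
#>    method       bias_hz    sd_hz n_outside_band
#> 3   water  4.382694e-10 11.92965              0
#> 2 phantom  1.095674e-09 37.60644              4
#> 1   drift -1.314808e-09 43.83135              4
```

The comparison table reads: every in-sample predictor is unbiased by
construction (the mean offset or trend is estimated from the same cohort),
so the discriminating statistic is the residual SD.  Predicting the
pyruvate frequency from the water ¹H resonance leaves ~12 Hz of scatter
(well inside the ~40 Hz half-pass-band of a spectral–spatial excitation
pulse), while phantom- and drift-based predictions scatter by ~38-44 Hz and
would each have mis-excited 4 of 17 subjects.

A command-line interface wrapping the same stages lives at
`inst/cli/hypercal.R` (`calibrate`, `b1map`, `predict-freq`, `kinetics`,
`simulate`).

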