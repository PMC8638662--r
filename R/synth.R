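# Seeded synthetic-data generators.
#
# Every generator is a deterministic function of (config, seed).  The truth
# parameters default to the point estimates a well-calibrated 3 T system
# exhibits (23Na/13C scale ~1.0518, gain offset ~10.4 dB, secular drift
# ~0.36 Hz/day, water-method offset ~2620 +/- 11 Hz, over-flip ~1.14-1.18,
# kPL ~0.007 1/s, lactate:pyruvate ~0.15); noise defaults are the matching
# observed spreads.  A single root seed expands into fixed per-stream
# sub-seeds so adding a generator never perturbs existing streams.

SYNTH_STREAMS <- c(prescan = 1L, csi = 2L, subjects = 3L, dynamic = 4L, noise = 5L)

#' Configuration for the synthetic-data generators
#'
#' @param seed Mandatory integer root seed; there is no implicit randomness.
#' @param n_subjects Cohort size for subject logs.
#' @param span_days Calendar span of the subject log in days.
#' @param base_f_pyr_hz In-vivo 13C-pyruvate frequency at the first study
#'   date, Hz.
#' @param drift_hz_per_day Secular frequency drift, Hz/day.
#' @param jitter_sd_hz Subject-level SD of the in-vivo frequency about the
#'   drift line, Hz.
#' @param water_offset_hz Mean offset of gyromagnetic-scaled water above the
#'   in-vivo pyruvate frequency, Hz.
#' @param water_jitter_sd_hz Subject-level SD of that offset, Hz.
#' @param phantom_offset_hz Mean offset of in-vivo pyruvate above the
#'   phantom reference, Hz.
#' @param phantom_jitter_sd_hz Subject-level SD of the phantom offset, Hz.
#' @param gamma_ratio 1H/13C frequency ratio used to place the water line.
#' @param freq_scale_na_c True 23Na/13C frequency scaling factor.
#' @param freq_scale_jitter_sd Per-experiment SD of that ratio.
#' @param tg_offset_db True 23Na-13C transmit-gain difference, dB.
#' @param tg_jitter_sd_db Per-experiment SD of the gain difference, dB.
#' @param overflip_c13,overflip_na23 Mean achieved/nominal flip ratios.
#' @param b0_sd_hz Across-voxel SD of resonance offsets in CSI grids, Hz.
#' @param linewidth_hz Voxel/metabolite Lorentzian FWHM, Hz.
#' @param nx,ny CSI grid size.
#' @param n_points Spectral points per synthesized spectrum.
#' @param spectral_width_hz Spectral width (1/dwell), Hz.
#' @param snr_csi Peak-signal to noise-SD ratio for CSI voxels.
#' @param snr_dyn Peak-signal to noise-SD ratio for dynamic frames.
#' @param kpl True pyruvate-to-lactate exchange rate, 1/s.
#' @param r1p,r1l Longitudinal relaxation rates, 1/s.
#' @param lac_pyr,bic_pyr Target metabolite amplitude ratios (ratio mode).
#' @param tr Dynamic repetition time, s.
#' @param flip Dynamic flip angle, degrees.
#' @param n_timepoints Dynamic frames.
#' @param bolus_shape,bolus_scale Gamma-variate pyruvate appearance
#'   parameters (shape, scale in s): peak at `(shape-1)*scale`, tail decay
#'   time constant `scale`.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_subjects = 17L, span_days = 940,
                         base_f_pyr_hz = 32131500, drift_hz_per_day = 0.36,
                         jitter_sd_hz = 39,
                         water_offset_hz = 2620, water_jitter_sd_hz = 11,
                         phantom_offset_hz = 186, phantom_jitter_sd_hz = 43,
                         gamma_ratio = GAMMA_RATIO_H1_C13,
                         freq_scale_na_c = 1.05180, freq_scale_jitter_sd = 1e-5,
                         tg_offset_db = 10.4, tg_jitter_sd_db = 0.6,
                         overflip_c13 = 1.18, overflip_na23 = 1.14,
                         b0_sd_hz = 18, linewidth_hz = 30,
                         nx = 8L, ny = 8L,
                         n_points = 1024L, spectral_width_hz = 5000,
                         snr_csi = 50, snr_dyn = 20,
                         kpl = 0.007, r1p = 1 / 30, r1l = 1 / 25,
                         lac_pyr = 0.15, bic_pyr = 0.006,
                         tr = 1, flip = 12, n_timepoints = 128L,
                         bolus_shape = 2, bolus_scale = 8) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("seed is mandatory: generators have no implicit randomness", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  sds <- c(cfg$jitter_sd_hz, cfg$water_jitter_sd_hz, cfg$phantom_jitter_sd_hz,
           cfg$freq_scale_jitter_sd, cfg$tg_jitter_sd_db, cfg$b0_sd_hz)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  structure(cfg, class = "synth_config")
}

# Deterministic sub-seed per named stream: root seeds are expected small
# (the CLI passes ints), and the expansion stays below 2^31 - 1.
sub_seed <- function(cfg, stream) {
  s <- SYNTH_STREAMS[[stream]]
  (abs(cfg$seed) %% 100000L) * 20011L + s * 101L
}

#' Generate matched prescan pairs
#'
#' Emulates repeated phantom calibration experiments: per experiment, a 13C
#' and a 23Na prescan whose frequencies are tied by the configured scaling
#' factor (with ratio jitter) and whose transmit gains differ by the
#' configured dB offset (with gain jitter).
#'
#' @param cfg A [synth_config()].
#' @param n Number of experiments (>= 1).
#' @return Data frame with columns `experiment_id`, `coil`, `nucleus`,
#'   `f0_hz`, `tg_db` — two rows per experiment — suitable for
#'   [aggregate_scaling()].
#' @export
gen_prescan_pairs <- function(cfg, n = 8L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(sub_seed(cfg, "prescan"))
  f_c13 <- 32130000 + stats::rnorm(n, 0, 5)
  scale <- cfg$freq_scale_na_c + stats::rnorm(n, 0, cfg$freq_scale_jitter_sd)
  f_na <- f_c13 * scale
  tg_c13 <- 15 + stats::rnorm(n, 0, 0.5)
  tg_na <- tg_c13 + cfg$tg_offset_db + stats::rnorm(n, 0, cfg$tg_jitter_sd_db)
  data.frame(
    experiment_id = rep(sprintf("exp%03d", seq_len(n)), each = 2L),
    coil = "loop",
    nucleus = rep(c("C13", "NA23"), times = n),
    f0_hz = as.vector(rbind(f_c13, f_na)),
    tg_db = as.vector(rbind(tg_c13, tg_na)),
    stringsAsFactors = FALSE)
}

# one synthetic voxel spectrum: complex Lorentzian at `offset` with peak
# amplitude `amp`, global phase `phi`, complex Gaussian noise `noise_sd`
synth_voxel_spectrum <- function(freq, amp, offset, fwhm, phi, noise_sd) {
  v <- lorentzian_complex(freq, amp, offset, fwhm) * exp(1i * phi)
  if (noise_sd > 0) {
    v <- v + complex(real = stats::rnorm(length(freq), 0, noise_sd),
                     imaginary = stats::rnorm(length(freq), 0, noise_sd))
  }
  new_spectrum(v, freq)
}

#' Generate a double-angle CSI study
#'
#' Produces two 2-D CSI grids (nominal flips `flip_a` and `2*flip_a`) for
#' one nucleus.  Each voxel holds a Lorentzian resonance at a per-voxel B0
#' offset (SD `b0_sd_hz`), with a random global voxel phase and complex
#' Gaussian noise at the configured peak SNR.  Voxel amplitudes follow
#' `sin(overflip * nominal_flip)`, i.e. a flat over-flip surface at the
#' configured value, optionally modulated by a smooth quadratic bump.
#'
#' @param cfg A [synth_config()].
#' @param nucleus `"C13"` or `"NA23"`; selects the over-flip truth.
#' @param flip_a Base nominal flip in degrees (second grid is `2*flip_a`).
#' @param surface_amp Relative amplitude of a smooth center-to-edge
#'   variation of the over-flip surface (0 = flat).
#' @return List with `grid_a`, `grid_2a` ([csi_grid()]s), and the true
#'   `overflip` surface matrix.
#' @export
gen_csi_study <- function(cfg, nucleus = "C13", flip_a = 40, surface_amp = 0) {
  stopifnot(inherits(cfg, "synth_config"))
  check_nucleus(nucleus)
  set.seed(sub_seed(cfg, "csi"))
  nx <- cfg$nx; ny <- cfg$ny
  freq <- seq(-cfg$spectral_width_hz / 2,
              cfg$spectral_width_hz / 2 - cfg$spectral_width_hz / cfg$n_points,
              length.out = cfg$n_points)
  base_overflip <- if (nucleus == "NA23") cfg$overflip_na23 else cfg$overflip_c13
  # smooth center-peaked surface in [-1, 1] scaled by surface_amp
  gx <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  gy <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  bump <- outer(gx, gy, function(u, v) 1 - (u^2 + v^2) / 2)
  overflip <- base_overflip * (1 + surface_amp * (bump - mean(bump)))
  b0 <- matrix(stats::rnorm(nx * ny, 0, cfg$b0_sd_hz), nx, ny)
  phases <- matrix(stats::runif(nx * ny, -pi, pi), nx, ny)
  a0 <- 100
  noise_sd <- if (is.finite(cfg$snr_csi)) a0 / cfg$snr_csi else 0
  make_grid <- function(nominal) {
    spectra <- vector("list", nx * ny)
    for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
      amp <- a0 * sin(overflip[ix, iy] * nominal * pi / 180)
      spectra[[ix + (iy - 1L) * nx]] <- synth_voxel_spectrum(
        freq, amp, b0[ix, iy], cfg$linewidth_hz, phases[ix, iy], noise_sd)
    }
    csi_grid(spectra, nx, ny, nominal_flip = nominal, nucleus = nucleus)
  }
  list(grid_a = make_grid(flip_a), grid_2a = make_grid(2 * flip_a),
       overflip = overflip, b0 = b0)
}

#' Generate a subject calibration log
#'
#' Emulates a multi-year cohort: study dates spread uniformly over the
#' configured span, in-vivo pyruvate frequency following the secular drift
#' line plus subject jitter, a phantom reference below it and a water 1H
#' frequency tied to it through the gyromagnetic ratio.
#'
#' @param cfg A [synth_config()].
#' @return Data frame with columns `subject_id`, `date`,
#'   `f_pyr_invivo_hz`, `f_phantom_hz`, `f_water_h1_hz`.
#' @export
gen_subject_log <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_subjects
  if (n < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  set.seed(sub_seed(cfg, "subjects"))
  days <- sort(round(stats::runif(n, 0, cfg$span_days)))
  f_pyr <- cfg$base_f_pyr_hz + cfg$drift_hz_per_day * days +
    stats::rnorm(n, 0, cfg$jitter_sd_hz)
  f_phantom <- f_pyr - (cfg$phantom_offset_hz +
                          stats::rnorm(n, 0, cfg$phantom_jitter_sd_hz))
  f_water <- (f_pyr + cfg$water_offset_hz +
                stats::rnorm(n, 0, cfg$water_jitter_sd_hz)) * cfg$gamma_ratio
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             date = as.Date("2016-03-01") + days,
             f_pyr_invivo_hz = f_pyr,
             f_phantom_hz = f_phantom,
             f_water_h1_hz = f_water,
             stringsAsFactors = FALSE)
}

# gamma-variate bolus envelope, peak height 1 at t = (shape-1)*scale
gamma_variate <- function(t, shape, scale) {
  tp <- (shape - 1) * scale
  g <- ifelse(t <= 0, 0, (t / tp)^(shape - 1) * exp((tp - t) / scale))
  g
}

#' Generate a dynamic hyperpolarized study
#'
#' The measured pyruvate signal follows a gamma-variate appearance (bolus
#' arrival, perfusion peak, T1/RF decay tail).  In `"kinetic"` mode the
#' lactate curve is the exact response of the two-pool exchange model driven
#' by that pyruvate curve (piecewise-exponential interpolation between
#' frames, cos(flip) RF depletion at each excitation) at the configured
#' `kpl`; bicarbonate is a fixed small fraction of pyruvate.  In `"ratio"`
#' mode lactate and bicarbonate are exact fixed fractions (`lac_pyr`,
#' `bic_pyr`) of the pyruvate curve, so integrated amplitude ratios equal
#' the configured targets by construction.  Frames are synthesized as
#' complex Lorentzians at the basis offsets plus complex Gaussian noise at
#' the configured peak SNR.
#'
#' @param cfg A [synth_config()].
#' @param mode `"kinetic"` or `"ratio"` (see above).
#' @param basis A [metabolite_basis()] providing offsets/linewidths.
#' @param noiseless If `TRUE`, omit the noise regardless of `snr_dyn`.
#' @return List with `dyn` ([dynamic_spectra()]), `curves` (true
#'   [metabolite_curves()]), and the config used.
#' @export
gen_dynamic_study <- function(cfg, mode = c("kinetic", "ratio"),
                              basis = metabolite_basis(), noiseless = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  mode <- match.arg(mode)
  set.seed(sub_seed(cfg, "dynamic"))
  n <- cfg$n_timepoints
  t <- (seq_len(n) - 1L) * cfg$tr
  pyr <- 100 * gamma_variate(t, cfg$bolus_shape, cfg$bolus_scale)
  lac <- switch(mode,
    kinetic = cfg$kpl * lactate_response(pyr, cfg$tr, cfg$flip, cfg$r1l),
    ratio = cfg$lac_pyr * pyr)
  bic <- cfg$bic_pyr * pyr
  truth <- metabolite_curves(list(pyruvate = pyr, lactate = lac,
                                  bicarbonate = bic),
                             tr = cfg$tr, flip = cfg$flip)
  freq <- seq(-cfg$spectral_width_hz / 2,
              cfg$spectral_width_hz / 2 - cfg$spectral_width_hz / cfg$n_points,
              length.out = cfg$n_points)
  off <- stats::setNames(basis$offsets_hz, basis$names)
  fw <- stats::setNames(basis$fwhm_hz, basis$names)
  noise_sd <- if (!noiseless && is.finite(cfg$snr_dyn)) max(pyr) / cfg$snr_dyn else 0
  frames <- lapply(seq_len(n), function(k) {
    v <- lorentzian_complex(freq, pyr[k], off[["pyruvate"]], fw[["pyruvate"]]) +
      lorentzian_complex(freq, lac[k], off[["lactate"]], fw[["lactate"]]) +
      lorentzian_complex(freq, bic[k], off[["bicarbonate"]], fw[["bicarbonate"]])
    if (noise_sd > 0) {
      v <- v + complex(real = stats::rnorm(length(freq), 0, noise_sd),
                       imaginary = stats::rnorm(length(freq), 0, noise_sd))
    }
    new_spectrum(v, freq)
  })
  list(dyn = dynamic_spectra(frames, tr = cfg$tr, flip = cfg$flip),
       curves = truth, config = cfg, mode = mode)
}

#' Generate correlated multichannel noise records
#'
#' Complex Gaussian channels with a common-source mixing construction that
#' induces pairwise correlation `rho` between every channel pair, emulating
#' a noise-only acquisition with the RF amplifier disabled.
#'
#' @param cfg A [synth_config()].
#' @param n_channels Number of receive channels.
#' @param rho Target pairwise correlation in `[0, 1)`.
#' @param n_samples Samples per channel.
#' @return Complex matrix `n_channels x n_samples`.
#' @export
gen_noise_channels <- function(cfg, n_channels = 8L, rho = 0, n_samples = 10000L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  set.seed(sub_seed(cfg, "noise"))
  cplx <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  common <- cplx(n_samples)
  x <- matrix(NA_complex_, n_channels, n_samples)
  for (i in seq_len(n_channels)) {
    x[i, ] <- sqrt(rho) * common + sqrt(1 - rho) * cplx(n_samples)
  }
  x
}
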