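# Voxel-wise B0 and double-angle B1 mapping from 2-D CSI grids, cross-nucleus
# map comparisons, and multichannel noise-correlation analysis.

#' 2-D chemical-shift-imaging grid
#'
#' A spatial grid of spectra acquired at one nominal flip angle.  Spectra are
#' stored column-major in a list indexed `[x + (y-1)*nx]`.
#'
#' @param spectra List of `nx * ny` [new_spectrum()] objects.
#' @param nx,ny Grid dimensions.
#' @param nominal_flip Prescribed flip angle in degrees, in (0, 180).
#' @param nucleus One of `"C13"`, `"NA23"`, `"H1"`.
#' @param tr Repetition time in seconds.
#' @param nex Number of averaged excitations.
#' @return Object of class `csi_grid`.
#' @export
csi_grid <- function(spectra, nx, ny, nominal_flip, nucleus = "C13",
                     tr = NA_real_, nex = 1L) {
  check_nucleus(nucleus)
  if (length(spectra) != nx * ny) stop("need nx*ny spectra", call. = FALSE)
  if (!is.finite(nominal_flip) || nominal_flip <= 0 || nominal_flip >= 180) {
    stop("nominal_flip must be in (0, 180) degrees", call. = FALSE)
  }
  structure(list(spectra = spectra, nx = as.integer(nx), ny = as.integer(ny),
                 nominal_flip = nominal_flip, nucleus = nucleus,
                 tr = tr, nex = nex),
            class = "csi_grid")
}

#' Masked scalar map over a CSI grid
#'
#' @param values `nx x ny` numeric matrix; masked-out voxels are `NA`.
#' @param mask `nx x ny` logical matrix of valid voxels.
#' @param units One of `"Hz"`, `"ratio"`, `"percent"`, `"dB"`.
#' @param mask_reason Optional character matrix recording why voxels were
#'   masked (`"out_of_domain"`, `"low_signal"`, `"fit_failure"`, ...).
#' @return Object of class `scalar_map` with `summary` (mean, sd, n over the
#'   mask) attached.
#' @export
scalar_map <- function(values, mask = NULL, units = c("Hz", "ratio", "percent", "dB"),
                       mask_reason = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  stopifnot(identical(dim(values), dim(mask)))
  values[!mask] <- NA_real_
  v <- values[mask]
  # n_masked_out counts analysis failures (voxels with a recorded reason),
  # not voxels simply outside the requested inner region
  n_failed <- if (is.null(mask_reason)) sum(!mask) else sum(!is.na(mask_reason))
  summ <- list(mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) stats::sd(v) else if (length(v)) 0 else NA_real_,
               mean_abs = if (length(v)) mean(abs(v)) else NA_real_,
               n = sum(mask), n_masked_out = n_failed)
  structure(list(values = values, mask = mask, units = units,
                 mask_reason = mask_reason, summary = summ),
            class = "scalar_map")
}

# logical matrix selecting the inner region after trimming `margin` voxels
# from each edge; margin 1 on an 8x8 grid gives the conventional 6x6.
inner_mask <- function(nx, ny, margin) {
  if (nx - 2L * margin < 1L || ny - 2L * margin < 1L) {
    stop("inner_margin leaves no voxels", call. = FALSE)
  }
  m <- matrix(FALSE, nx, ny)
  m[(margin + 1L):(nx - margin), (margin + 1L):(ny - margin)] <- TRUE
  m
}

grid_spectrum <- function(grid, ix, iy) grid$spectra[[ix + (iy - 1L) * grid$nx]]

#' B0 map from a CSI grid
#'
#' Per-voxel resonance offset from the system center frequency, obtained by
#' phasing each voxel spectrum and fitting a Lorentzian.  Voxels whose fit
#' fails are masked out (counted, not fatal).
#'
#' @param grid A [csi_grid()].
#' @param inner_margin Voxels trimmed from each edge before analysis
#'   (default 1: the inner 6x6 of an 8x8 grid).
#' @return A [scalar_map()] in Hz.
#' @export
compute_b0_map <- function(grid, inner_margin = 1L) {
  stopifnot(inherits(grid, "csi_grid"))
  mask <- inner_mask(grid$nx, grid$ny, inner_margin)
  values <- matrix(NA_real_, grid$nx, grid$ny)
  reason <- matrix(NA_character_, grid$nx, grid$ny)
  for (iy in seq_len(grid$ny)) for (ix in seq_len(grid$nx)) {
    if (!mask[ix, iy]) next
    off <- tryCatch(peak_offset(zero_order_phase(grid_spectrum(grid, ix, iy))),
                    error = function(e) NA_real_)
    if (is.na(off)) {
      mask[ix, iy] <- FALSE
      reason[ix, iy] <- "fit_failure"
    } else {
      values[ix, iy] <- off
    }
  }
  scalar_map(values, mask, units = "Hz", mask_reason = reason)
}

# fitted absorption amplitude of the dominant voxel resonance, NA on failure
voxel_amplitude <- function(spec) {
  tryCatch(fit_lorentzian(zero_order_phase(spec))$amplitude,
           error = function(e) NA_real_)
}

#' Double-angle B1 (flip-angle) map
#'
#' From two CSI grids acquired at nominal flips alpha and 2*alpha, the
#' achieved flip is `acos(S(2a) / (2 S(a)))` per voxel, with `S` the fitted
#' Lorentzian amplitude.  The map value is the ratio achieved/nominal, so
#' 1.18 means 18% over-flipping.  Voxels where the arccos argument leaves
#' [-1, 1] are masked `"out_of_domain"`; voxels with unusable signal are
#' masked `"low_signal"` — never clipped silently.
#'
#' @param grid_a CSI grid at the base flip angle.
#' @param grid_2a CSI grid at exactly twice the base flip angle (same
#'   nucleus and geometry).
#' @param inner_margin Edge trim, as in [compute_b0_map()].
#' @return A [scalar_map()] of achieved/nominal flip ratios.
#' @export
double_angle_flip_map <- function(grid_a, grid_2a, inner_margin = 1L) {
  stopifnot(inherits(grid_a, "csi_grid"), inherits(grid_2a, "csi_grid"))
  if (grid_a$nx != grid_2a$nx || grid_a$ny != grid_2a$ny) {
    stop("grid dimensions differ", call. = FALSE)
  }
  if (grid_a$nucleus != grid_2a$nucleus) stop("grid nuclei differ", call. = FALSE)
  if (abs(grid_2a$nominal_flip - 2 * grid_a$nominal_flip) > 1e-9) {
    stop("second grid must be at exactly twice the nominal flip", call. = FALSE)
  }
  mask <- inner_mask(grid_a$nx, grid_a$ny, inner_margin)
  values <- matrix(NA_real_, grid_a$nx, grid_a$ny)
  reason <- matrix(NA_character_, grid_a$nx, grid_a$ny)
  for (iy in seq_len(grid_a$ny)) for (ix in seq_len(grid_a$nx)) {
    if (!mask[ix, iy]) next
    s1 <- voxel_amplitude(grid_spectrum(grid_a, ix, iy))
    s2 <- voxel_amplitude(grid_spectrum(grid_2a, ix, iy))
    if (is.na(s1) || is.na(s2) || s1 <= 0) {
      mask[ix, iy] <- FALSE; reason[ix, iy] <- "low_signal"; next
    }
    arg <- s2 / (2 * s1)
    if (abs(arg) > 1) {
      mask[ix, iy] <- FALSE; reason[ix, iy] <- "out_of_domain"; next
    }
    flip_meas_deg <- acos(arg) * 180 / pi
    values[ix, iy] <- flip_meas_deg / grid_a$nominal_flip
  }
  scalar_map(values, mask, units = "ratio", mask_reason = reason)
}

congruent <- function(a, b) {
  identical(dim(a$values), dim(b$values))
}

#' Per-voxel percentage difference between two B1 maps
#'
#' `100 * (B1_C - B1_Na) / B1_Na` per voxel.  The summary carries both the
#' mean of absolute values (the mean absolute percentage difference) and the
#' signed mean.
#'
#' @param map_c13,map_na23 Congruent [scalar_map()]s (13C and 23Na B1).
#' @return A [scalar_map()] in percent.
#' @export
percent_difference_map <- function(map_c13, map_na23) {
  stopifnot(inherits(map_c13, "scalar_map"), inherits(map_na23, "scalar_map"))
  if (!congruent(map_c13, map_na23)) stop("maps are not congruent", call. = FALSE)
  mask <- map_c13$mask & map_na23$mask & (map_na23$values != 0)
  mask[is.na(mask)] <- FALSE
  values <- 100 * (map_c13$values - map_na23$values) / map_na23$values
  scalar_map(values, mask, units = "percent")
}

#' dB difference between two B1 maps
#'
#' `20 * log10(B1_Na / B1_C)` per voxel, the amplitude-domain dB form used
#' when comparing simulated transmit fields between the two frequencies.
#' Non-positive voxels are masked.
#'
#' @param b1_na,b1_c13 Congruent [scalar_map()]s.
#' @return A [scalar_map()] in dB.
#' @export
b1_db_difference <- function(b1_na, b1_c13) {
  stopifnot(inherits(b1_na, "scalar_map"), inherits(b1_c13, "scalar_map"))
  if (!congruent(b1_na, b1_c13)) stop("maps are not congruent", call. = FALSE)
  mask <- b1_na$mask & b1_c13$mask &
    (b1_na$values > 0) & (b1_c13$values > 0)
  mask[is.na(mask)] <- FALSE
  values <- 20 * log10(b1_na$values / b1_c13$values)
  scalar_map(values, mask, units = "dB")
}

#' Multichannel noise correlation matrix
#'
#' Magnitude of the complex Pearson correlation between every pair of
#' receive channels of a noise-only acquisition (RF amplifier disabled).
#' Off-diagonal coupling above ~0.3 indicates inter-element coupling that
#' degrades array performance.
#'
#' @param channels Complex matrix, `n_channels x n_samples` (>= 2 channels,
#'   >= 100 samples).
#' @param concat_real_imag If `TRUE`, correlate the concatenated real and
#'   imaginary parts instead of using the complex estimator.
#' @return Object of class `noise_correlation` with fields `matrix`
#'   (symmetric, unit diagonal) and `n_channels`.
#' @export
noise_correlation <- function(channels, concat_real_imag = FALSE) {
  channels <- as.matrix(channels)
  nc <- nrow(channels); ns <- ncol(channels)
  if (nc < 2L) stop("need at least 2 channels", call. = FALSE)
  if (ns < 100L) stop("need at least 100 samples", call. = FALSE)
  if (concat_real_imag) {
    x <- cbind(Re(channels), Im(channels))
    v <- apply(x, 1L, stats::var)
    if (any(v == 0)) stop("zero-variance channel: ", which(v == 0)[1L], call. = FALSE)
    m <- abs(stats::cor(t(x)))
  } else {
    centered <- channels - rowMeans(channels)
    cov <- centered %*% Conj(t(centered))
    v <- Re(diag(cov))
    if (any(v <= 0)) stop("zero-variance channel: ", which(v <= 0)[1L], call. = FALSE)
    m <- Mod(cov) / sqrt(outer(v, v))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 1
  structure(list(matrix = m, n_channels = nc), class = "noise_correlation")
}

#' @export
print.scalar_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("scalar_map [%s]: %dx%d, mean %.4g, sd %.4g over %d voxels (%d masked out)\n",
              x$units, nrow(x$values), ncol(x$values), s$mean, s$sd, s$n, s$n_masked_out))
  invisible(x)
}
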