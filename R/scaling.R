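# Cross-nuclear frequency and transmit-gain calibration.
#
# A 13C-tuned coil can observe the endogenous 23Na (and, via the body coil,
# 1H) resonance.  Because resonance frequencies of two nuclei scale with the
# ratio of their gyromagnetic ratios, a single dimensionless factor converts a
# measured 23Na or 1H center frequency into the 13C one; transmit gain (RF
# amplifier setting) is logarithmic, so the correction between nuclei is a dB
# difference, not a ratio.

VALID_NUCLEI <- c("C13", "NA23", "H1")

check_nucleus <- function(nucleus) {
  if (!is.character(nucleus) || length(nucleus) != 1L ||
      !(nucleus %in% VALID_NUCLEI)) {
    stop("nucleus must be one of ", paste(VALID_NUCLEI, collapse = ", "),
         call. = FALSE)
  }
  nucleus
}

#' Single-nucleus prescan calibration outcome
#'
#' Bundles the center frequency and transmit gain measured for one nucleus in
#' one prescan experiment.  Scanner transmit gain is stored internally in dB;
#' raw scanner units (0.1 dB per unit) may be supplied instead of, or in
#' addition to, the dB value.
#'
#' @param nucleus One of `"C13"`, `"NA23"`, `"H1"`.
#' @param f0_hz Center frequency in Hz (positive), or `NA` for gain-only
#'   records (e.g. transcribed transmit-gain tables).
#' @param tg_db Transmit gain in dB, or `NA`.
#' @param tg_raw Optional transmit gain in raw scanner units of 0.1 dB.  If
#'   both `tg_db` and `tg_raw` are given they must agree within 0.05 dB.
#' @return An object of class `prescan_result`.
#' @export
prescan_result <- function(nucleus, f0_hz, tg_db = NA_real_, tg_raw = NA_real_) {
  check_nucleus(nucleus)
  if (!is.na(f0_hz) && (!is.finite(f0_hz) || f0_hz <= 0)) {
    stop("f0_hz must be positive", call. = FALSE)
  }
  if (!is.na(tg_raw)) {
    db_from_raw <- tg_raw_to_db(tg_raw)
    if (is.na(tg_db)) {
      tg_db <- db_from_raw
    } else if (abs(tg_db - db_from_raw) > 0.05) {
      stop("tg_db and tg_raw disagree by more than 0.05 dB", call. = FALSE)
    }
  }
  structure(list(nucleus = nucleus, f0_hz = as.numeric(f0_hz),
                 tg_db = as.numeric(tg_db), tg_raw = tg_raw),
            class = "prescan_result")
}

#' Convert raw scanner transmit-gain units to dB
#'
#' Scanner transmit-gain integers are 0.1 dB per unit, so e.g. raw gains of
#' 260 and 156 for 23Na and 13C correspond to a 10.4 dB correction.
#'
#' @param tg_raw Gain in raw 0.1-dB units.
#' @return Gain in dB.
#' @export
tg_raw_to_db <- function(tg_raw) tg_raw / 10

#' Cross-nuclear frequency scaling factor
#'
#' Ratio of a reference-nucleus center frequency (23Na or 1H) to the 13C
#' center frequency.  The ratio equals the gyromagnetic-ratio ratio of the two
#' nuclei and is field-strength independent, which is what makes it a stable
#' calibration constant.
#'
#' @param f_ref Reference-nucleus center frequency in Hz.
#' @param f_c13 13C center frequency in Hz.
#' @return `f_ref / f_c13`, dimensionless.
#' @seealso [predict_f0()] for the prospective inversion.
#' @export
frequency_scaling_factor <- function(f_ref, f_c13) {
  if (!all(is.finite(f_ref)) || !all(is.finite(f_c13)) ||
      any(f_ref <= 0) || any(f_c13 <= 0)) {
    stop("center frequencies must be positive and finite", call. = FALSE)
  }
  f_ref / f_c13
}

#' Predict a 13C center frequency from a reference-nucleus frequency
#'
#' Inverts the frequency scaling factor: given a measured 23Na or 1H center
#' frequency and the calibrated scale, returns the predicted 13C frequency.
#' Round-trips with [frequency_scaling_factor()] to machine precision.
#'
#' @param f_ref Measured reference frequency in Hz.
#' @param scale Calibrated scaling factor (positive).
#' @return Predicted 13C frequency in Hz.
#' @export
predict_f0 <- function(f_ref, scale) {
  if (!all(is.finite(scale)) || any(scale <= 0)) {
    stop("scale must be positive and finite", call. = FALSE)
  }
  f_ref / scale
}

#' Transmit-gain correction between 23Na and 13C
#'
#' RF gain is logarithmically scaled, so the correction between nuclei is the
#' signed dB difference `tg_na - tg_c13` rather than a ratio.
#'
#' @param tg_na 23Na transmit gain in dB.
#' @param tg_c13 13C transmit gain in dB.
#' @param raw If `TRUE`, inputs are in raw 0.1-dB scanner units and are
#'   converted before subtraction.
#' @return Signed correction in dB.
#' @export
tg_correction <- function(tg_na, tg_c13, raw = FALSE) {
  if (!all(is.finite(tg_na)) || !all(is.finite(tg_c13))) {
    stop("transmit gains must be finite", call. = FALSE)
  }
  if (raw) tg_raw_to_db(tg_na) - tg_raw_to_db(tg_c13) else tg_na - tg_c13
}

#' Amplitude multiplier equivalent to a dB gain difference
#'
#' Converts a dB difference into the equivalent pulse amplitude-or-width
#' multiplier at fixed amplitude, using the amplitude-domain convention
#' `10^(dB/20)`.  E.g. ~12 dB corresponds to quadrupling the hard-pulse width.
#' Note this is the amplitude convention, not the power convention
#' `10^(dB/10)`.
#'
#' @param delta_db Gain difference in dB.
#' @return Dimensionless amplitude factor.
#' @export
db_to_amplitude_factor <- function(delta_db) {
  if (!all(is.finite(delta_db))) stop("delta_db must be finite", call. = FALSE)
  10^(delta_db / 20)
}

#' Aggregate repeated prescan pairs into a scaling calibration
#'
#' Given matched (reference nucleus, 13C) prescan pairs from repeated
#' experiments, computes the mean and sample SD (n-1 denominator) of the
#' per-pair frequency scaling factors and transmit-gain corrections.
#'
#' @param pairs A list in which each element is a list/pair of two
#'   [prescan_result()] objects with distinct nuclei, one of them `"C13"`;
#'   or a data frame with columns `experiment_id`, `nucleus`, `f0_hz`,
#'   `tg_db` (as read by [read_prescan_csv()]), from which pairs are formed
#'   by experiment identifier.
#' @return An object of class `scaling_calibration` with fields
#'   `freq_scale_na_c`, `freq_scale_h_c`, `tg_correction_db`,
#'   `n_experiments`, `sd_freq_scale`, `sd_freq_scale_h`, `sd_tg_db`.
#' @export
aggregate_scaling <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- prescan_pairs_from_records(pairs)
  if (!is.list(pairs) || length(pairs) == 0L) {
    stop("pairs must be a non-empty list of matched prescan pairs", call. = FALSE)
  }
  ratio_na <- c(); ratio_h <- c(); tg_diff <- c()
  for (p in pairs) {
    if (length(p) != 2L) stop("each pair must contain exactly two prescan results", call. = FALSE)
    a <- p[[1L]]; b <- p[[2L]]
    if (!inherits(a, "prescan_result") || !inherits(b, "prescan_result")) {
      stop("pair elements must be prescan_result objects", call. = FALSE)
    }
    if (a$nucleus == b$nucleus) stop("pair nuclei must be distinct", call. = FALSE)
    # orient so that `cc` is the 13C member
    if (a$nucleus == "C13") { ref <- b; cc <- a } else { ref <- a; cc <- b }
    if (cc$nucleus != "C13") stop("each pair must include a C13 prescan", call. = FALSE)
    if (!is.na(ref$f0_hz) && !is.na(cc$f0_hz)) {
      r <- frequency_scaling_factor(ref$f0_hz, cc$f0_hz)
      if (ref$nucleus == "NA23") ratio_na <- c(ratio_na, r) else ratio_h <- c(ratio_h, r)
    }
    if (!is.na(ref$tg_db) && !is.na(cc$tg_db)) {
      tg_diff <- c(tg_diff, tg_correction(ref$tg_db, cc$tg_db))
    }
  }
  sd0 <- function(x) if (length(x) >= 2L) stats::sd(x) else if (length(x) == 1L) 0 else NA_real_
  mn  <- function(x) if (length(x)) mean(x) else NA_real_
  cal <- structure(list(
    freq_scale_na_c = mn(ratio_na),
    freq_scale_h_c  = mn(ratio_h),
    tg_correction_db = mn(tg_diff),
    n_experiments = length(pairs),
    sd_freq_scale = sd0(ratio_na),
    sd_freq_scale_h = sd0(ratio_h),
    sd_tg_db = sd0(tg_diff),
    per_pair = list(ratio_na_c = ratio_na, ratio_h_c = ratio_h,
                    tg_diff_db = tg_diff)
  ), class = "scaling_calibration")
  if (!is.na(cal$freq_scale_na_c) &&
      (cal$freq_scale_na_c <= 1.0 || cal$freq_scale_na_c >= 1.1)) {
    warning("23Na/13C frequency scale outside the physical band (1.0, 1.1)")
  }
  if (!is.na(cal$freq_scale_h_c) &&
      (cal$freq_scale_h_c <= 3.9 || cal$freq_scale_h_c >= 4.05)) {
    warning("1H/13C frequency scale outside the physical band (3.9, 4.05)")
  }
  cal
}

# Form (reference, C13) pairs from a long-format prescan record table, matched
# by experiment identifier.  Each experiment must contain exactly one C13 row
# and one reference (NA23 or H1) row per reference nucleus present.
prescan_pairs_from_records <- function(records) {
  req <- c("experiment_id", "nucleus", "f0_hz")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("prescan records missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"tg_db" %in% names(records)) {
    records$tg_db <- if ("tg_raw" %in% names(records)) {
      tg_raw_to_db(records$tg_raw)
    } else NA_real_
  }
  pairs <- list()
  for (eid in unique(records$experiment_id)) {
    sub <- records[records$experiment_id == eid, , drop = FALSE]
    c13 <- sub[sub$nucleus == "C13", , drop = FALSE]
    if (nrow(c13) != 1L) {
      stop("experiment ", eid, " must contain exactly one C13 record", call. = FALSE)
    }
    for (refnuc in intersect(c("NA23", "H1"), sub$nucleus)) {
      rr <- sub[sub$nucleus == refnuc, , drop = FALSE]
      if (nrow(rr) != 1L) {
        stop("experiment ", eid, " has duplicated ", refnuc, " records", call. = FALSE)
      }
      pairs[[length(pairs) + 1L]] <- list(
        prescan_result(refnuc, rr$f0_hz[1L], rr$tg_db[1L]),
        prescan_result("C13", c13$f0_hz[1L], c13$tg_db[1L]))
    }
  }
  if (!length(pairs)) stop("no matched prescan pairs found", call. = FALSE)
  pairs
}

#' @export
print.scaling_calibration <- function(x, ...) {
  cat("Cross-nuclear scaling calibration (", x$n_experiments, " experiments)\n", sep = "")
  if (!is.na(x$freq_scale_na_c)) {
    cat(sprintf("  23Na/13C frequency scale: %.5f +/- %.5f\n",
                x$freq_scale_na_c, x$sd_freq_scale))
  }
  if (!is.na(x$freq_scale_h_c)) {
    cat(sprintf("  1H/13C frequency scale:   %.5f +/- %.5f\n",
                x$freq_scale_h_c, x$sd_freq_scale_h))
  }
  if (!is.na(x$tg_correction_db)) {
    cat(sprintf("  TG correction (Na - C):   %.1f +/- %.1f dB\n",
                x$tg_correction_db, x$sd_tg_db))
  }
  invisible(x)
}
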