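# Retrospective 13C-pyruvate center-frequency prediction.
#
# Three predictors of the in-vivo pyruvate frequency, each evaluated with a
# Bland-Altman analysis of (predicted - actual) residuals and a count of
# subjects whose error exceeds the spectral-spatial excitation tolerance
# (|error| > 40 Hz, half the ~85 Hz pass-band):
#   drift   - linear secular field drift against the study date,
#   phantom - mean offset from a 13C reference phantom,
#   water   - water 1H frequency scaled by the 1H/13C gyromagnetic ratio
#             plus the mean in-vivo offset.

#' Default 1H/13C gyromagnetic-ratio divisor for the water method
#' @export
GAMMA_RATIO_H1_C13 <- 3.97595

#' Ordinary least-squares line with R-squared
#'
#' @param x,y Numeric vectors of equal length (>= 2 points; `x` not all
#'   equal).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
fit_linear_trend <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (diff(range(x)) == 0) stop("x values are degenerate (all equal)", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else as.numeric(ssr < .Machine$double.eps)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2)
}

#' Bland-Altman statistics of prediction residuals
#'
#' Bias (mean), sample SD, limits of agreement (bias +/- 1.96 SD) and the
#' count of residuals strictly exceeding the excitation band.
#'
#' @param residuals Numeric vector of predicted-minus-actual differences in
#'   Hz (>= 2 values).
#' @param band_hz Failure band; residuals with `|r| > band_hz` (strict) are
#'   counted as excitation failures.
#' @return List with `bias`, `sd`, `loa_low`, `loa_high`, `n_outside_band`,
#'   `band_hz`, `n`.
#' @export
bland_altman <- function(residuals, band_hz = 40) {
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 2L) stop("need at least 2 residuals", call. = FALSE)
  bias <- mean(residuals)
  s <- stats::sd(residuals)
  list(bias = bias, sd = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n_outside_band = sum(abs(residuals) > band_hz),
       band_hz = band_hz, n = n)
}

method_summary <- function(method, predicted, actual, band_hz, extra = list()) {
  residuals <- predicted - actual
  ba <- bland_altman(residuals, band_hz)
  structure(c(list(method = method, per_subject_predicted = predicted,
                   residuals = residuals), ba, extra),
            class = "method_summary")
}

# days since the earliest record; time of day is ignored
days_since_first <- function(dates) {
  dates <- as.Date(dates)
  as.numeric(dates - min(dates))
}

#' Temporal-drift frequency predictor
#'
#' Assumes the in-vivo pyruvate frequency varies slowly and linearly with
#' the study date (secular B0 drift).  Fits frequency against days since the
#' first study and predicts each subject from the fitted line.
#'
#' @param records Data frame with columns `subject_id`, `date`,
#'   `f_pyr_invivo_hz` (see [read_subject_log()]).
#' @param band_hz Excitation failure band in Hz (strict inequality).
#' @param in_sample If `TRUE` (default, matching a retrospective analysis)
#'   each subject's prediction uses the fit to all subjects including
#'   itself; if `FALSE`, leave-one-out refits are used.
#' @return A `method_summary` with extra fields `slope_hz_per_day`,
#'   `intercept_hz`, `r_squared`.
#' @export
predict_temporal_drift <- function(records, band_hz = 40, in_sample = TRUE) {
  keep <- is.finite(records$f_pyr_invivo_hz)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < 3L) stop("need at least 3 records with in-vivo frequency", call. = FALSE)
  d <- days_since_first(rec$date)
  f <- rec$f_pyr_invivo_hz
  trend <- fit_linear_trend(d, f)
  if (in_sample) {
    predicted <- trend$intercept + trend$slope * d
  } else {
    predicted <- vapply(seq_along(d), function(i) {
      tr <- fit_linear_trend(d[-i], f[-i])
      tr$intercept + tr$slope * d[i]
    }, numeric(1))
  }
  method_summary("drift", predicted, f, band_hz,
                 extra = list(slope_hz_per_day = trend$slope,
                              intercept_hz = trend$intercept,
                              r_squared = trend$r_squared))
}

#' Phantom-offset frequency predictor
#'
#' Tabulates the offset between the in-vivo pyruvate frequency and the
#' reference phantom frequency, and applies the mean offset to each
#' subject's phantom measurement.
#'
#' @inheritParams predict_temporal_drift
#' @param in_sample If `FALSE`, each subject's mean offset excludes that
#'   subject (leave-one-out).
#' @return A `method_summary` with extra field `mean_offset_hz`.
#' @export
predict_phantom <- function(records, band_hz = 40, in_sample = TRUE) {
  keep <- is.finite(records$f_pyr_invivo_hz) & is.finite(records$f_phantom_hz)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < 2L) stop("need at least 2 records with phantom frequency", call. = FALSE)
  offset <- rec$f_pyr_invivo_hz - rec$f_phantom_hz
  mo <- if (in_sample) rep(mean(offset), length(offset)) else loo_means(offset)
  predicted <- rec$f_phantom_hz + mo
  method_summary("phantom", predicted, rec$f_pyr_invivo_hz, band_hz,
                 extra = list(mean_offset_hz = mean(offset)))
}

#' Water-1H frequency predictor
#'
#' Divides the water 1H frequency by the 1H/13C gyromagnetic-ratio constant
#' (3.97595) to land near the 13C band, tabulates the remaining offset to
#' the in-vivo pyruvate frequency (~2620 Hz here), and applies the mean
#' offset to each subject.
#'
#' @inheritParams predict_phantom
#' @param gamma_ratio The 1H/13C frequency divisor; the printed constant is
#'   used verbatim by default, never replaced by a physical-constants table.
#' @return A `method_summary` with extra field `mean_offset_hz` (mean of
#'   scaled-water minus pyruvate).
#' @export
predict_water <- function(records, gamma_ratio = GAMMA_RATIO_H1_C13,
                          band_hz = 40, in_sample = TRUE) {
  if (!is.finite(gamma_ratio) || gamma_ratio <= 0) {
    stop("gamma_ratio must be positive", call. = FALSE)
  }
  keep <- is.finite(records$f_pyr_invivo_hz) & is.finite(records$f_water_h1_hz)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < 2L) stop("need at least 2 records with water frequency", call. = FALSE)
  scaled <- rec$f_water_h1_hz / gamma_ratio
  offset <- scaled - rec$f_pyr_invivo_hz
  mo <- if (in_sample) rep(mean(offset), length(offset)) else loo_means(offset)
  predicted <- scaled - mo
  method_summary("water", predicted, rec$f_pyr_invivo_hz, band_hz,
                 extra = list(mean_offset_hz = mean(offset)))
}

# leave-one-out means: element i is the mean of x[-i]
loo_means <- function(x) (sum(x) - x) / (length(x) - 1L)

#' Compare all three frequency predictors
#'
#' Runs every predictor the record set supports and ranks them by residual
#' SD (smaller is better).
#'
#' @inheritParams predict_temporal_drift
#' @param gamma_ratio Passed to [predict_water()].
#' @return Named list of `method_summary` objects plus a `comparison` data
#'   frame sorted by residual SD.
#' @export
compare_predictors <- function(records, band_hz = 40,
                               gamma_ratio = GAMMA_RATIO_H1_C13,
                               in_sample = TRUE) {
  out <- list()
  out$drift <- tryCatch(predict_temporal_drift(records, band_hz, in_sample),
                        error = function(e) NULL)
  out$phantom <- tryCatch(predict_phantom(records, band_hz, in_sample),
                          error = function(e) NULL)
  out$water <- tryCatch(predict_water(records, gamma_ratio, band_hz, in_sample),
                        error = function(e) NULL)
  out <- Filter(Negate(is.null), out)
  if (!length(out)) stop("no predictor could be run on these records", call. = FALSE)
  cmp <- data.frame(
    method = vapply(out, `[[`, character(1), "method"),
    bias_hz = vapply(out, `[[`, numeric(1), "bias"),
    sd_hz = vapply(out, `[[`, numeric(1), "sd"),
    n_outside_band = vapply(out, `[[`, numeric(1), "n_outside_band"),
    row.names = NULL)
  cmp <- cmp[order(cmp$sd_hz), , drop = FALSE]
  c(out, list(comparison = cmp))
}

#' @export
print.method_summary <- function(x, ...) {
  cat(sprintf("%s method: bias %.1f Hz, SD %.1f Hz, LoA [%.1f, %.1f], %d/%d outside +/-%g Hz\n",
              x$method, x$bias, x$sd, x$loa_low, x$loa_high,
              x$n_outside_band, x$n, x$band_hz))
  invisible(x)
}
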