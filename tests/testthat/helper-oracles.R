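# Independent oracles and small fixture builders shared across test files.

# default 1024-point axis over +/-2500 Hz (5 kHz spectral width)
test_axis <- function(n = 1024L, sw = 5000) {
  seq(-sw / 2, sw / 2 - sw / n, length.out = n)
}

# Lorentzian spectrum builder; dispersion = FALSE gives a purely real
# absorption lineshape (the "already real-positive" construction)
make_spectrum <- function(amp = 1, center = 0, fwhm = 20, phase = 0,
                          noise_sd = 0, axis = test_axis(), baseline = 0,
                          dispersion = TRUE) {
  shape <- if (dispersion) {
    amp / (1 + 2i * (axis - center) / fwhm)
  } else {
    complex(real = amp * (fwhm / 2)^2 / ((axis - center)^2 + (fwhm / 2)^2))
  }
  v <- (shape + baseline) * exp(1i * phase)
  if (noise_sd > 0) {
    v <- v + complex(real = rnorm(length(axis), 0, noise_sd),
                     imaginary = rnorm(length(axis), 0, noise_sd))
  }
  new_spectrum(v, axis)
}

# dense grid-search oracle for the Lorentzian fit: center x width grid with
# linear amplitude/baseline solve per node; independent of the optimizer path
grid_search_lorentzian <- function(spec, centers, widths) {
  y <- Re(spec$values)
  f <- spec$freq_axis
  best <- list(rss = Inf)
  for (cen in centers) for (w in widths) {
    b <- (w / 2)^2 / ((f - cen)^2 + (w / 2)^2)
    fit <- stats::lm.fit(cbind(b, 1), y)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss) {
      best <- list(rss = rss, center = cen, fwhm = w,
                   amplitude = unname(fit$coefficients[1]),
                   baseline = unname(fit$coefficients[2]))
    }
  }
  best
}

# fine-step RK4 integrator oracle for the two-pool exchange system with
# cos(flip) depletion at each excitation; independent of the matrix
# exponential used by simulate_two_site
integrate_two_site_fine <- function(kpl, r1p, r1l, p0, tr, flip, n,
                                    steps_per_tr = 1000L) {
  deriv <- function(m) c(-(kpl + r1p) * m[1], kpl * m[1] - r1l * m[2])
  ct <- cos(flip * pi / 180); st <- sin(flip * pi / 180)
  h <- tr / steps_per_tr
  m <- c(p0, 0)
  out <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    out[k, ] <- m * st
    m <- m * ct
    for (s in seq_len(steps_per_tr)) {
      k1 <- deriv(m); k2 <- deriv(m + h / 2 * k1)
      k3 <- deriv(m + h / 2 * k2); k4 <- deriv(m + h * k3)
      m <- m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  out
}

# full-dictionary linear least-squares oracle for matching pursuit
ls_dictionary_oracle <- function(spec, basis) {
  f <- spec$freq_axis
  A <- vapply(seq_along(basis$names), function(j) {
    a <- basis$fwhm_hz[j]
    v <- (a / 2)^2 / ((f - basis$offsets_hz[j])^2 + (a / 2)^2)
    v / sqrt(sum(v^2))
  }, numeric(length(f)))
  stats::setNames(qr.solve(A, Re(spec$values)), basis$names)
}
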