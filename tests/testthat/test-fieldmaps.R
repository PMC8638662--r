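# B0/B1 mapping, cross-map comparisons, noise correlation.

make_uniform_grid <- function(offset_hz = 0, amp = 100, nx = 4, ny = 4,
                              flip = 40, noise_sd = 0, phase = 0) {
  axis <- test_axis(512)
  spectra <- replicate(nx * ny, make_spectrum(amp = amp, center = offset_hz,
                                              fwhm = 30, phase = phase,
                                              noise_sd = noise_sd, axis = axis),
                       simplify = FALSE)
  csi_grid(spectra, nx, ny, nominal_flip = flip)
}

test_that("compute_b0_map recovers uniform and random offsets", {
  g0 <- make_uniform_grid(0)
  m0 <- compute_b0_map(g0, inner_margin = 1)
  expect_equal(m0$summary$mean, 0, tolerance = 1e-6)
  expect_equal(m0$summary$sd, 0, tolerance = 1e-6)
  expect_equal(m0$summary$n, 4)         # inner 2x2 of a 4x4
  g10 <- make_uniform_grid(10)
  expect_equal(compute_b0_map(g10)$summary$mean, 10, tolerance = 0.2 / 10)
  # random voxel offsets, SD ~ 20 Hz at n = 36
  set.seed(5)
  axis <- test_axis(512)
  offs <- rnorm(64, 0, 20)
  spectra <- lapply(offs, function(o) make_spectrum(amp = 50, center = o,
                                                    fwhm = 30, axis = axis))
  m <- compute_b0_map(csi_grid(spectra, 8, 8, 40), inner_margin = 1)
  inner <- matrix(offs, 8, 8)[2:7, 2:7]
  expect_equal(m$summary$sd, 20, tolerance = 0.3)
  expect_equal(m$summary$mean, mean(inner), tolerance = 0.5)
})

test_that("compute_b0_map is equivariant under a global frequency shift", {
  set.seed(6)
  axis <- test_axis()
  offs <- rnorm(16, 0, 15)
  mk <- function(shift) {
    spectra <- lapply(offs + shift, function(o)
      make_spectrum(amp = 50, center = o, fwhm = 30, axis = axis))
    compute_b0_map(csi_grid(spectra, 4, 4, 40))
  }
  m0 <- mk(0); m25 <- mk(25)
  expect_lt(abs((m25$summary$mean - m0$summary$mean) - 25), 0.1)
  expect_lt(abs(m25$summary$sd - m0$summary$sd), 0.1)
})

test_that("double-angle map inverts the forward signal model", {
  axis <- test_axis(512)
  mk_pair <- function(true_over, nominal = 40, nx = 4, ny = 4) {
    mk <- function(nom) {
      spectra <- replicate(nx * ny, make_spectrum(
        amp = 100 * sin(true_over * nom * pi / 180), center = 0, fwhm = 30,
        axis = axis), simplify = FALSE)
      csi_grid(spectra, nx, ny, nominal_flip = nom)
    }
    list(a = mk(nominal), b = mk(2 * nominal))
  }
  # identity at true flip = nominal, across the (5, 85) degree range
  for (nom in c(10, 25, 40)) {
    p <- mk_pair(1.0, nominal = nom)
    m <- double_angle_flip_map(p$a, p$b)
    expect_equal(m$summary$mean, 1.0, tolerance = 1e-6)
    expect_equal(m$summary$sd, 0, tolerance = 1e-6)
  }
  # over-flip 1.18 recovered
  p <- mk_pair(1.18)
  expect_equal(double_angle_flip_map(p$a, p$b)$summary$mean, 1.18,
               tolerance = 0.01 / 1.18)
  # mismatched flips rejected
  expect_error(double_angle_flip_map(p$a, p$a), "twice")
})

test_that("arccos domain violations mask voxels instead of erroring", {
  axis <- test_axis(512)
  mk <- function(amp, nom) {
    spectra <- replicate(9, make_spectrum(amp = amp, center = 0, fwhm = 30,
                                          axis = axis), simplify = FALSE)
    csi_grid(spectra, 3, 3, nominal_flip = nom)
  }
  # S(2a)/(2 S(a)) = 1.05 -> out of acos domain
  m <- double_angle_flip_map(mk(10, 40), mk(21, 80), inner_margin = 1)
  expect_equal(m$summary$n, 0)
  expect_equal(m$summary$n_masked_out, 1)
  expect_true(all(m$mask_reason[2, 2] == "out_of_domain"))
  # zero-amplitude voxels -> low_signal mask
  m2 <- double_angle_flip_map(mk(0, 40), mk(0, 80), inner_margin = 1)
  expect_equal(m2$summary$n, 0)
  expect_equal(m2$mask_reason[2, 2], "low_signal")
})

test_that("percentage and dB difference maps are mutually consistent", {
  a <- scalar_map(matrix(1.18, 4, 4), units = "ratio")
  b <- scalar_map(matrix(1.14, 4, 4), units = "ratio")
  pct <- percent_difference_map(a, b)
  expect_equal(pct$summary$mean, 100 * (1.18 - 1.14) / 1.14, tolerance = 1e-9)
  expect_equal(pct$summary$mean, 3.51, tolerance = 0.01 / 3.51)
  expect_equal(percent_difference_map(a, a)$summary$mean, 0)
  db <- b1_db_difference(b, a)     # 20 log10(Na / C)
  # Eq-consistency: 20 log10(1 + pct/100) = -dB value, voxel-wise
  expect_equal(20 * log10(1 + pct$values / 100), -db$values, tolerance = 1e-9)
  two <- scalar_map(matrix(2, 4, 4), units = "ratio")
  one <- scalar_map(matrix(1, 4, 4), units = "ratio")
  expect_equal(b1_db_difference(two, one)$summary$mean, 6.02, tolerance = 0.01 / 6)
  expect_equal(b1_db_difference(scalar_map(matrix(1.122, 4, 4), units = "ratio"),
                                one)$summary$mean, 1.0, tolerance = 0.01)
  expect_equal(b1_db_difference(one, one)$summary$mean, 0)
})

test_that("signed percentage differences of noisy map pairs center on zero", {
  set.seed(8)
  means <- replicate(200, {
    base <- matrix(1.15, 3, 3)
    a <- scalar_map(base + matrix(rnorm(9, 0, 0.02), 3, 3), units = "ratio")
    b <- scalar_map(base + matrix(rnorm(9, 0, 0.02), 3, 3), units = "ratio")
    percent_difference_map(a, b)$summary$mean
  })
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)) + 0.02)
})

test_that("noise_correlation recovers constructed coupling and stays PSD", {
  set.seed(9)
  cplx <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))
  # duplicated channel -> off-diagonal exactly 1
  x <- cplx(500)
  dup <- rbind(x, x)
  expect_equal(noise_correlation(dup)$matrix[1, 2], 1, tolerance = 1e-12)
  # independent channels at 1e5 samples
  ind <- rbind(cplx(1e5), cplx(1e5), cplx(1e5))
  m <- noise_correlation(ind)$matrix
  expect_lt(max(m[upper.tri(m)]), 0.02)
  # mixing construction at rho = 0.6
  n <- 5e4
  common <- cplx(n)
  mixed <- t(sapply(1:4, function(i) sqrt(0.6) * common + sqrt(0.4) * cplx(n)))
  m6 <- noise_correlation(mixed)$matrix
  expect_equal(mean(m6[upper.tri(m6)]), 0.6, tolerance = 0.02 / 0.6)
  # structural invariants over generated cases
  for (rho in c(0, 0.3, 0.6)) {
    xx <- gen_noise_channels(synth_config(seed = 20 + round(10 * rho)),
                             n_channels = 4, rho = rho, n_samples = 2000)
    nm <- noise_correlation(xx)$matrix
    expect_equal(nm, t(nm))
    expect_equal(diag(nm), rep(1, 4))
    expect_gt(min(eigen(nm, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  expect_error(noise_correlation(rbind(cplx(200), rep(0 + 0i, 200))),
               "zero-variance channel: 2")
  expect_error(noise_correlation(rbind(cplx(50), cplx(50))), "100")
})
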