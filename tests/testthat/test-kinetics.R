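# Matching pursuit, two-site exchange simulation, kPL estimation, ratios.

test_that("matching pursuit recovers a single atom exactly", {
  axis <- test_axis()
  basis <- metabolite_basis()
  atom <- hypercal:::mp_dictionary(axis, basis)[, "pyruvate"]
  sp <- new_spectrum(7 * atom + 0i, axis)
  amps <- matching_pursuit_fit(sp, basis)
  expect_equal(unname(amps["pyruvate"]), 7, tolerance = 1e-9)
  expect_equal(unname(amps[names(amps) != "pyruvate"]), rep(0, 4))
})

test_that("matching pursuit equals projection on an orthogonal dictionary", {
  axis <- test_axis(256)
  # two disjoint-support "Lorentzian-like" atoms are orthogonal by distance:
  # at 2000 Hz separation with 10 Hz width the overlap is ~1e-8
  basis <- metabolite_basis(names = c("pyruvate", "lactate"),
                            offsets_hz = c(-1000, 1000), fwhm_hz = 10)
  A <- hypercal:::mp_dictionary(axis, basis)
  y <- 3.2 * A[, 1] + 0.45 * A[, 2]
  amps <- matching_pursuit_fit(new_spectrum(y + 0i, axis), basis)
  proj <- drop(crossprod(A, y))
  # the Lorentzian tails leave an atom overlap of ~1e-5, which bounds how
  # far projection and the exact decomposition can disagree
  expect_equal(unname(amps), unname(proj), tolerance = 1e-4)
})

test_that("well-separated and overlapping dictionaries match the LS oracle", {
  axis <- test_axis()
  sep <- metabolite_basis(names = c("pyruvate", "lactate"),
                          offsets_hz = c(0, 392), fwhm_hz = 20)
  y <- hypercal:::lorentzian_real(axis, 1, 0, 20) +
    hypercal:::lorentzian_real(axis, 0.15, 392, 20)
  amps <- matching_pursuit_fit(new_spectrum(y + 0i, axis), sep, 40, 1e-8)
  nrm <- sqrt(sum(hypercal:::lorentzian_real(axis, 1, 0, 20)^2))
  expect_equal(unname(amps["pyruvate"]) / nrm, 1, tolerance = 1e-3)
  expect_equal(unname(amps["lactate"]) / nrm, 0.15, tolerance = 1e-3 / 0.15)
  # overlapping atoms (separation = fwhm): compare to full LS oracle
  ov <- metabolite_basis(names = c("pyruvate", "lactate"),
                         offsets_hz = c(0, 20), fwhm_hz = 20)
  y2 <- hypercal:::lorentzian_real(axis, 1, 0, 20) +
    hypercal:::lorentzian_real(axis, 0.5, 20, 20)
  sp2 <- new_spectrum(y2 + 0i, axis)
  amps2 <- matching_pursuit_fit(sp2, ov, 40, 1e-8)
  oracle <- ls_dictionary_oracle(sp2, ov)
  expect_equal(unname(amps2), unname(oracle), tolerance = 0.05)
  # atom outside the axis is rejected
  far <- metabolite_basis(names = c("pyruvate", "x"), offsets_hz = c(0, 9000))
  expect_error(matching_pursuit_fit(sp2, far), "outside")
})

test_that("simulate_two_site matches closed forms and a fine-step integrator", {
  # kpl = 0 -> lactate identically zero
  z <- simulate_two_site(0, 1 / 30, 1 / 25, 1, 1, 12, 32)
  expect_equal(z$amplitudes$lactate, rep(0, 32))
  # mass conservation in the no-loss, vanishing-flip limit
  c0 <- simulate_two_site(0.007, 0, 0, 1, 1, 1e-8, 64)
  expect_lt(max(abs(rowSums(c0$pools) - 1)), 1e-9)
  expect_equal(c0$pools[, 1], exp(-0.007 * (0:63)), tolerance = 1e-9)
  # RK4 oracle across parameter sets
  cases <- list(c(0.007, 1 / 30, 1 / 25, 1, 12),
                c(0.05, 1 / 20, 1 / 40, 2, 20),
                c(0.001, 0, 0.1, 3, 5))
  for (cs in cases) {
    sim <- simulate_two_site(cs[1], cs[2], cs[3], 1, cs[4], cs[5], 20)
    ora <- integrate_two_site_fine(cs[1], cs[2], cs[3], 1, cs[4], cs[5], 20)
    expect_equal(sim$amplitudes$pyruvate, ora[, 1], tolerance = 1e-6)
    expect_equal(sim$amplitudes$lactate, ora[, 2], tolerance = 1e-6)
  }
  expect_error(simulate_two_site(-0.1, 0, 0, 1, 1, 12, 10), "non-negative")
})

test_that("time-domain kPL fit is a parameter-recovery identity, noiseless", {
  for (kpl in c(0.001, 0.007, 0.02, 0.05)) {
    for (flip in c(5, 12, 20)) {
      cur <- simulate_two_site(kpl, 1 / 30, 1 / 25, 1, 1, flip, 128)
      fit <- fit_kpl_time_domain(cur, r1l = 1 / 25)
      expect_equal(fit$kpl, kpl, tolerance = 1e-3)
    }
  }
  # tighter check at the working point
  cur <- simulate_two_site(0.007, 1 / 30, 1 / 25, 1, 1, 12, 128)
  expect_equal(fit_kpl_time_domain(cur, r1l = 1 / 25)$kpl, 0.007,
               tolerance = 1e-4 / 0.007)
  # lactate identically zero -> kpl 0
  cur0 <- simulate_two_site(0, 1 / 30, 1 / 25, 1, 1, 12, 64)
  expect_lt(fit_kpl_time_domain(cur0, r1l = 1 / 25)$kpl, 1e-6)
})

test_that("time-domain fit tolerates noise with small bias", {
  set.seed(21)
  truth <- simulate_two_site(0.007, 1 / 30, 1 / 25, 1, 1, 12, 128)
  peak <- max(truth$amplitudes$pyruvate)
  # noise on the quantified curves themselves (zero-mean, unrectified:
  # rectification is a reporting policy, not part of the estimator)
  est <- replicate(100, {
    noisy <- metabolite_curves(list(
      pyruvate = truth$amplitudes$pyruvate + rnorm(128, 0, peak / 20),
      lactate = truth$amplitudes$lactate + rnorm(128, 0, peak / 20)),
      tr = 1, flip = 12)
    fit_kpl_time_domain(noisy, r1l = 1 / 25)$kpl
  })
  expect_lt(abs(mean(est) - 0.007), 0.1 * 0.007)
})

test_that("frequency-domain fit agrees with the time-domain fit", {
  g <- gen_dynamic_study(synth_config(seed = 1), noiseless = TRUE)
  ff <- fit_kpl_frequency_domain(g$dyn, r1l = 1 / 25)
  ft <- fit_kpl_time_domain(g$curves, r1l = 1 / 25)
  expect_equal(ff$kpl, ft$kpl, tolerance = 1e-3)
  expect_equal(ff$domain, "frequency")
  # pyruvate-only study -> kpl 0
  cfg0 <- synth_config(seed = 2, kpl = 0, bic_pyr = 0)
  g0 <- gen_dynamic_study(cfg0, noiseless = TRUE)
  expect_lt(fit_kpl_frequency_domain(g0$dyn, r1l = 1 / 25)$kpl, 1e-6)
  # noisy: both estimators near each other (they share the quantified curves'
  # information up to quantification noise)
  gn <- gen_dynamic_study(synth_config(seed = 3))
  fn <- fit_kpl_frequency_domain(gn$dyn, r1l = 1 / 25)
  tn <- fit_kpl_time_domain(hypercal:::quantify_frames(gn$dyn, metabolite_basis()),
                            r1l = 1 / 25)
  expect_equal(fn$kpl, tn$kpl, tolerance = 1e-9)
  expect_lt(abs(fn$kpl - 0.007), 0.15 * 0.007)
})

test_that("amplitude scaling leaves kPL and ratios unchanged", {
  g <- gen_dynamic_study(synth_config(seed = 4), mode = "ratio")
  scaled <- dynamic_spectra(lapply(g$dyn$frames, function(fr)
    new_spectrum(fr$values * 37, fr$freq_axis)), tr = g$dyn$tr, flip = g$dyn$flip)
  expect_equal(fit_kpl_frequency_domain(scaled, r1l = 1 / 25)$kpl,
               fit_kpl_frequency_domain(g$dyn, r1l = 1 / 25)$kpl,
               tolerance = 1e-9)
  expect_equal(summed_spectrum_ratios(scaled)$lac_pyr,
               summed_spectrum_ratios(g$dyn)$lac_pyr, tolerance = 1e-9)
})

test_that("summed-spectrum ratios recover constructed values", {
  axis <- test_axis()
  mk <- function(lac) new_spectrum(
    hypercal:::lorentzian_complex(axis, 100, 0, 20) +
      hypercal:::lorentzian_complex(axis, lac, 392, 20), axis)
  dyn <- dynamic_spectra(replicate(8, mk(15), simplify = FALSE), tr = 1, flip = 12)
  rr <- summed_spectrum_ratios(dyn)
  expect_equal(rr$lac_pyr, 0.15, tolerance = 1e-3 / 0.15)
  # lactate-free frames
  dyn0 <- dynamic_spectra(replicate(4, mk(0), simplify = FALSE), tr = 1, flip = 12)
  expect_equal(summed_spectrum_ratios(dyn0)$lac_pyr, 0)
  # random per-frame phases -> destructive interference warning
  set.seed(23)
  frames <- lapply(runif(32, -pi, pi), function(ph)
    new_spectrum(mk(15)$values * exp(1i * ph), axis))
  dynp <- dynamic_spectra(frames, tr = 1, flip = 12)
  expect_warning(summed_spectrum_ratios(dynp), "destructive")
})

test_that("rectification is reported, not silently applied", {
  gn <- gen_dynamic_study(synth_config(seed = 5))
  q <- hypercal:::quantify_frames(gn$dyn, metabolite_basis())
  expect_gte(q$n_rectified, 0)
  expect_true(all(as.matrix(q$amplitudes) >= 0))
})
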