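test_that("absorption model is linear in its weights", {
  flat <- tissue_model(0, 0.5, 0, 0.1, 2, 0.3, 1)
  lam <- seq(400, 700, 10)
  expect_equal(mua_spectrum(flat, lam), rep(0.1, length(lam)))

  m1 <- tissue_model(0.5, 0.2, 0.1, 0.05, 2, 0.3, 1)
  m2 <- tissue_model(1.0, 0.2, 0.1, 0.05, 2, 0.3, 1)
  hb1 <- mua_spectrum(m1, lam) - mua_spectrum(flat, lam) * 0 -
    0.1 * chromophore_basis(lam)[, "bilirubin"] - 0.05
  hb2 <- mua_spectrum(m2, lam) -
    0.1 * chromophore_basis(lam)[, "bilirubin"] - 0.05
  expect_equal(hb2, 2 * hb1, tolerance = 1e-12)

  expect_error(mua_spectrum(m1, 380), "support")
  expect_true(all(mua_spectrum(m1, lam) >= 0))
})

test_that("scattering model is anchored at 500 nm with a Rayleigh limit", {
  m <- tissue_model(0, 0.5, 0, 0, 2.6, 0.4, 1.2)
  expect_equal(musp_spectrum(m, 500), 2.6, tolerance = 1e-12)
  ray <- tissue_model(0, 0.5, 0, 0, 1, 1, 1)
  expect_equal(musp_spectrum(ray, 400) / musp_spectrum(ray, 500),
               (500 / 400)^4, tolerance = 1e-12)
})

test_that("deoxygenated blood absorbs more than oxygenated in the red", {
  lam <- seq(600, 700, 2)
  b <- chromophore_basis(lam)
  expect_true(all(b[, "deoxy"] > b[, "oxy"]))
  expect_true(all(b >= 0))
})

test_that("ureter-like preset reproduces the reference scattering entries", {
  m <- tissue_preset("human_ureter")
  ref <- reference_spectra("ureter", "human")
  for (wl in c(410, 690)) {
    row <- ref[ref$wavelength == wl, ]
    expect_lt(abs(musp_spectrum(m, wl) - row$mu_sp), row$mu_sp_sd)
  }
  # dominant deoxyhemoglobin peaks at the grid points nearest 427/550 nm
  lam <- default_wavelengths()
  mua <- mua_spectrum(m, lam)
  peaks <- lam[which(diff(sign(diff(mua))) == -2) + 1]
  expect_true(425 %in% peaks)
  expect_true(550 %in% peaks)
  expect_error(tissue_preset("liver"), "unknown preset")
})

test_that("cohorts are reproducible, positive, and monotone in scattering", {
  co1 <- generate_cohort("human_ureter", n_samples = 6, seed = 13)
  co2 <- generate_cohort("human_ureter", n_samples = 6, seed = 13)
  expect_identical(cohort_truth(co1), cohort_truth(co2))

  tr <- cohort_truth(co1)
  expect_true(all(tr$mu_a >= 0))
  expect_true(all(tr$thickness >= 0.1))
  for (s in co1$samples) expect_true(all(diff(s$mu_sp) < 0))

  # inter-sample spread at 635 nm is of the order of the reference SD
  co <- generate_cohort("human_ureter", n_samples = 20, seed = 29)
  tr <- cohort_truth(co)
  s635 <- tr[tr$wavelength == 635, ]
  cv <- sd(s635$mu_sp) / mean(s635$mu_sp)
  ref_cv <- 0.35 / 1.71
  expect_gt(cv, ref_cv / 2)
  expect_lt(cv, ref_cv * 2)
})

test_that("simulated measurements carry the bounded calibration error", {
  lam <- c(532, 635)
  m <- tissue_preset("human_ureter")
  mua <- mua_spectrum(m, lam); musp <- musp_spectrum(m, lam)

  clean <- simulate_measurement(lam, mua, musp, 1.2,
                                instrument = instrument_config(
                                  n_photons = 5e3, noise = FALSE,
                                  n_replicates = 2), seed = 5)
  expect_equal(clean$Rd[clean$replicate == 1],
               clean$Rd[clean$replicate == 2])
  # noise-free records equal the raw forward tallies
  st <- build_slab(mua[1], musp[1], 1.2)
  r <- simulate_rt(st, n_photons = 5e3,
                   seed = (5 * 131071 + 1 * 7919) %% 2147483647)
  expect_identical(clean$Rd[1], r$Rd)

  noisy <- simulate_measurement(lam, mua, musp, 1.2,
                                instrument = instrument_config(
                                  n_photons = 5e3, n_replicates = 50),
                                seed = 5)
  rel <- abs(noisy$Rd / rep(clean$Rd[1:2], 50) - 1)
  expect_true(all(rel <= 0.008 + 1e-12))
  expect_gt(max(rel), 0.002)  # the noise is actually applied

  # reproducible end to end
  again <- simulate_measurement(lam, mua, musp, 1.2,
                                instrument = instrument_config(
                                  n_photons = 5e3, n_replicates = 50),
                                seed = 5)
  expect_identical(noisy, again)
})
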