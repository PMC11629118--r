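test_that("lookup table construction and interpolation are consistent", {
  expect_error(build_lookup(1, n_mua = 1), "at least 2")
  lut <- build_lookup(1.0, n_mua = 3, n_musp = 3, n_photons = 5e3, seed = 4,
                      mua_range = c(0.1, 2), musp_range = c(0.5, 4))
  expect_true(all(lut$Rd >= 0 & lut$Rd <= 1))
  expect_true(all(lut$Tt >= 0 & lut$Tt <= 1))

  # a node equals a direct forward run with the same seed
  st <- build_slab(lut$mua_grid[2], lut$musp_grid[2], 1.0)
  r <- simulate_rt(st, n_photons = 5e3, seed = 4)
  expect_identical(lut$Rd[2, 2], r$Rd)
  expect_identical(lut$Tt[2, 2], r$Tt)

  # interpolation identity at the nodes
  p <- uroptics:::lut_interpolate(lut, lut$mua_grid[3], lut$musp_grid[1])
  expect_equal(p$Rd, lut$Rd[3, 1], tolerance = 1e-12)
  expect_equal(p$Tt, lut$Tt[3, 1], tolerance = 1e-12)

  # transmittance falls with absorption along the grid rows
  expect_lt(lut$Tt[3, 2], lut$Tt[1, 2])
})

test_that("non-physical measurements are refused", {
  expect_error(invert_rdtt(0.6, 0.5, 1.0), "non-physical")
  expect_error(invert_rdtt(-0.1, 0.2, 1.0), "non-negative")
})

test_that("inversion is deterministic and self-consistent on a round trip", {
  lut <- build_lookup(1.0, n_mua = 4, n_musp = 4, n_photons = 5e3, seed = 2,
                      mua_range = c(0.05, 3), musp_range = c(0.5, 6))
  truth <- simulate_rt(build_slab(0.6, 2.2, 1.0), n_photons = 2e5, seed = 55)
  ctl <- unit_control()
  inv1 <- invert_rdtt(truth$Rd, truth$Tt, 1.0, lut = lut, control = ctl)
  inv2 <- invert_rdtt(truth$Rd, truth$Tt, 1.0, lut = lut, control = ctl)
  expect_identical(unclass(inv1), unclass(inv2))
  expect_lt(abs(inv1$mu_a - 0.6) / 0.6, 0.15)
  expect_lt(abs(inv1$mu_sp - 2.2) / 2.2, 0.15)

  # re-simulating at the recovered properties reproduces the measurement
  # within tol plus 3 combined SEs; the recovered parameters carry the
  # forward noise of the fitting budget, so that SE enters the combination
  st <- build_slab(inv1$mu_a, inv1$mu_sp, 1.0)
  re <- simulate_rt(st, n_photons = 2e5, seed = 56)
  tol <- ctl$tol
  expect_lt(abs(re$Rd - truth$Rd),
            tol * truth$Rd +
              3 * sqrt(re$se_Rd^2 + truth$se_Rd^2 + inv1$forward_se[1]^2))
  expect_lt(abs(re$Tt - truth$Tt),
            tol * truth$Tt +
              3 * sqrt(re$se_Tt^2 + truth$se_Tt^2 + inv1$forward_se[2]^2))
})

test_that("truths outside the grid are flagged, not silently clipped", {
  lut <- build_lookup(1.0, n_mua = 4, n_musp = 4, n_photons = 5e3, seed = 2,
                      mua_range = c(0.05, 1), musp_range = c(0.5, 3))
  # true absorption far above the grid ceiling
  truth <- simulate_rt(build_slab(4, 1.5, 1.0), n_photons = 1e5, seed = 77)
  inv <- invert_rdtt(truth$Rd, truth$Tt, 1.0, lut = lut,
                     control = unit_control())
  expect_true(inv$at_bound)
  expect_false(inv$converged)
})

test_that("a pure scatterer inverts to a near-zero absorption", {
  lut <- build_lookup(1.0, n_mua = 4, n_musp = 4, n_photons = 5e3, seed = 2,
                      mua_range = c(0.005, 2), musp_range = c(0.5, 5))
  truth <- simulate_rt(build_slab(0, 2, 1.0), n_photons = 1e6, seed = 88)
  inv <- invert_rdtt(truth$Rd, truth$Tt, 1.0, lut = lut,
                     control = imc_control(verify = FALSE))
  expect_lte(inv$mu_a, 0.02)
})

test_that("imc_fit averages replicates and summarizes cohorts correctly", {
  lut <- build_lookup(1.0, n_mua = 4, n_musp = 4, n_photons = 5e3, seed = 2,
                      mua_range = c(0.05, 3), musp_range = c(0.5, 6))
  m <- simulate_rt(build_slab(0.5, 2, 1.0), n_photons = 1e5, seed = 9)
  rec <- data.frame(wavelength = 635, Rd = m$Rd, Tt = m$Tt, thickness = 1.0)

  # duplicate identical samples -> zero cohort SD
  two <- rbind(transform(rec, sample = 1), transform(rec, sample = 2))
  fit2 <- imc_fit(two, lut = lut, control = unit_control())
  expect_equal(fit2$spectra$mu_a_sd, 0)
  expect_equal(fit2$spectra$mu_sp_sd, 0)
  expect_equal(fit2$spectra$n_samples, 2L)

  # replicates of one sample are averaged, and a single-sample cohort
  # reports SD as absent, not zero
  reps <- rbind(transform(rec, replicate = 1),
                transform(rec, Rd = rec$Rd * 1.01, replicate = 2))
  fit1 <- imc_fit(reps, lut = lut, control = unit_control())
  expect_equal(nrow(fit1$estimates), 1)
  expect_true(is.na(fit1$spectra$mu_a_sd))
  expect_equal(mean(c(rec$Rd, rec$Rd * 1.01)), fit1$data$Rd)

  # a non-physical wavelength is flagged and kept
  bad <- rbind(transform(rec, sample = 1),
               data.frame(wavelength = 700, Rd = 0.7, Tt = 0.4,
                          thickness = 1.0, sample = 1))
  fitb <- imc_fit(bad, lut = lut, control = unit_control())
  expect_equal(nrow(fitb$estimates), 2)
  expect_true(fitb$estimates$failed[fitb$estimates$wavelength == 700])
  expect_match(fitb$estimates$message[fitb$estimates$wavelength == 700],
               "non-physical")

  # methods on the fitted object
  expect_equal(dim(coef(fit2)), c(1, 2))
  expect_output(print(fit2), "Inverse Monte Carlo fit")
  expect_output(print(summary(fit2)), "cohort spectra")
  pr <- predict(fit2, n_photons = 5e3)
  expect_true(all(c("Rd_fit", "Tt_fit") %in% names(pr)))
  expect_equal(nrow(pr), 2)
})
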