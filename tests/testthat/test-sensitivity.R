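test_that("a baseline-only scan reports exactly zero change", {
  lut <- build_lookup(1.0, n_mua = 4, n_musp = 4, n_photons = 5e3, seed = 2,
                      mua_range = c(0.05, 3), musp_range = c(0.5, 6))
  m <- simulate_rt(build_slab(0.5, 2, 1.0), n_photons = 5e4, seed = 9)
  rec <- data.frame(wavelength = 635, Rd = m$Rd, Tt = m$Tt, thickness = 1.0)

  rep0 <- sensitivity_scan(rec, g_values = 0.9, n_values = 1.4, lut = lut,
                           control = unit_control())
  expect_true(all(rep0$changes$pct_mu_a == 0))
  expect_true(all(rep0$changes$pct_mu_sp == 0))
  expect_equal(sort(unique(rep0$changes$param)), c("g", "n"))
  expect_true(all(rep0$summary$mu_a_max_abs_pct == 0))

  expect_error(sensitivity_scan(rec, g_values = c(0.8, 0.95),
                                n_values = 1.4), "baseline")
})
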