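test_that("reference engine keeps the exact ledger and is reproducible", {
  st <- build_slab(0.4, 1.5, 0.8)
  a <- simulate_rt_reference(st, n_photons = 3e3, seed = 21)
  b <- simulate_rt_reference(st, n_photons = 3e3, seed = 21)
  expect_lt(abs(energy_total(a) - 1), 1e-9)
  expect_identical(unclass(a), unclass(b))
})

test_that("reference engine reproduces the Beer-Lambert limit", {
  r <- simulate_rt_reference(matched_slab(1, d = 1), pencil(),
                             open_detector(), n_photons = 2e4, seed = 5)
  expect_lt(abs(r$Tt - exp(-1)), 3 * r$se_Tt)
})

test_that("compiled engine agrees with the independent reference", {
  set.seed(77)
  for (k in 1:2) {
    st <- build_slab(runif(1, 0.2, 1), runif(1, 0.8, 2.5), runif(1, 0.6, 1.2))
    rc <- simulate_rt(st, n_photons = 1e5, seed = 123 + k)
    rr <- simulate_rt_reference(st, n_photons = 2e4, seed = 321 + k)
    for (q in c("Rd", "Tt")) {
      se <- sqrt(rc[[paste0("se_", q)]]^2 + rr[[paste0("se_", q)]]^2)
      expect_lt(abs(rc[[q]] - rr[[q]]), 3 * se)
    }
  }
})
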