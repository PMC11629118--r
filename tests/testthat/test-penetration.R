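test_that("penetration depth matches its closed form", {
  expect_equal(penetration_depth(1, 1)$delta, 1 / sqrt(6), tolerance = 1e-12)
  # reference-table means at 635 nm: porcine and human ureter
  expect_equal(penetration_depth(0.29, 2.17)$delta, 0.684, tolerance = 1e-3)
  expect_equal(penetration_depth(0.25, 1.71)$delta, 0.8248, tolerance = 1e-4)

  expect_error(penetration_depth(0, 1), "undefined")
  expect_error(penetration_depth(-1, 1), "undefined")

  pd <- penetration_depth(1, 1)  # ratio 1/3 > 0.1: outside diffusion regime
  expect_false(pd$valid)
  expect_match(attr(pd, "warning"), "diffusion")
  expect_true(penetration_depth(0.1, 2)$valid)
  expect_equal(penetration_depth(0.5, 0)$validity_ratio, Inf)
})

test_that("depth decreases with both coefficients and scales as 1/k", {
  mua <- seq(0.1, 2, length.out = 8)
  expect_true(all(diff(penetration_depth(mua, 2)$delta) < 0))
  musp <- seq(0.5, 5, length.out = 8)
  expect_true(all(diff(penetration_depth(0.3, musp)$delta) < 0))
  d0 <- penetration_depth(0.4, 1.7)$delta
  for (k in c(0.5, 2, 10))
    expect_equal(penetration_depth(0.4 * k, 1.7 * k)$delta, d0 / k,
                 tolerance = 1e-12)
})

test_that("cohort depth spectra aggregate per-sample-first", {
  coh <- data.frame(sample = rep(1:3, each = 2),
                    wavelength = rep(c(500, 600), 3),
                    mu_a = c(0.5, 0.3, 0.6, 0.35, 0.4, 0.25),
                    mu_sp = c(2, 1.8, 2.2, 1.9, 1.8, 1.7))
  ds <- depth_spectrum(coh)
  hand <- sapply(c(500, 600), function(w) {
    sub <- coh[coh$wavelength == w, ]
    mean(1 / sqrt(3 * sub$mu_a * (sub$mu_a + sub$mu_sp)))
  })
  expect_equal(ds$delta, hand, tolerance = 1e-12)
  expect_true(all(ds$n_samples == 3))

  same <- depth_spectrum(coh[coh$sample == 1, ])
  expect_true(all(is.na(same$delta_sd)))

  dup <- coh; dup$mu_a <- rep(c(0.5, 0.3), 3); dup$mu_sp <- rep(c(2, 1.8), 3)
  expect_equal(depth_spectrum(dup)$delta_sd, c(0, 0))

  one <- depth_spectrum(data.frame(wavelength = 635, mu_a = 0.25,
                                   mu_sp = 1.71))
  expect_equal(nrow(one), 1)

  # non-positive absorption is flagged, not dropped
  fl <- depth_spectrum(data.frame(wavelength = c(500, 600), mu_a = c(0, 0.3),
                                  mu_sp = c(2, 2)))
  expect_true(fl$flagged[1])
  expect_false(fl$flagged[2])
})

test_that("comparisons are reciprocal and reject empty bands", {
  a <- data.frame(wavelength = c(450, 550, 650), delta = c(0.3, 0.6, 0.9))
  b <- data.frame(wavelength = c(450, 550, 650), delta = c(0.36, 0.8, 0.95))
  ab <- compare_depths(a, b, mode = "ratio")
  ba <- compare_depths(b, a, mode = "ratio")
  expect_equal(ab$value, 1 / ba$value, tolerance = 1e-12)

  idem <- compare_depths(a, a, mode = "ratio")
  expect_equal(idem$band_min, 1)
  expect_equal(idem$band_max, 1)

  fd <- compare_depths(a, b, mode = "fractional_difference")
  expect_equal(fd$value, (a$delta - b$delta) / a$delta, tolerance = 1e-12)

  expect_error(compare_depths(a, b, band = c(200, 300)), "no shared")
})

test_that("tumor-to-normal depth ratios reproduce the reported bands", {
  ureter <- ref_depths("ureter", "human")
  uc <- ref_depths("ureteral_carcinoma", "human")
  rp <- ref_depths("renal_pelvic_carcinoma", "human")

  r_uc <- compare_depths(ureter, uc, band = c(400, 700), mode = "ratio")
  expect_equal(r_uc$band_min, 1.22, tolerance = 0.01)
  expect_equal(r_uc$band_max, 1.72, tolerance = 0.01)
  expect_equal(r_uc$wavelength[which.max(r_uc$value)], 410)

  r_rp <- compare_depths(ureter, rp, band = c(400, 700), mode = "ratio")
  expect_equal(round(r_rp$band_min, 1), 1.1)
  expect_equal(round(r_rp$band_max, 1), 1.5)
})
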