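test_that("build_slab applies the similarity relation and stacks glass", {
  st <- build_slab(mu_a = 0.25, mu_sp = 1.71, thickness = 1.2,
                   g = 0.9, n = 1.4)
  expect_equal(nrow(st$layers), 3)
  expect_equal(st$layers$mu_s[2], 17.1, tolerance = 1e-12)
  expect_equal(st$layers$n, c(1.524, 1.4, 1.524))
  expect_equal(st$layers$thickness, c(1.0, 1.2, 1.0))

  expect_equal(build_slab(0, 0, 0.7)$layers$mu_s[2], 0)
  expect_equal(build_slab(0, 1.0, 1, g = 0.5)$layers$mu_s[2], 2.0)

  expect_error(build_slab(0.1, 1, 0), "positive")
  expect_error(build_slab(0.1, -1, 1), "non-negative")
  expect_error(layer(1, 0.9), ">= 1")
})

test_that("hop, spin, and Fresnel primitives match their closed forms", {
  expect_equal(sample_step(exp(-1), 1), 1.0)
  expect_equal(sample_step(1, 5), 0.0)
  expect_equal(sample_step(0.5, 2), log(2) / 2)
  expect_error(sample_step(0.5, 0), "positive")

  expect_equal(sample_hg_cosine(1, 0.9), 1.0)
  expect_equal(sample_hg_cosine(0, 0.9), -1.0)
  expect_equal(sample_hg_cosine(0.5, 0), 0.0)
  # quadrature mean of the sampled cosine recovers the anisotropy factor
  u <- seq(1 / 2e5, 1 - 1 / 2e5, length.out = 1e5)
  for (g in c(-0.5, 0.3, 0.9, 0.95)) {
    expect_true(all(abs(sample_hg_cosine(u, g)) <= 1))
    expect_equal(mean(sample_hg_cosine(u, g)), g, tolerance = 1e-3)
  }

  expect_equal(fresnel_reflectance(1.0, 1.524, 1),
               ((1.524 - 1) / (1.524 + 1))^2, tolerance = 1e-12)
  expect_equal(fresnel_reflectance(1.4, 1.4, 0.3), 0)
  # beyond the critical angle: total internal reflection
  expect_equal(fresnel_reflectance(1.524, 1.0, 0.2), 1)
  # reciprocity at normal incidence
  expect_equal(fresnel_reflectance(1.0, 1.4, 1),
               fresnel_reflectance(1.4, 1.0, 1))
})

test_that("energy ledger is exact and runs are seed-deterministic", {
  set.seed(41)
  for (k in 1:5) {
    st <- build_slab(runif(1, 0.05, 2), runif(1, 0.5, 4),
                     runif(1, 0.5, 2))
    r <- simulate_rt(st, n_photons = 2e4, seed = 100 + k)
    expect_lt(abs(energy_total(r) - 1), 1e-9)
    expect_true(all(c(r$Rd, r$Tt, r$specular, r$lost) >= 0))
    expect_true(all(c(r$Rd, r$Tt, r$specular, r$lost) <= 1))
  }
  st <- build_slab(0.3, 2, 1)
  a <- simulate_rt(st, n_photons = 5e3, seed = 7)
  b <- simulate_rt(st, n_photons = 5e3, seed = 7)
  expect_identical(unclass(a), unclass(b))
  c_ <- simulate_rt(st, n_photons = 5e3, seed = 8)
  expect_false(identical(a$Rd, c_$Rd))
})

test_that("zero absorption with open ports conserves light exactly", {
  st <- matched_slab(0, mu_s = 20, g = 0.9, d = 1)
  r <- simulate_rt(st, pencil(), open_detector(), n_photons = 2e4, seed = 3)
  expect_identical(r$absorbed, 0)
  expect_identical(r$lost, 0)
  expect_lt(abs(r$specular + r$Rd + r$Tt - 1), 1e-9)
})

test_that("transmittance reaches the Beer-Lambert limit without scattering", {
  for (mu_a in c(0.3, 1, 2)) {
    for (d in c(0.4, 1)) {
      r <- simulate_rt(matched_slab(mu_a, d = d), pencil(), open_detector(),
                       n_photons = 2e4, seed = round(1000 * mu_a + d))
      expect_lt(abs(r$Tt - exp(-mu_a * d)), 3 * r$se_Tt + 1e-12)
      expect_equal(r$Rd, 0)
    }
  }
})

test_that("launch specular of the glass stack matches the analytic pile", {
  # non-scattering absorber: no diffuse light returns, so the specular
  # tally is purely the analytic multiple-reflection term
  st <- layer_stack(layer(1, 1.524), layer(1, 1.4, mu_a = 5),
                    layer(1, 1.524), ambient_n = 1)
  r <- simulate_rt(st, n_photons = 1e3, seed = 1)
  r1 <- fresnel_reflectance(1.0, 1.524, 1)
  r2 <- fresnel_reflectance(1.524, 1.4, 1)
  expect_equal(r$specular, r1 + (1 - r1)^2 * r2 / (1 - r1 * r2),
               tolerance = 1e-12)
})

test_that("raising absorption lowers both Rd and Tt beyond noise", {
  lo <- simulate_rt(build_slab(0.1, 2, 1), n_photons = 5e4, seed = 11)
  hi <- simulate_rt(build_slab(1.0, 2, 1), n_photons = 5e4, seed = 12)
  expect_gt(lo$Tt - hi$Tt, 3 * sqrt(lo$se_Tt^2 + hi$se_Tt^2))
  expect_gt(lo$Rd - hi$Rd, 3 * sqrt(lo$se_Rd^2 + hi$se_Rd^2))
})

test_that("invalid transport inputs are rejected", {
  st <- build_slab(0.3, 2, 1)
  expect_error(simulate_rt(st, n_photons = 0), ">= 1")
  expect_error(simulate_rt(list(), n_photons = 10), "layer_stack")
  expect_error(layer_stack(), "at least one")
})
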