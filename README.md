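# uroptics

Estimation of tissue optical properties — the absorption coefficient
μa(λ) and the reduced scattering coefficient μs′(λ) — from
double-integrating-sphere (DIS) measurements of diffuse reflectance (Rd)
and total transmittance (Tt), by inverse Monte Carlo, with projected
light penetration depths for comparing tissues. The package targets the
biophotonics workflow used to characterize upper-urinary-tract tissues
(ureter, peri-ureteral fat, urothelial carcinomas) in the 400–700 nm
range relevant to photodynamic therapy (410–690 nm) and laser ablation
(445/450, 532 nm), and ships a synthetic tissue-spectrum generator so the
whole pipeline is testable without measured data.

## What it computes

1. **Forward model** — `simulate_rt()`: MCML-style weighted-photon
   transport (hop–drop–spin, Henyey–Greenstein scattering, Fresnel
   boundaries) through a glass/tissue/glass slab, reproducing the DIS
   geometry (1 mm beam, 0.25 inch ports, background-subtracted specular).
   The energy ledger `specular + Rd + Tt + absorbed + lost = 1` is exact
   to 1e-9 on every run, and runs are bitwise reproducible by seed.
2. **Inverse fit** — `imc_fit()`: per-wavelength recovery of
   (μa, μs′) from measured (Rd, Tt) under fixed anisotropy g = 0.9 and
   refractive index n = 1.4, via lookup-table initialization plus a
   Nelder–Mead simplex on (log μa, log μs′) minimizing the combined
   relative misfit with common-random-number forward evaluations.
   Returns a classed object with `print`, `summary`, `coef`, `predict`,
   `residuals`, `plot` and `simulate` methods.
3. **Penetration depth** — `penetration_depth()`, `depth_spectrum()`,
   `compare_depths()`: the diffusion-regime projected depth

       delta = 1 / sqrt(3 * mu_a * (mu_a + mu_s'))

   with validity tracking (μa/(3μs′) ≤ 0.1), cohort aggregation, and
   banded tissue-pair ratio / fractional-difference summaries.
4. **Sensitivity** — `sensitivity_scan()`: re-inversion of the same
   records under g ∈ {0.8, 0.9, 0.95} and n ∈ {1.3, 1.4, 1.5}, one at a
   time, reporting percent changes of the recovered coefficients.
5. **Synthetic data** — `tissue_preset()`, `generate_cohort()`,
   `simulate_cohort()`: hemoglobin/bilirubin chromophore absorption,
   Rayleigh/Mie power-law scattering, lognormal inter-sample variability
   and a ±0.8% instrument calibration error, calibrated against the
   bundled reference table of published tissue optical properties
   (`reference_spectra()`).

A thin command-line wrapper (`inst/cli/uroptics.R`, subcommands `synth`,
`forward`, `invert`, `depth`, `compare`, `sensitivity`) maps 1:1 onto
these functions.

## Worked example

```r
library(uroptics)

# penetration depth of the human vs porcine ureter at 635 nm, from the
# bundled reference means
hu <- reference_spectra("ureter", "human")
pu <- reference_spectra("ureter", "porcine")
penetration_depth(hu$mu_a[hu$wavelength == 635], hu$mu_sp[hu$wavelength == 635])
#>       delta validity_ratio valid
#> 1 0.8247861     0.04873294  TRUE
penetration_depth(pu$mu_a[pu$wavelength == 635], pu$mu_sp[pu$wavelength == 635])
#>      delta validity_ratio valid
#> 1 0.683554     0.04454685  TRUE

# tumor-to-normal depth ratio across the band: prints its 1.22-1.72 range
compare_depths(ref <- depth_spectrum(hu, mode = "mean_properties"),
               depth_spectrum(reference_spectra("ureteral_carcinoma", "human"),
                              mode = "mean_properties"))
#> Depth comparison over 400-700 nm (delta_b / delta_a)
#>   band range: 1.222 to 1.723 (one decimal: 1.2 to 1.7)

# end-to-end synthetic round trip: generate a cohort, measure it, invert
coh <- generate_cohort("human_ureter", n_samples = 3, seed = 41,
                       lambda = c(450, 510, 635, 690))
rec <- simulate_cohort(coh, instrument = instrument_config(n_photons = 1e6),
                       seed = 42)
lut <- build_lookup(1.2, n_mua = 6, n_musp = 6, n_photons = 2e4, seed = 18)
fit <- imc_fit(rec, lut = lut,
               control = imc_control(verify = FALSE, maxit = 25,
                                     n_photons_stage2 = 5e4))
fit
#> Inverse Monte Carlo fit of optical-property spectra
#>   assumptions: g = 0.9, n = 1.4
#>   4 wavelengths, 3 sample(s), 12 inversions (12 converged, 0 failed)
round(coef(fit), 4)   # per-wavelength cohort mean mu_a, mu_sp (mm^-1)
#>       mu_a  mu_sp
#> 450 1.0017 3.5401
#> 510 0.4769 2.7598
#> 635 0.2615 1.7808
#> 690 0.2498 1.5272
```

The interpretation: at 635 nm light penetrates ~0.8 mm into the human
ureter versus ~0.7 mm in the porcine ureter, and carcinomas admit light
1.2–1.7× deeper than normal ureter — the quantities that drive dose
selection for light-based therapy and the choice of porcine tissue as an
ex vivo model.

## Package layout

- `R/`, `src/` — forward engine (Rcpp) and reference R engine, inverse
  solver, penetration depths, sensitivity scan, synthetic generator, IO
  and CLI.
- `inst/extdata/uut_optical_properties.csv` — bundled reference table
  (mean ± SD, six tissue/species combinations, eleven wavelengths).
- `vignettes/tissue-optics-methods.Rmd` — the model, its assumptions,
  tunable parameters, numerical choices and limitations.
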