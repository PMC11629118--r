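# shared fixtures for the test suite (built in code, nothing on disk)

# open geometry: no port clipping, no specular cone, no lateral loss
open_detector <- function() detector_geometry(port_radius = Inf,
                                              specular_cone_deg = 0,
                                              sample_halfwidth = Inf)

pencil <- function() beam_geometry(0, "pencil")

# bare absorbing/scattering slab with matched refractive indices
matched_slab <- function(mu_a, mu_s = 0, g = 0, d = 1) {
  layer_stack(layer(d, 1.0, mu_a = mu_a, mu_s = mu_s, g = g),
              ambient_n = 1.0)
}

# depth spectrum straight from the bundled reference table means
ref_depths <- function(tissue, species) {
  tab <- reference_spectra(tissue, species)
  depth_spectrum(data.frame(wavelength = tab$wavelength, mu_a = tab$mu_a,
                            mu_sp = tab$mu_sp), mode = "mean_properties")
}

# fast-but-honest inversion control for unit tests
unit_control <- function(...) {
  imc_control(n_photons_stage1 = 1e4, n_photons_stage2 = 3e4,
              verify = FALSE, ...)
}
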