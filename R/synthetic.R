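# Synthetic tissue-spectrum generator: ground-truth optical-property
# spectra with the statistical structure the measurement pipeline assumes
# (chromophore absorption peaks, monotone power-law reduced scattering,
# lognormal inter-sample variability, instrument calibration noise), so
# the full analysis is testable without any measured data.

.uroptics_env <- new.env(parent = emptyenv())

# md5 of the bundled transcription; guards against silent edits
.REF_TABLE_MD5 <- "4d53c76783dcce26c11f5f4e94bd48f3"

#' Bundled reference optical properties of upper-urinary-tract tissues
#'
#' Published mean +/- SD absorption and reduced scattering coefficients of
#' human and porcine upper-urinary-tract tissues at the eleven wavelengths
#' used for photodynamic therapy and laser ablation (410, 445, 450, 510,
#' 532, 545, 580, 630, 635, 664 and 690 nm).  These measured values serve
#' as calibration targets for the synthetic presets and as inputs for the
#' penetration-depth comparisons.
#'
#' @param tissue One of `"ureter"`, `"fat"`, `"ureteral_carcinoma"`,
#'   `"renal_pelvic_carcinoma"`, or `NULL` for all.
#' @param species `"human"`, `"porcine"`, or `NULL` for all.
#' @return A data frame with columns `tissue`, `species`, `wavelength`,
#'   `mu_a`, `mu_a_sd`, `mu_sp`, `mu_sp_sd`.
#' @export
reference_spectra <- function(tissue = NULL, species = NULL) {
  if (is.null(.uroptics_env$ref_table)) {
    path <- system.file("extdata", "uut_optical_properties.csv",
                        package = "uroptics")
    if (!nzchar(path)) stop("bundled reference table not found")
    if (unname(tools::md5sum(path)) != .REF_TABLE_MD5)
      stop("reference table failed its transcription checksum")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(tab)[names(tab) == "wavelength_nm"] <- "wavelength"
    .uroptics_env$ref_table <- tab
  }
  tab <- .uroptics_env$ref_table
  if (!is.null(tissue)) tab <- tab[tab$tissue == tissue, ]
  if (!is.null(species)) tab <- tab[tab$species == species, ]
  if (nrow(tab) == 0) stop("unknown tissue/species combination")
  rownames(tab) <- NULL
  tab
}

#' Default cohort wavelength grid
#'
#' 400-700 nm in 5 nm steps, with the eleven therapy wavelengths of the
#' reference table always included exactly.
#' @return Sorted numeric vector of wavelengths (nm).
#' @export
default_wavelengths <- function() {
  sort(unique(c(seq(400, 700, by = 5),
                c(410, 445, 450, 510, 532, 545, 580, 630, 635, 664, 690))))
}

#' Construct a synthetic tissue model
#'
#' Ground truth for one tissue: chromophore weights generating the
#' absorption spectrum and power-law parameters generating the reduced
#' scattering spectrum (see [mua_spectrum()] and [musp_spectrum()]).
#'
#' @param blood_volume_fraction Effective hemoglobin weight (mm^-1 at the
#'   relative-extinction peak; absorbs the physical volume fraction and
#'   the absolute extinction scale).
#' @param oxygen_saturation Fraction of hemoglobin oxygenated, in
#'   \[0, 1\].
#' @param bilirubin_weight Effective bilirubin weight, mm^-1.
#' @param baseline_mu_a Flat background absorption, mm^-1.
#' @param scatter_amplitude Reduced scattering at 500 nm, mm^-1.
#' @param rayleigh_fraction Fraction of the 500 nm reduced scattering due
#'   to the Rayleigh (`lambda^-4`) component, in \[0, 1\].
#' @param mie_power Mie scattering power-law exponent (>= 0).
#' @param thickness_mean,thickness_sd Cohort slab thickness distribution
#'   parameters, mm.
#' @param variability Named list of inter-sample variability parameters
#'   used by [generate_cohort()]: `sdlog_blood`, `sdlog_scatter`,
#'   `sdlog_bilirubin`, `sdlog_baseline` (lognormal log-SDs),
#'   `saturation_logit_sd`, `mie_power_sd`.
#' @param name Optional label.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(blood_volume_fraction, oxygen_saturation,
                         bilirubin_weight, baseline_mu_a,
                         scatter_amplitude, rayleigh_fraction, mie_power,
                         thickness_mean = 1.2, thickness_sd = 0.4,
                         variability = list(), name = "custom") {
  stopifnot(blood_volume_fraction >= 0, bilirubin_weight >= 0,
            baseline_mu_a >= 0, scatter_amplitude >= 0, mie_power >= 0,
            oxygen_saturation >= 0, oxygen_saturation <= 1,
            rayleigh_fraction >= 0, rayleigh_fraction <= 1)
  vdef <- list(sdlog_blood = 0.35, sdlog_scatter = 0.20,
               sdlog_bilirubin = 0.40, sdlog_baseline = 0.20,
               saturation_logit_sd = 0.5, mie_power_sd = 0.10)
  structure(list(blood_volume_fraction = blood_volume_fraction,
                 oxygen_saturation = oxygen_saturation,
                 bilirubin_weight = bilirubin_weight,
                 baseline_mu_a = baseline_mu_a,
                 scatter_amplitude = scatter_amplitude,
                 rayleigh_fraction = rayleigh_fraction,
                 mie_power = mie_power, thickness_mean = thickness_mean,
                 thickness_sd = thickness_sd,
                 variability = utils::modifyList(vdef, variability),
                 name = name),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("Synthetic tissue model '%s'\n", x$name))
  cat(sprintf("  blood %.3f mm^-1, SO2 %.2f, bilirubin %.3f, baseline %.3f\n",
              x$blood_volume_fraction, x$oxygen_saturation,
              x$bilirubin_weight, x$baseline_mu_a))
  cat(sprintf("  mu_sp(500) = %.2f mm^-1, Rayleigh fraction %.2f, Mie power %.2f\n",
              x$scatter_amplitude, x$rayleigh_fraction, x$mie_power))
  cat(sprintf("  thickness %.2f +/- %.2f mm\n", x$thickness_mean,
              x$thickness_sd))
  invisible(x)
}

#' Absorption spectrum of a tissue model
#'
#' `mu_a(lambda) = B * (S * eps_oxy + (1 - S) * eps_deoxy) +
#'  W_bil * eps_bil + baseline`, linear in every weight.
#'
#' @param model A [tissue_model()].
#' @param lambda Wavelengths (nm) within the 400-700 nm basis support.
#' @return Absorption coefficients, mm^-1.
#' @export
mua_spectrum <- function(model, lambda) {
  basis <- chromophore_basis(lambda)
  S <- model$oxygen_saturation
  model$blood_volume_fraction *
    (S * basis[, "oxy"] + (1 - S) * basis[, "deoxy"]) +
    model$bilirubin_weight * basis[, "bilirubin"] + model$baseline_mu_a
}

#' Reduced scattering spectrum of a tissue model
#'
#' Rayleigh/Mie mixture normalized at 500 nm:
#' `mu_sp(lambda) = a * (f * (lambda/500)^-4 + (1-f) * (lambda/500)^-b)`,
#' strictly decreasing in wavelength for `a > 0`.
#'
#' @inheritParams mua_spectrum
#' @return Reduced scattering coefficients, mm^-1.
#' @export
musp_spectrum <- function(model, lambda) {
  if (any(lambda < 400 | lambda > 700))
    stop("wavelengths outside the 400-700 nm support", call. = FALSE)
  x <- lambda / 500
  model$scatter_amplitude * (model$rayleigh_fraction * x^-4 +
    (1 - model$rayleigh_fraction) * x^-model$mie_power)
}

# cohort metadata for the built-in presets (sample counts and slab
# thickness mean +/- SD in mm)
.preset_meta <- list(
  human_ureter = list(tissue = "ureter", species = "human",
                      n_samples = 20, th = c(1.2, 0.4)),
  human_fat = list(tissue = "fat", species = "human",
                   n_samples = 15, th = c(1.5, 0.3)),
  ureteral_carcinoma = list(tissue = "ureteral_carcinoma",
                            species = "human", n_samples = 5,
                            th = c(1.8, 0.5)),
  renal_pelvic_carcinoma = list(tissue = "renal_pelvic_carcinoma",
                                species = "human", n_samples = 7,
                                th = c(1.7, 0.2)),
  porcine_ureter = list(tissue = "ureter", species = "porcine",
                        n_samples = 9, th = c(0.6, 0.2)),
  porcine_fat = list(tissue = "fat", species = "porcine",
                     n_samples = 9, th = c(1.6, 0.2))
)

#' Built-in tissue presets calibrated to the reference table
#'
#' Returns a [tissue_model()] whose chromophore weights and scattering
#' power-law parameters are fitted by SD-weighted least squares to the
#' bundled reference spectra ([reference_spectra()]) at their eleven
#' wavelengths.  Fits are cached per session.
#'
#' @param name One of `"human_ureter"`, `"human_fat"`,
#'   `"ureteral_carcinoma"`, `"renal_pelvic_carcinoma"`,
#'   `"porcine_ureter"`, `"porcine_fat"`.
#' @return A `tissue_model`.
#' @examples
#' m <- tissue_preset("human_ureter")
#' mua_spectrum(m, c(427, 550, 635))
#' @export
tissue_preset <- function(name) {
  if (!name %in% names(.preset_meta))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.preset_meta), collapse = ", "), call. = FALSE)
  key <- paste0("preset_", name)
  if (!is.null(.uroptics_env[[key]])) return(.uroptics_env[[key]])

  meta <- .preset_meta[[name]]
  ref <- reference_spectra(meta$tissue, meta$species)
  lam <- ref$wavelength
  basis <- chromophore_basis(lam)

  # absorption: SD-weighted least squares on (blood, saturation,
  # bilirubin, baseline).  Eleven wavelengths cannot identify the
  # oxygenation on their own, so the saturation is constrained to the
  # dominant hemoglobin species each tissue class exhibits (deoxy peaks
  # at 427/550 nm in urothelial tissue, oxy peaks at 416/540/575 nm in
  # fat).
  s_bounds <- if (meta$tissue == "fat") c(0.88, 1) else c(0, 0.12)
  wts <- 1 / ref$mu_a_sd^2
  fa <- function(p) {
    pred <- p[1] * (p[2] * basis[, "oxy"] + (1 - p[2]) * basis[, "deoxy"]) +
      p[3] * basis[, "bilirubin"] + p[4]
    sum(wts * (pred - ref$mu_a)^2)
  }
  oa <- stats::optim(c(1, mean(s_bounds), 0.1, 0.1), fa,
                     method = "L-BFGS-B",
                     lower = c(0, s_bounds[1], 0, 0),
                     upper = c(20, s_bounds[2], 20, 20))
  p <- oa$par
  blood <- p[1]
  S <- p[2]

  # reduced scattering: (amplitude, Rayleigh fraction, Mie power)
  wss <- 1 / ref$mu_sp_sd^2
  fs <- function(q) {
    x <- lam / 500
    pred <- q[1] * (q[2] * x^-4 + (1 - q[2]) * x^-q[3])
    sum(wss * (pred - ref$mu_sp)^2)
  }
  os <- stats::optim(c(mean(ref$mu_sp), 0.3, 1), fs, method = "L-BFGS-B",
                     lower = c(1e-3, 0, 0.05), upper = c(50, 1, 4))
  q <- os$par

  model <- tissue_model(blood_volume_fraction = blood,
                        oxygen_saturation = S,
                        bilirubin_weight = p[3], baseline_mu_a = p[4],
                        variability = list(),
                        scatter_amplitude = q[1], rayleigh_fraction = q[2],
                        mie_power = q[3], thickness_mean = meta$th[1],
                        thickness_sd = meta$th[2], name = name)
  attr(model, "n_samples") <- meta$n_samples
  .uroptics_env[[key]] <- model
  model
}

# seed-scoped RNG: run expr under set.seed(seed) and restore R's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a synthetic tissue cohort
#'
#' Draws per-sample ground-truth optical-property spectra around a tissue
#' model: lognormal multiplicative variability on the chromophore weights
#' and scattering amplitude (positivity-preserving), a logit-normal
#' jitter on the oxygen saturation, and slab thicknesses from a truncated
#' normal (minimum 0.1 mm).  Fully reproducible from the seed.
#'
#' @param preset A preset name (see [tissue_preset()]) or a
#'   [tissue_model()].
#' @param n_samples Cohort size (>= 1); defaults to the preset's study
#'   cohort size, or 10 for a custom model.
#' @param seed Integer seed.
#' @param lambda Wavelength grid (nm), default [default_wavelengths()].
#' @return An object of class `synthetic_cohort`: list with the `model`,
#'   `lambda`, and `samples` (each with `mu_a`, `mu_sp`, `thickness`).
#' @export
generate_cohort <- function(preset, n_samples = NULL, seed = 1,
                            lambda = default_wavelengths()) {
  model <- if (is.character(preset)) tissue_preset(preset) else preset
  if (!inherits(model, "tissue_model"))
    stop("preset must be a preset name or a tissue_model", call. = FALSE)
  if (is.null(n_samples))
    n_samples <- if (!is.null(attr(model, "n_samples")))
      attr(model, "n_samples") else 10
  stopifnot(n_samples >= 1)
  v <- model$variability

  samples <- with_seed(seed, {
    lapply(seq_len(n_samples), function(i) {
      m <- model
      m$blood_volume_fraction <- model$blood_volume_fraction *
        stats::rlnorm(1, 0, v$sdlog_blood)
      m$bilirubin_weight <- model$bilirubin_weight *
        stats::rlnorm(1, 0, v$sdlog_bilirubin)
      m$baseline_mu_a <- model$baseline_mu_a *
        stats::rlnorm(1, 0, v$sdlog_baseline)
      m$scatter_amplitude <- model$scatter_amplitude *
        stats::rlnorm(1, 0, v$sdlog_scatter)
      s0 <- min(max(model$oxygen_saturation, 1e-3), 1 - 1e-3)
      lg <- log(s0 / (1 - s0)) + stats::rnorm(1, 0, v$saturation_logit_sd)
      m$oxygen_saturation <- 1 / (1 + exp(-lg))
      m$mie_power <- max(0.05, model$mie_power +
                           stats::rnorm(1, 0, v$mie_power_sd))
      th <- max(0.1, stats::rnorm(1, model$thickness_mean,
                                  model$thickness_sd))
      list(mu_a = mua_spectrum(m, lambda), mu_sp = musp_spectrum(m, lambda),
           thickness = th, model = m)
    })
  })
  structure(list(model = model, lambda = lambda, samples = samples,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort '%s': %d samples, %d wavelengths (seed %d)\n",
    x$model$name, length(x$samples), length(x$lambda), x$seed))
  invisible(x)
}

#' Ground-truth spectra of a cohort as a data frame
#'
#' @param cohort A [generate_cohort()] object.
#' @return Data frame with `sample`, `wavelength`, `mu_a`, `mu_sp`,
#'   `thickness`.
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(seq_along(cohort$samples), function(i) {
    s <- cohort$samples[[i]]
    data.frame(sample = i, wavelength = cohort$lambda, mu_a = s$mu_a,
               mu_sp = s$mu_sp, thickness = s$thickness)
  }))
}

#' Instrument configuration for simulated measurements
#'
#' @param n_photons Forward photon budget per wavelength.
#' @param calibration_error Half-width of the uniform multiplicative
#'   calibration error applied independently to Rd and Tt per replicate
#'   (default 0.008, i.e. the 0.8% double-integrating-sphere calibration
#'   bound).
#' @param n_replicates Repeated measurements per sample (default 3).
#' @param noise Apply the calibration error (`FALSE` returns the raw
#'   forward tallies).
#' @export
instrument_config <- function(n_photons = 1e6, calibration_error = 0.008,
                              n_replicates = 3, noise = TRUE) {
  list(n_photons = n_photons, calibration_error = calibration_error,
       n_replicates = n_replicates, noise = noise)
}

#' Simulate double-integrating-sphere measurements of a spectrum
#'
#' Runs the forward Monte Carlo per wavelength at the true optical
#' properties, then applies a multiplicative calibration error drawn
#' uniformly within the instrument's calibration bound, independently per
#' replicate and per channel.
#'
#' @param wavelength,mu_a,mu_sp True spectra (equal-length vectors).
#' @param thickness Slab thickness, mm.
#' @param g,n True anisotropy and refractive index used in the forward
#'   simulation.
#' @param glass,beam,detector Measurement geometry.
#' @param instrument An [instrument_config()].
#' @param seed Integer seed (drives both the engine and the noise draws).
#' @return A data frame of measurement records: `wavelength`, `Rd`, `Tt`,
#'   `thickness`, `replicate`.
#' @export
simulate_measurement <- function(wavelength, mu_a, mu_sp, thickness,
                                 g = 0.9, n = 1.4, glass = glass_slide(),
                                 beam = beam_geometry(),
                                 detector = detector_geometry(),
                                 instrument = instrument_config(),
                                 seed = 1) {
  stopifnot(length(wavelength) == length(mu_a),
            length(wavelength) == length(mu_sp))
  nw <- length(wavelength)
  base <- data.frame(wavelength = wavelength, Rd = NA_real_, Tt = NA_real_)
  for (i in seq_len(nw)) {
    st <- build_slab(mu_a[i], mu_sp[i], thickness, g, n, glass)
    r <- simulate_rt(st, beam, detector, instrument$n_photons,
                     seed = (seed * 131071 + i * 7919) %% 2147483647)
    base$Rd[i] <- r$Rd
    base$Tt[i] <- r$Tt
  }
  recs <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(instrument$n_replicates), function(rep) {
      out <- base
      if (instrument$noise && instrument$calibration_error > 0) {
        ce <- instrument$calibration_error
        out$Rd <- out$Rd * (1 + stats::runif(nw, -ce, ce))
        out$Tt <- out$Tt * (1 + stats::runif(nw, -ce, ce))
      }
      out$replicate <- rep
      out
    }))
  })
  recs$thickness <- thickness
  recs[, c("wavelength", "Rd", "Tt", "thickness", "replicate")]
}

#' Simulate measurements for a whole synthetic cohort
#'
#' @param cohort A [generate_cohort()] object.
#' @param ... Passed to [simulate_measurement()].
#' @param seed Integer seed; each sample gets a derived seed.
#' @return A data frame of records with a `sample` column, ready for
#'   [imc_fit()].
#' @export
simulate_cohort <- function(cohort, ..., seed = 1) {
  do.call(rbind, lapply(seq_along(cohort$samples), function(i) {
    s <- cohort$samples[[i]]
    rec <- simulate_measurement(cohort$lambda, s$mu_a, s$mu_sp,
                                s$thickness, ...,
                                seed = (seed + 104729 * i) %% 2147483647)
    rec$sample <- i
    rec
  }))
}
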