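#' Projected light penetration depth
#'
#' In the diffusion regime (`mu_a << 3 mu_sp`) the depth over which the
#' fluence decays by 1/e is
#' `delta = 1 / sqrt(3 mu_a (mu_a + mu_sp))`.
#' The validity of the approximation is tracked through the ratio
#' `mu_a / (3 mu_sp)`; values above 0.1 attach a warning flag, since the
#' diffusion picture degrades as absorption approaches scattering.
#'
#' @param mu_a Absorption coefficient(s), mm^-1 (> 0).
#' @param mu_sp Reduced scattering coefficient(s), mm^-1 (>= 0).
#' @return A data frame with columns `delta` (mm), `validity_ratio`
#'   (`Inf` for a pure absorber), and `valid` (`validity_ratio <= 0.1`).
#' @examples
#' penetration_depth(0.29, 2.17)  # ~0.68 mm
#' @export
penetration_depth <- function(mu_a, mu_sp) {
  if (any(!is.finite(mu_a)) || any(mu_a <= 0))
    stop("penetration depth undefined for mu_a <= 0", call. = FALSE)
  if (any(mu_sp < 0)) stop("mu_sp must be >= 0", call. = FALSE)
  delta <- 1 / sqrt(3 * mu_a * (mu_a + mu_sp))
  ratio <- ifelse(mu_sp > 0, mu_a / (3 * mu_sp), Inf)
  out <- data.frame(delta = delta, validity_ratio = ratio,
                    valid = ratio <= 0.1)
  if (any(!out$valid))
    attr(out, "warning") <-
      "mu_a/(3 mu_sp) > 0.1 for some entries: diffusion approximation degraded"
  out
}

#' Penetration-depth spectrum of a cohort
#'
#' Computes the projected penetration depth per sample and wavelength and
#' aggregates across samples (mean and sample SD).  The order of
#' operations is per-sample-first: depths are computed for each sample's
#' own optical properties and then averaged, which matches cohort
#' reporting of depth means; a `mean_properties` mode computes a single
#' depth from cohort-mean optical properties instead (the only option
#' when per-sample spectra are unavailable).  Wavelengths with
#' non-positive `mu_a` are flagged, not dropped.
#'
#' @param x An [imc_fit()] object, or a data frame with columns
#'   `wavelength`, `mu_a`, `mu_sp` and optionally `sample`.
#' @param mode `"per_sample"` (default) or `"mean_properties"`.
#' @return An object of class `depth_spectrum`: a data frame with
#'   `wavelength`, `delta`, `delta_sd`, `validity_ratio`, `n_samples`,
#'   `flagged`.
#' @export
depth_spectrum <- function(x, mode = c("per_sample", "mean_properties")) {
  mode <- match.arg(mode)
  if (inherits(x, "imc_fit")) {
    df <- if (mode == "per_sample")
      x$estimates[!x$estimates$failed,
                  c("sample", "wavelength", "mu_a", "mu_sp")]
    else
      data.frame(sample = 1L, wavelength = x$spectra$wavelength,
                 mu_a = x$spectra$mu_a, mu_sp = x$spectra$mu_sp)
  } else {
    df <- as.data.frame(x)
    if (!all(c("wavelength", "mu_a", "mu_sp") %in% names(df)))
      stop("need columns wavelength, mu_a, mu_sp", call. = FALSE)
    if (is.null(df$sample)) df$sample <- 1L
    if (mode == "mean_properties") {
      df <- stats::aggregate(cbind(mu_a, mu_sp) ~ wavelength, data = df,
                             FUN = mean)
      df$sample <- 1L
    }
  }
  if (nrow(df) == 0) stop("empty spectrum", call. = FALSE)

  wl <- sort(unique(df$wavelength))
  out <- data.frame(wavelength = wl, delta = NA_real_, delta_sd = NA_real_,
                    validity_ratio = NA_real_, n_samples = 0L,
                    flagged = FALSE)
  for (i in seq_along(wl)) {
    sub <- df[df$wavelength == wl[i], ]
    bad <- !is.finite(sub$mu_a) | sub$mu_a <= 0
    if (any(bad)) out$flagged[i] <- TRUE
    sub <- sub[!bad, ]
    if (nrow(sub) == 0) next
    pd <- penetration_depth(sub$mu_a, sub$mu_sp)
    out$delta[i] <- mean(pd$delta)
    out$validity_ratio[i] <- mean(pd$validity_ratio)
    out$n_samples[i] <- nrow(sub)
    if (nrow(sub) > 1) out$delta_sd[i] <- stats::sd(pd$delta)
  }
  class(out) <- c("depth_spectrum", "data.frame")
  out
}

#' @export
print.depth_spectrum <- function(x, digits = 3, ...) {
  cat("Projected light penetration depth spectrum (mm)\n")
  df <- as.data.frame(x)
  df$delta_1dp <- round(df$delta, 1)  # one-decimal presentation values
  print(df, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Compare penetration-depth spectra of two tissues
#'
#' Per-wavelength comparison over a wavelength band, summarized by the
#' band minimum and maximum.  `ratio` mode reports `b / a` (e.g. tumor
#' over normal when `a` is the normal tissue); `fractional_difference`
#' reports `(a - b) / a` (the fractional reduction of `b` relative to
#' `a`).
#'
#' @param a,b `depth_spectrum` objects (or data frames with `wavelength`
#'   and `delta`) on a shared wavelength grid.
#' @param band Wavelength interval `c(min, max)` in nm.
#' @param mode `"ratio"` or `"fractional_difference"`.
#' @return An object of class `depth_comparison`: list with `wavelength`,
#'   `value`, `band_min`, `band_max`, `band`, `mode`.
#' @examples
#' a <- data.frame(wavelength = c(500, 600), delta = c(0.5, 0.8))
#' b <- data.frame(wavelength = c(500, 600), delta = c(0.6, 1.0))
#' compare_depths(a, b, band = c(400, 700), mode = "ratio")
#' @export
compare_depths <- function(a, b, band = c(400, 700),
                           mode = c("ratio", "fractional_difference")) {
  mode <- match.arg(mode)
  a <- as.data.frame(a); b <- as.data.frame(b)
  wl <- intersect(a$wavelength, b$wavelength)
  wl <- sort(wl[wl >= band[1] & wl <= band[2]])
  if (length(wl) == 0)
    stop("no shared wavelengths inside the band", call. = FALSE)
  da <- a$delta[match(wl, a$wavelength)]
  db <- b$delta[match(wl, b$wavelength)]
  value <- if (mode == "ratio") db / da else (da - db) / da
  structure(list(wavelength = wl, value = value,
                 band_min = min(value), band_max = max(value),
                 band = band, mode = mode),
            class = "depth_comparison")
}

#' @export
print.depth_comparison <- function(x, ...) {
  lab <- if (x$mode == "ratio") "delta_b / delta_a"
         else "(delta_a - delta_b) / delta_a"
  cat(sprintf("Depth comparison over %g-%g nm (%s)\n", x$band[1], x$band[2],
              lab))
  cat(sprintf("  band range: %.3f to %.3f (one decimal: %.1f to %.1f)\n",
              x$band_min, x$band_max, round(x$band_min, 1),
              round(x$band_max, 1)))
  invisible(x)
}
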