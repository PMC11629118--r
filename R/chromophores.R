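# Embedded relative chromophore absorption curves on 400-700 nm, built as
# sums of Gaussian bands at the visible peak wavelengths of the tissue
# chromophores (deoxyhemoglobin: 427 and 550 nm; oxyhemoglobin: 416, 540
# and 575 nm; bilirubin: 485 nm) plus broad red-tail terms.  The curves are
# relative shapes (peak-normalized, dimensionless); tissue models scale
# them by effective chromophore weights in mm^-1.  The deoxy tail exceeds
# the oxy tail so that deoxygenated blood absorbs more than oxygenated
# blood everywhere in 600-700 nm, as it does in vivo.

gauss_band <- function(lambda, center, width) {
  exp(-((lambda - center)^2) / (2 * width^2))
}

eps_deoxy <- function(lambda) {
  gauss_band(lambda, 427, 20) +
    0.30 * gauss_band(lambda, 550, 18) +
    0.060 * gauss_band(lambda, 605, 120)
}

eps_oxy <- function(lambda) {
  1.05 * gauss_band(lambda, 416, 15) +
    0.26 * gauss_band(lambda, 540, 14) +
    0.30 * gauss_band(lambda, 575, 12) +
    0.012 * gauss_band(lambda, 640, 150)
}

eps_bilirubin <- function(lambda) {
  gauss_band(lambda, 485, 30)
}

#' Relative chromophore absorption basis
#'
#' Evaluates the embedded relative absorption curves of oxyhemoglobin,
#' deoxyhemoglobin and bilirubin on a wavelength grid.  Curves are
#' dimensionless shapes; [mua_spectrum()] scales them by effective
#' weights with units of mm^-1.
#'
#' @param lambda Wavelengths in nm, within 400-700 nm.
#' @return A matrix with columns `oxy`, `deoxy`, `bilirubin`.
#' @export
chromophore_basis <- function(lambda) {
  if (any(lambda < 400 | lambda > 700))
    stop("wavelengths outside the 400-700 nm basis support", call. = FALSE)
  cbind(oxy = eps_oxy(lambda), deoxy = eps_deoxy(lambda),
        bilirubin = eps_bilirubin(lambda))
}
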