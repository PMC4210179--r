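# Spectral band grid and PAR reduction.

PLANCK_H <- 6.62607015e-34   # J s
LIGHT_C <- 2.99792458e8      # m s^-1
AVOGADRO <- 6.02214076e23    # mol^-1

#' Spectral waveband grid
#'
#' The model's fixed spectral discretisation: 17 contiguous wavebands of
#' 20 nm width spanning 400--740 nm. All spectral quantities in the package
#' (radiance, irradiance, absorption, reflectance) are resolved on this grid;
#' photosynthetically available radiation (PAR) integrates the 15 bands whose
#' upper edge does not exceed 700 nm, the remaining 700--740 nm bands being
#' carried for spectral completeness only.
#'
#' @return A data frame with columns `lower`, `upper`, `centre` (nm) and
#'   logical `par` marking bands inside 400--700 nm.
#' @export
spectral_bands <- function() {
  lower <- seq(400, 720, by = 20)
  data.frame(
    lower = lower,
    upper = lower + 20,
    centre = lower + 10,
    par = (lower + 20) <= 700
  )
}

n_bands <- function() 17L

#' Reduce band-integrated spectral irradiance to PAR photon flux
#'
#' Converts planar spectral irradiance on the 17-band grid (W m^-2 per band,
#' band-integrated) to photosynthetically available radiation in
#' micromol quanta m^-2 s^-1, summing photons over the 400--700 nm bands.
#' Each band's photon flux uses the band-centre wavelength:
#' E_band * lambda_c / (h c N_A).
#'
#' @param e_band Numeric vector (or matrix with bands in columns) of
#'   band-integrated irradiance, W m^-2, in band order of [spectral_bands()].
#' @param bands Band grid, defaults to [spectral_bands()].
#' @return PAR in micromol quanta m^-2 s^-1 (vector if `e_band` is a matrix,
#'   one value per row).
#' @export
to_par <- function(e_band, bands = spectral_bands()) {
  w <- photon_weights(bands)
  if (is.matrix(e_band)) {
    stopifnot(ncol(e_band) == nrow(bands))
    return(as.numeric(e_band %*% w))
  }
  stopifnot(length(e_band) == nrow(bands))
  sum(e_band * w)
}

# micromol photons per joule for each band (zero outside PAR range)
photon_weights <- function(bands = spectral_bands()) {
  w <- bands$centre * 1e-9 / (PLANCK_H * LIGHT_C * AVOGADRO) * 1e6
  w[!bands$par] <- 0
  w
}

#' Resample a wavelength-resolved spectrum onto the model band grid
#'
#' Linear interpolation of a 2-column (wavelength nm, value) spectrum,
#' averaged over each 20 nm band (11-point mean per band). Used to bring
#' externally supplied inherent optical property or surface spectra onto the
#' model grid.
#'
#' @param wavelength,value Numeric vectors describing the spectrum.
#' @param bands Band grid.
#' @return Numeric vector, one value per band.
#' @export
resample_to_bands <- function(wavelength, value, bands = spectral_bands()) {
  stopifnot(length(wavelength) == length(value), length(wavelength) >= 2)
  vapply(seq_len(nrow(bands)), function(i) {
    wl <- seq(bands$lower[i], bands$upper[i], length.out = 11L)
    mean(approx(wavelength, value, xout = wl, rule = 2)$y)
  }, numeric(1))
}
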