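#' Diffraction-limited lateral resolution of a confocal system
#'
#' `r_lateral = 1.22 * lambda / (2 * NA)`. For the 532 nm laser through a
#' water-immersion objective with NA = 1.0 this is 324.5 nm, displayed as
#' 325 nm.
#'
#' @param wavelength Laser wavelength in nm (> 0).
#' @param numerical_aperture Objective numerical aperture (> 0).
#' @return Lateral resolution in nm (full precision; round only for
#'   display).
#' @export
lateral_resolution <- function(wavelength, numerical_aperture) {
  check_positive(wavelength, "wavelength")
  check_positive(numerical_aperture, "numerical_aperture")
  1.22 * wavelength / (2 * numerical_aperture)
}

#' Diffraction-limited axial resolution of a confocal system
#'
#' `r_axial = 1.4 * lambda * n / NA^2`. For 532 nm, n = 1.33 (water) and
#' NA = 1.0 this is 990.6 nm, displayed as 991 nm.
#'
#' @inheritParams lateral_resolution
#' @param refractive_index Immersion-medium refractive index (> 0).
#' @return Axial resolution in nm (full precision).
#' @export
axial_resolution <- function(wavelength, refractive_index, numerical_aperture) {
  check_positive(wavelength, "wavelength")
  check_positive(refractive_index, "refractive_index")
  check_positive(numerical_aperture, "numerical_aperture")
  1.4 * wavelength * refractive_index / numerical_aperture^2
}

#' Fraction of an emission spectrum captured by a detection window
#'
#' Integrates a wavelength-domain emission spectrum over
#' `[center - span/2, center + span/2]` and divides by the total integral.
#' Used to compare grating settings: for the NV emission model a 680 nm
#' centre captures more of the phonon sideband than the standard 610 nm
#' Raman setting.
#'
#' @param emission Data frame with numeric columns `wavelength` (nm,
#'   strictly increasing) and `intensity` (non-negative, positive total),
#'   e.g. from [nv_spectrum()].
#' @param center Window centre (nm).
#' @param span Window width (nm, > 0).
#' @return Captured fraction in `[0, 1]`.
#' @export
window_capture_fraction <- function(emission, center, span) {
  stopifnot(
    is.data.frame(emission),
    all(c("wavelength", "intensity") %in% names(emission))
  )
  check_positive(span, "span")
  x <- emission$wavelength
  y <- emission$intensity
  if (any(y < 0)) abort("`intensity` must be non-negative.")
  total <- trapz(x, y)
  if (total <= 0) abort("Total emission is zero: capture fraction undefined.")
  lo <- center - span / 2
  hi <- center + span / 2
  inside <- x >= lo & x <= hi
  if (sum(inside) < 2) return(0)
  trapz(x[inside], y[inside]) / total
}
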