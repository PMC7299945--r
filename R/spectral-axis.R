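# Conversion constant between nm and cm^-1 (1 nm = 1e-7 cm).
NM_CM <- 1e7

#' Convert a Raman shift to the Stokes emission wavelength
#'
#' A Raman shift `shift` (cm^-1) under excitation at `excitation` (nm)
#' is scattered at wavelength `1e7 / (1e7/excitation - shift)` nm.
#' The conversion is strictly increasing in the shift, so an ordered shift
#' axis maps to an ordered wavelength axis.
#'
#' @param shift Raman shift(s) in cm^-1. Must satisfy
#'   `shift < 1e7 / excitation` (the Stokes side; larger shifts have no
#'   finite emission wavelength).
#' @param excitation Excitation laser wavelength in nm (> 0).
#' @return Emission wavelength(s) in nm.
#' @examples
#' shift_to_wavelength(0, 532)     # the laser line itself
#' shift_to_wavelength(2920, 532)  # the protein C-H stretching band
#' @export
shift_to_wavelength <- function(shift, excitation) {
  check_positive(excitation, "excitation")
  nu0 <- NM_CM / excitation
  if (any(shift >= nu0)) {
    abort(sprintf(
      "`shift` must be < %0.1f cm^-1 for %g nm excitation (finite Stokes wavelength).",
      nu0, excitation
    ))
  }
  NM_CM / (nu0 - shift)
}

#' Convert an emission wavelength back to a Raman shift
#'
#' Exact inverse of [shift_to_wavelength()].
#'
#' @param wavelength Emission wavelength(s) in nm; must be >= `excitation`.
#' @inheritParams shift_to_wavelength
#' @return Raman shift(s) in cm^-1.
#' @export
wavelength_to_shift <- function(wavelength, excitation) {
  check_positive(excitation, "excitation")
  if (any(wavelength < excitation)) {
    abort("`wavelength` must be >= `excitation` (Stokes side only).")
  }
  NM_CM / excitation - NM_CM / wavelength
}

#' Calibrated spectral axis of a hyperspectral scan
#'
#' The axis stores the per-channel Raman shifts (cm^-1) together with the
#' excitation wavelength; emission wavelengths are always derived from the
#' shifts via [shift_to_wavelength()], never stored, so the two views of
#' the axis can never drift apart.
#'
#' @param shifts Strictly increasing numeric vector of Raman shifts
#'   (cm^-1), length >= 2.
#' @param excitation_nm Excitation wavelength in nm (default 532, the
#'   frequency-doubled Nd:YAG line used for combined NV/Raman work).
#' @return An object of class `spectral_axis`.
#' @examples
#' ax <- spectral_axis(seq(100, 4000, by = 4))
#' range(axis_wavelengths(ax))
#' @export
spectral_axis <- function(shifts, excitation_nm = 532) {
  shifts <- as.numeric(shifts)
  if (length(shifts) < 2) abort("`shifts` must have length >= 2.")
  if (any(!is.finite(shifts))) abort("`shifts` must be finite.")
  if (any(diff(shifts) <= 0)) abort("`shifts` must be strictly increasing.")
  check_positive(excitation_nm, "excitation_nm")
  if (max(shifts) >= NM_CM / excitation_nm) {
    abort("All shifts must be below 1e7/excitation_nm (finite Stokes wavelength).")
  }
  structure(
    list(shifts = shifts, excitation_nm = excitation_nm),
    class = "spectral_axis"
  )
}

#' Emission wavelengths of a spectral axis
#'
#' @param axis A [spectral_axis()].
#' @return Numeric vector of emission wavelengths (nm), strictly increasing.
#' @export
axis_wavelengths <- function(axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  shift_to_wavelength(axis$shifts, axis$excitation_nm)
}

#' @export
length.spectral_axis <- function(x) length(x$shifts)

#' @export
print.spectral_axis <- function(x, ...) {
  wl <- axis_wavelengths(x)
  cat(sprintf(
    "<spectral_axis> %d channels, %.1f-%.1f cm^-1 (%.1f-%.1f nm) @ %g nm excitation\n",
    length(x$shifts), min(x$shifts), max(x$shifts), min(wl), max(wl),
    x$excitation_nm
  ))
  invisible(x)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be a positive finite number.", name))
  }
  invisible(x)
}
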