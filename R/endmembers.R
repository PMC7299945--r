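# Spectral endmembers of the synthetic phantom, as sums of Gaussian bands
# (center cm^-1, sigma cm^-1, relative height). Peak positions follow the
# published band assignments: protein C-H at 2920 cm^-1, lipid C-H at
# 2855 cm^-1, whole-cell C-H composite at 2915 cm^-1, water O-H at
# 3400 cm^-1 and the CaF2 substrate line at 320 cm^-1. Shoulder weights
# were balanced so each argmax sits on its nominal position.
ENDMEMBER_BANDS <- list(
  protein_ch = cbind(
    center = c(2920, 2975, 2875), sigma = c(32, 26, 24),
    height = c(1, 0.42, 0.25)
  ),
  lipid_ch = cbind(
    center = c(2855, 2900, 2825), sigma = c(20, 26, 20),
    height = c(1, 0.25, 0.15)
  ),
  cell_ch_composite = cbind(
    center = c(2915, 2860, 2970), sigma = c(40, 28, 26),
    height = c(1, 0.22, 0.28)
  ),
  water_oh = cbind(center = 3400, sigma = 115, height = 1),
  caf2 = cbind(center = 320, sigma = 5, height = 1)
)

# Fingerprint-region (700-1700 cm^-1) band set: DNA/RNA backbone ring
# breathing 785, phenylalanine 1004, PO2-/C-O 1095, amide III 1260,
# CH deformation/adenine 1340, CH2 scissoring 1450, amide I 1660 cm^-1.
FINGERPRINT_CENTERS <- c(785, 1004, 1095, 1260, 1340, 1450, 1660)
FINGERPRINT_SIGMAS <- c(12, 8, 12, 15, 14, 14, 16)

# Organelle-specific band weights: nucleic-acid bands dominate in the
# nucleus and (more strongly) the nucleolus, protein bands in the
# cytoplasm, CH-deformation bands in lipid droplets. Declared fixtures,
# not estimates of any particular cell line.
FINGERPRINT_WEIGHTS <- list(
  fp_cytoplasm = c(0.30, 1.00, 0.30, 0.70, 0.45, 1.00, 0.90),
  fp_nucleus = c(1.00, 0.55, 0.90, 0.50, 0.70, 0.65, 0.60),
  fp_nucleolus = c(1.00, 0.20, 1.00, 0.25, 1.00, 0.30, 0.40),
  fp_droplet = c(0.10, 0.25, 0.15, 0.60, 0.35, 1.00, 0.75)
)

# unit-height Gaussian
gauss_peak <- function(x, mu, sigma) exp(-(x - mu)^2 / (2 * sigma^2))

eval_bands <- function(shifts, centers, sigmas, heights) {
  y <- numeric(length(shifts))
  for (j in seq_along(centers)) {
    y <- y + heights[j] * gauss_peak(shifts, centers[j], sigmas[j])
  }
  y
}

endmember_names <- function() {
  c(names(ENDMEMBER_BANDS), names(FINGERPRINT_WEIGHTS), "nv_emission")
}

#' Evaluate one phantom endmember spectrum
#'
#' Endmembers are non-negative and normalized to unit peak height (the
#' maximum over a dense grid of their support) before any region
#' weighting. `"nv_emission"` is the wavelength-domain NV model of
#' [nv_spectrum()] evaluated at the Stokes wavelength of each shift.
#'
#' @param name One of `"protein_ch"`, `"lipid_ch"`, `"cell_ch_composite"`,
#'   `"water_oh"`, `"caf2"`, `"fp_cytoplasm"`, `"fp_nucleus"`,
#'   `"fp_nucleolus"`, `"fp_droplet"`, `"nv_emission"`.
#' @param shifts Raman-shift grid (cm^-1).
#' @param excitation_nm Excitation wavelength, used only for
#'   `"nv_emission"`.
#' @return Numeric vector of unit-peak intensities on `shifts`.
#' @export
endmember <- function(name, shifts, excitation_nm = 532) {
  name <- match.arg(name, endmember_names())
  if (name == "nv_emission") {
    wl <- shift_to_wavelength(shifts, excitation_nm)
    y <- suppressWarnings(nv_spectrum(wl)$intensity)
    wl_ref <- seq(540, 980, by = 0.1)
    peak <- max(suppressWarnings(nv_spectrum(wl_ref)$intensity))
    return(y / peak)
  }
  if (name %in% names(FINGERPRINT_WEIGHTS)) {
    w <- FINGERPRINT_WEIGHTS[[name]]
    y <- eval_bands(shifts, FINGERPRINT_CENTERS, FINGERPRINT_SIGMAS, w)
    ref <- seq(700, 1700, by = 0.25)
    peak <- max(eval_bands(ref, FINGERPRINT_CENTERS, FINGERPRINT_SIGMAS, w))
    return(y / peak)
  }
  b <- ENDMEMBER_BANDS[[name]]
  y <- eval_bands(shifts, b[, "center"], b[, "sigma"], b[, "height"])
  ref <- seq(min(b[, "center"]) - 6 * max(b[, "sigma"]),
             max(b[, "center"]) + 6 * max(b[, "sigma"]), by = 0.25)
  peak <- max(eval_bands(ref, b[, "center"], b[, "sigma"], b[, "height"]))
  y / peak
}

#' Phantom component library on a shift axis
#'
#' Evaluates every endmember on the given axis and returns them as one
#' long tibble, convenient for inspection and plotting.
#'
#' @param axis A [spectral_axis()], or a numeric shift grid (cm^-1).
#' @param excitation_nm Excitation wavelength (used when `axis` is a bare
#'   grid).
#' @return A tibble with columns `component`, `shift`, `intensity`.
#' @export
component_library <- function(axis = spectral_axis(seq(100, 4000, by = 2)),
                              excitation_nm = 532) {
  if (inherits(axis, "spectral_axis")) {
    shifts <- axis$shifts
    excitation_nm <- axis$excitation_nm
  } else {
    shifts <- as.numeric(axis)
  }
  purrr::map_dfr(endmember_names(), function(nm) {
    tibble(
      component = nm, shift = shifts,
      intensity = endmember(nm, shifts, excitation_nm)
    )
  })
}
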