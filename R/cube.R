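#' Hyperspectral cube of per-pixel spectra
#'
#' The single-scan record everything else in the package consumes: an
#' `H x W x C` array of detector counts with a calibrated [spectral_axis()].
#' Pixel indexing is row-major with `(row 1, col 1)` at the top-left; all
#' modules share this convention.
#'
#' @param data Numeric `H x W x C` array of detector counts (finite).
#' @param axis [spectral_axis()] with `C` channels.
#' @param pixel_size_um Optional pixel pitch in micrometres.
#' @param metadata Free-form named list of acquisition metadata (grating
#'   centre in nm, integration time, ...).
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, axis, pixel_size_um = NULL, metadata = list()) {
  stopifnot(inherits(axis, "spectral_axis"))
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("`data` must be a 3-d array (H x W x C).")
  }
  if (dim(data)[3] != length(axis)) {
    abort(sprintf(
      "Channel count mismatch: data has %d channels, axis has %d.",
      dim(data)[3], length(axis)
    ))
  }
  if (!all(is.finite(data))) abort("`data` must be finite.")
  if (!is.null(pixel_size_um)) check_positive(pixel_size_um, "pixel_size_um")
  structure(
    list(
      data = data, axis = axis,
      pixel_size_um = pixel_size_um, metadata = metadata
    ),
    class = "hyper_cube"
  )
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d channels\n", d[1], d[2], d[3]))
  print(x$axis)
  if (!is.null(x$pixel_size_um)) {
    cat(sprintf("  pixel size: %g um\n", x$pixel_size_um))
  }
  invisible(x)
}

#' Extract one pixel spectrum as a tibble
#'
#' @param cube A [hyper_cube()].
#' @param row,col Pixel indices (1-based, row 1 at the top).
#' @return A tibble with columns `shift`, `wavelength`, `counts`.
#' @export
pixel_spectrum <- function(cube, row, col) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  if (row < 1 || row > d[1] || col < 1 || col > d[2]) {
    abort("Pixel indices out of range.")
  }
  tibble(
    shift = cube$axis$shifts,
    wavelength = axis_wavelengths(cube$axis),
    counts = as.numeric(cube$data[row, col, ])
  )
}

#' Flatten a cube to a long tibble
#'
#' One row per (pixel, channel); the format used by the CSV cube container.
#'
#' @param cube A [hyper_cube()].
#' @return A tibble with columns `row`, `col`, `shift`, `counts`.
#' @export
cube_to_tibble <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  tibble(
    row = rep(seq_len(d[1]), times = d[2] * d[3]),
    col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    shift = rep(cube$axis$shifts, each = d[1] * d[2]),
    counts = as.numeric(cube$data)
  )
}

#' Truncate a cube to a spectrograph detection window
#'
#' Retains the channels whose emission wavelength falls inside
#' `[center - span/2, center + span/2]`, emulating the choice of grating
#' central wavelength: a 610 nm centre keeps the fingerprint region, a
#' 680 nm centre trades it away for the NV phonon sideband.
#'
#' @param cube A [hyper_cube()].
#' @param center Grating central wavelength (nm).
#' @param span Captured spectral span (nm).
#' @return A [hyper_cube()] restricted to the window.
#' @export
crop_to_window <- function(cube, center, span) {
  stopifnot(inherits(cube, "hyper_cube"))
  check_positive(center, "center")
  check_positive(span, "span")
  wl <- axis_wavelengths(cube$axis)
  keep <- wl >= center - span / 2 & wl <= center + span / 2
  if (sum(keep) < 2) {
    abort("Detection window overlaps fewer than 2 channels of the axis.")
  }
  md <- cube$metadata
  md$grating_center_nm <- center
  md$grating_span_nm <- span
  hyper_cube(
    cube$data[, , keep, drop = FALSE],
    spectral_axis(cube$axis$shifts[keep], cube$axis$excitation_nm),
    pixel_size_um = cube$pixel_size_um,
    metadata = md
  )
}
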