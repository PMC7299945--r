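# Trapezoidal integral on a (possibly non-uniform) grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Indices of channels inside [lo, hi]; windows are clipped to channel
# boundaries (no sub-channel interpolation).
window_channels <- function(shifts, window) {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be c(lo, hi) with lo < hi.")
  }
  if (window[1] < min(shifts) || window[2] > max(shifts)) {
    abort(sprintf(
      "Band window [%g, %g] cm^-1 outside axis range [%g, %g] cm^-1.",
      window[1], window[2], min(shifts), max(shifts)
    ))
  }
  idx <- which(shifts >= window[1] & shifts <= window[2])
  if (length(idx) < 2) {
    abort("Fewer than 2 channels inside the band window (axis too coarse).")
  }
  idx
}

#' Integrated band intensity of a single spectrum
#'
#' Trapezoidal integral of the counts over a Raman-shift window. With
#' `baseline = "linear_endpoints"` the chord through the two window-edge
#' values is subtracted first, which removes any broadband pedestal (e.g.
#' NV photoluminescence) under the band; the result may then be negative.
#'
#' @param spectrum A data frame with numeric columns `shift` (cm^-1,
#'   strictly increasing) and `counts`, e.g. from [pixel_spectrum()].
#' @param window Numeric `c(lo, hi)` in cm^-1; must lie inside the axis
#'   range and contain at least 2 channels.
#' @param baseline `"none"` (plain integral) or `"linear_endpoints"`
#'   (chord subtraction).
#' @return Band area in counts * cm^-1.
#' @examples
#' sp <- tibble::tibble(shift = seq(2700, 3100, 2),
#'                      counts = exp(-(shift - 2920)^2 / (2 * 30^2)))
#' band_integral(sp, c(2800, 3030))
#' @export
band_integral <- function(spectrum, window,
                          baseline = c("none", "linear_endpoints")) {
  baseline <- match.arg(baseline)
  stopifnot(is.data.frame(spectrum), all(c("shift", "counts") %in% names(spectrum)))
  x <- spectrum$shift
  y <- spectrum$counts
  idx <- window_channels(x, window)
  xi <- x[idx]
  yi <- y[idx]
  if (baseline == "linear_endpoints") {
    n <- length(xi)
    yi <- yi - (yi[1] + (yi[n] - yi[1]) * (xi - xi[1]) / (xi[n] - xi[1]))
  }
  trapz(xi, yi)
}

#' Per-pixel band intensity map of a cube
#'
#' Applies [band_integral()] to every pixel spectrum, yielding an
#' `H x W` [intensity_map()].
#'
#' @param cube A [hyper_cube()].
#' @inheritParams band_integral
#' @return An [intensity_map()] in counts * cm^-1.
#' @export
band_map <- function(cube, window, baseline = c("none", "linear_endpoints")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(cube, "hyper_cube"))
  x <- cube$axis$shifts
  idx <- window_channels(x, window)
  xi <- x[idx]
  d <- dim(cube$data)
  # flatten pixels x channels for one vectorized pass
  m <- matrix(cube$data[, , idx, drop = FALSE], nrow = d[1] * d[2])
  if (baseline == "linear_endpoints") {
    n <- length(xi)
    w <- (xi - xi[1]) / (xi[n] - xi[1])
    chord <- outer(m[, 1], 1 - w) + outer(m[, n], w)
    m <- m - chord
  }
  # trapezoid weights on the shift grid
  dx <- diff(xi)
  wts <- c(dx / 2, 0) + c(0, dx / 2)
  vals <- as.numeric(m %*% wts)
  intensity_map(matrix(vals, d[1], d[2]), units = "counts.cm-1")
}

#' Scalar image derived from a hyperspectral cube
#'
#' A thin matrix wrapper tagging the physical units (band areas in
#' counts * cm^-1, or dimensionless after [normalize_map()]).
#'
#' @param values Numeric `H x W` matrix, finite.
#' @param units Units tag.
#' @return An object of class `intensity_map` (a matrix with attributes).
#' @export
intensity_map <- function(values, units = "counts.cm-1") {
  if (!is.matrix(values) || !all(is.finite(values))) {
    abort("`values` must be a finite numeric matrix.")
  }
  structure(values, class = c("intensity_map", class(matrix())), units = units)
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf(
    "<intensity_map> %d x %d [%s], range [%.4g, %.4g]\n",
    nrow(x), ncol(x), attr(x, "units"), min(x), max(x)
  ))
  invisible(x)
}

#' @rdname intensity_map
#' @param x An `intensity_map`.
#' @param ... Unused.
#' @export
as_tibble.intensity_map <- function(x, ...) {
  tibble(
    row = rep(seq_len(nrow(x)), times = ncol(x)),
    col = rep(seq_len(ncol(x)), each = nrow(x)),
    value = as.numeric(x)
  )
}

#' Percentile-clipped display normalization of an intensity map
#'
#' Clips to the `[clip_lo_pct, clip_hi_pct]` percentiles and affinely maps
#' the result to `[0, 1]`, which keeps isolated hot fND pixels from
#' compressing the dynamic range of the cell image. A constant map has no
#' dynamic range and maps to 0.5 everywhere (with a warning).
#'
#' @param map An [intensity_map()].
#' @param clip_lo_pct,clip_hi_pct Percentiles in `[0, 100]`,
#'   `clip_lo_pct < clip_hi_pct`. Defaults 1 and 99.
#' @return A normalized [intensity_map()] with values in `[0, 1]`.
#' @export
normalize_map <- function(map, clip_lo_pct = 1, clip_hi_pct = 99) {
  stopifnot(inherits(map, "intensity_map"))
  if (clip_lo_pct < 0 || clip_hi_pct > 100 || clip_lo_pct >= clip_hi_pct) {
    abort("Need 0 <= clip_lo_pct < clip_hi_pct <= 100.")
  }
  v <- as.numeric(map)
  p <- quantile(v, c(clip_lo_pct, clip_hi_pct) / 100, names = FALSE)
  if (p[1] == p[2]) {
    if (min(v) == max(v)) {
      warn("Constant intensity map: normalizing to 0.5 everywhere.")
      out <- matrix(0.5, nrow(map), ncol(map))
      return(intensity_map(out, units = "normalized"))
    }
    # degenerate percentiles on a non-constant map: fall back to full range
    p <- range(v)
  }
  out <- pmin(pmax(v, p[1]), p[2])
  out <- (out - p[1]) / (p[2] - p[1])
  intensity_map(matrix(out, nrow(map), ncol(map)), units = "normalized")
}

#' @export
autoplot.intensity_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(
      low = "black", high = "red",
      name = attr(object, "units")
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
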