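#' Compose the C-H cell layer with the fND cluster overlay
#'
#' The two-layer image of the method: the cell intensity map rendered
#' through a black-to-red ramp, with the luminescent cluster pixels
#' painted over it in the fixed class colors. An overlay filter can
#' restrict the painted classes (e.g. intracellular-only, the yellow and
#' white pixels).
#'
#' @param base An [intensity_map()] (negative, positive or full C-H
#'   image); display-normalized internally unless already normalized.
#' @param labels A [label_map()] over the five-class scheme with matching
#'   shape.
#' @param overlay Character vector of classes to paint (default all four
#'   luminescent classes). `NONLUM` is never painted: it shows the base.
#' @param clip_lo_pct,clip_hi_pct Percentile clip for the base layer.
#' @return An `H x W x 3` RGB array in `[0, 1]`.
#' @export
render_overlay <- function(base, labels,
                           overlay = c("EXTRA_LOW", "EXTRA_HIGH",
                                       "INTRA_LOW", "INTRA_HIGH"),
                           clip_lo_pct = 1, clip_hi_pct = 99) {
  stopifnot(inherits(base, "intensity_map"), inherits(labels, "label_map"))
  if (!all(dim(base) == dim(labels))) {
    abort("`base` and `labels` must have the same shape.")
  }
  overlay <- match.arg(overlay, FND_LEVELS[-1], several.ok = TRUE)
  if (!identical(attr(base, "units"), "normalized")) {
    base <- normalize_map(base, clip_lo_pct, clip_hi_pct)
  }
  img <- array(0, dim = c(nrow(base), ncol(base), 3))
  img[, , 1] <- unclass(base) # black -> red ramp
  pal <- grDevices::col2rgb(cluster_palette()) / 255
  lv <- attr(labels, "levels")
  for (cls in overlay) {
    sel <- matrix(lv[as.integer(labels)] == cls, nrow(base), ncol(base))
    if (!any(sel)) next
    col <- pal[, cls]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- col[ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' @export
autoplot.fnd_classification <- function(object, base = NULL, ...) {
  base <- base %||% object$ch_map
  img <- render_overlay(base, object$labels, ...)
  df <- as_tibble(object$labels)
  df$fill <- grDevices::rgb(
    as.numeric(img[, , 1]), as.numeric(img[, , 2]), as.numeric(img[, , 3])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot the mean spectra of the classes of a classification
#'
#' @param spectra Output of [cluster_mean_spectra()].
#' @return A ggplot.
#' @export
plot_cluster_spectra <- function(spectra) {
  stopifnot(is.data.frame(spectra))
  pal <- cluster_palette()
  pal["INTRA_HIGH"] <- "#000000" # white is unreadable on spectra plots
  ggplot2::ggplot(
    spectra,
    ggplot2::aes(.data$shift, .data$counts, color = .data$label)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = pal) +
    ggplot2::labs(
      x = expression("Raman shift (cm"^-1 * ")"),
      y = "mean counts", color = "cluster"
    ) +
    ggplot2::theme_minimal()
}
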