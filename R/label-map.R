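#' Categorical image over a label scheme
#'
#' @param values Integer `H x W` matrix of level indices (1-based).
#' @param levels Character vector of level names.
#' @return An object of class `label_map`.
#' @export
label_map <- function(values, levels) {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  values <- matrix(as.integer(values), nrow(values), ncol(values))
  if (any(values < 1L) || any(values > length(levels))) {
    abort("Label indices out of range of `levels`.")
  }
  structure(values, class = c("label_map", class(matrix())), levels = levels)
}

#' @export
print.label_map <- function(x, ...) {
  lv <- attr(x, "levels")
  counts <- tabulate(x, nbins = length(lv))
  cat(sprintf("<label_map> %d x %d\n", nrow(x), ncol(x)))
  for (i in seq_along(lv)) {
    cat(sprintf("  %-12s %6d px\n", lv[i], counts[i]))
  }
  invisible(x)
}

#' @rdname label_map
#' @param x A `label_map`.
#' @param ... Unused.
#' @export
as_tibble.label_map <- function(x, ...) {
  lv <- attr(x, "levels")
  tibble(
    row = rep(seq_len(nrow(x)), times = ncol(x)),
    col = rep(seq_len(ncol(x)), each = nrow(x)),
    label = factor(lv[as.integer(x)], levels = lv)
  )
}

#' Pixel counts per label
#'
#' @param labels A [label_map()].
#' @return A tibble with columns `label` and `n_pixels`.
#' @export
label_counts <- function(labels) {
  lv <- attr(labels, "levels")
  tibble(label = lv, n_pixels = tabulate(labels, nbins = length(lv)))
}

#' @export
autoplot.label_map <- function(object, ...) {
  df <- as_tibble(object)
  lv <- attr(object, "levels")
  pal <- if (all(lv %in% names(cluster_palette()))) {
    cluster_palette()[lv]
  } else {
    stats::setNames(grDevices::hcl.colors(length(lv), "Dark 3"), lv)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
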