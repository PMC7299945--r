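# Long-format CSV cube container: comment header lines carry the scalar
# metadata, then one row per (pixel, channel). Numeric columns are
# written with 17 significant digits so the round trip is lossless
# within double precision.
#
#   # ramanfnd-cube v1
#   # excitation_nm: 532
#   # pixel_size_um: 0.5          (optional)
#   # meta <name>: <value>        (numeric/character scalar metadata)
#   row,col,shift,counts

#' Write a hyperspectral cube to a long-format CSV file
#'
#' @param cube A [hyper_cube()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  header <- c(
    "# ramanfnd-cube v1",
    sprintf("# excitation_nm: %.17g", cube$axis$excitation_nm)
  )
  if (!is.null(cube$pixel_size_um)) {
    header <- c(header, sprintf("# pixel_size_um: %.17g", cube$pixel_size_um))
  }
  for (nm in names(cube$metadata)) {
    val <- cube$metadata[[nm]]
    if (length(val) == 1 && (is.numeric(val) || is.character(val))) {
      header <- c(header, sprintf(
        "# meta %s: %s", nm,
        if (is.numeric(val)) sprintf("%.17g", val) else as.character(val)
      ))
    }
  }
  df <- cube_to_tibble(cube)
  df$shift <- sprintf("%.17g", df$shift)
  df$counts <- sprintf("%.17g", df$counts)
  writeLines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

parse_cube_header <- function(path) {
  out <- list(metadata = list())
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    m <- regmatches(line, regexec("^# (meta )?([^:]+): (.*)$", line))[[1]]
    if (length(m) == 4) {
      key <- trimws(m[3])
      val <- trimws(m[4])
      num <- suppressWarnings(as.numeric(val))
      val <- if (is.na(num)) val else num
      if (nzchar(m[2])) out$metadata[[key]] <- val else out[[key]] <- val
    }
  }
  out
}

#' Read a hyperspectral cube from a long-format CSV file
#'
#' @param path Path to a file produced by [write_cube()] (or following
#'   the same layout).
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  hdr <- parse_cube_header(path)
  if (is.null(hdr$excitation_nm)) {
    abort("Cube format error: missing `excitation_nm` header field.")
  }
  df <- tryCatch(
    suppressWarnings(readr::read_csv(
      path, comment = "#", show_col_types = FALSE,
      # shift/counts come in as text and go through strtod (as.numeric),
      # which is correctly rounded; readr's own float parser can be off
      # by one ulp and would break bitwise round trips
      col_types = readr::cols(
        row = readr::col_integer(), col = readr::col_integer(),
        shift = readr::col_character(), counts = readr::col_character()
      )
    )),
    error = function(e) abort(sprintf("Cube format error: %s", conditionMessage(e)))
  )
  need <- c("row", "col", "shift", "counts")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Cube format error: missing column(s) %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  df$shift <- suppressWarnings(as.numeric(df$shift))
  df$counts <- suppressWarnings(as.numeric(df$counts))
  if (nrow(df) == 0 || anyNA(df[need])) {
    abort("Cube format error: empty table or non-numeric values.")
  }
  shifts <- sort(unique(df$shift))
  h <- max(df$row)
  w <- max(df$col)
  if (length(shifts) < 2) {
    abort("Cube format error: needs at least 2 spectral channels.")
  }
  if (nrow(df) != h * w * length(shifts)) {
    abort("Cube format error: table is not a complete (row, col, shift) grid.")
  }
  df <- dplyr::arrange(df, .data$shift, .data$col, .data$row)
  data <- array(df$counts, dim = c(h, w, length(shifts)))
  hyper_cube(
    data, spectral_axis(shifts, hdr$excitation_nm),
    pixel_size_um = hdr$pixel_size_um,
    metadata = hdr$metadata
  )
}

#' Export an intensity map as a 32-bit TIFF with a calibration sidecar
#'
#' TIFF sample values are stored affinely rescaled to `[0, 1]` at 32-bit
#' depth; the offset, scale and units needed to recover absolute band
#' areas (`value = offset + scale * sample`) are written to a JSON
#' sidecar at `<path>.json`. Full-precision absolute values are also
#' available through the CSV cube container.
#'
#' @param map An [intensity_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "intensity_map"))
  lo <- min(map)
  hi <- max(map)
  scale <- hi - lo
  stored <- if (scale > 0) (unclass(map) - lo) / scale else
    matrix(0, nrow(map), ncol(map))
  suppressWarnings(tiff::writeTIFF(stored, path, bits.per.sample = 32L))
  jsonlite::write_json(
    list(offset = lo, scale = scale, units = attr(map, "units")),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Export an intensity map as an 8-bit grayscale PNG
#'
#' The map is display-normalized with [normalize_map()] first unless it
#' is already tagged `normalized`.
#'
#' @param map An [intensity_map()].
#' @param path Output path.
#' @param ... Passed to [normalize_map()].
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path, ...) {
  stopifnot(inherits(map, "intensity_map"))
  if (!identical(attr(map, "units"), "normalized")) {
    map <- normalize_map(map, ...)
  }
  png::writePNG(unclass(map), path)
  invisible(path)
}

#' Export a label map as a colored PNG plus a CSV legend
#'
#' @param labels A [label_map()].
#' @param path_png Output PNG path.
#' @param path_csv Output CSV legend path (label, color, pixel count).
#' @param palette Named colors per level; defaults to [cluster_palette()]
#'   when the levels match the five-class scheme.
#' @return `path_png`, invisibly.
#' @export
write_label_map <- function(labels, path_png, path_csv, palette = NULL) {
  stopifnot(inherits(labels, "label_map"))
  lv <- attr(labels, "levels")
  if (is.null(palette)) {
    palette <- if (all(lv %in% names(cluster_palette()))) {
      cluster_palette()[lv]
    } else {
      stats::setNames(grDevices::hcl.colors(length(lv), "Dark 3"), lv)
    }
  }
  rgb <- grDevices::col2rgb(palette[as.integer(labels)]) / 255
  img <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  for (ch in 1:3) {
    img[, , ch] <- matrix(rgb[ch, ], nrow(labels), ncol(labels))
  }
  png::writePNG(img, path_png)
  readr::write_csv(
    dplyr::mutate(label_counts(labels), color = unname(palette[.data$label])),
    path_csv
  )
  invisible(path_png)
}

#' Write a classification (or any) report as JSON
#'
#' @param report A named list, e.g. the `report` of [classify_fnd()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
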