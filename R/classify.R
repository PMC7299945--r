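# The five-class scheme of the hierarchical classification and its fixed
# rendering colors: non-luminescent pixels carry the red cell layer;
# extracellular fNDs are dark blue (low) / light blue (high); internalized
# fNDs are yellow (low) / white (high; black in spectra plots).
FND_LEVELS <- c("NONLUM", "EXTRA_LOW", "EXTRA_HIGH", "INTRA_LOW", "INTRA_HIGH")

#' Fixed colors of the five-cluster scheme
#'
#' @return Named character vector of hex colors over the five labels.
#' @export
cluster_palette <- function() {
  c(
    NONLUM = "#FF0000",
    EXTRA_LOW = "#00008B",
    EXTRA_HIGH = "#ADD8E6",
    INTRA_LOW = "#FFFF00",
    INTRA_HIGH = "#FFFFFF"
  )
}

#' Configuration of the hierarchical fND classifier
#'
#' @param pl_window Raman-silent window (cm^-1) for the broadband NV
#'   photoluminescence feature. The default 1800-2700 cm^-1 carries no
#'   cell Raman bands, so broadband NV emission dominates it.
#' @param ch_window C-H band window (cm^-1) for the chemical
#'   (intracellular vs extracellular) score. The default 2800-2980 cm^-1
#'   deliberately stops short of the full C-H range: under 532 nm
#'   excitation the NV- zero-phonon line at 636 nm falls at
#'   ~3076 cm^-1 on the Raman-shift axis, and a window edge within its
#'   tail would corrupt the chord baseline of bright fND pixels.
#' @param threshold_mode `"two_means"` (exact 1-d two-cluster k-means at
#'   every stage) or `"fixed"` (user-supplied thresholds).
#' @param fixed_thresholds Named list with elements `pl`, `ch`, `grade`
#'   (required for `threshold_mode = "fixed"`).
#' @param min_separation Minimum separation between the two cluster means
#'   of the luminescence split, in multiples of the robust noise level of
#'   the feature map, below which no pixel is called luminescent. The
#'   default 5 guards against false-positive fND detection on fND-free
#'   scans.
#' @param seed Integer seed recorded in the report (the exact 1-d
#'   algorithm itself uses no randomness).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(pl_window = c(1800, 2700),
                              ch_window = c(2800, 2980),
                              threshold_mode = c("two_means", "fixed"),
                              fixed_thresholds = NULL,
                              min_separation = 5,
                              seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  if (min_separation < 0) abort("`min_separation` must be >= 0.")
  if (threshold_mode == "fixed" &&
      !all(c("pl", "ch", "grade") %in% names(fixed_thresholds))) {
    abort("Fixed mode needs `fixed_thresholds` with elements pl, ch, grade.")
  }
  structure(
    list(
      pl_window = pl_window, ch_window = ch_window,
      threshold_mode = threshold_mode, fixed_thresholds = fixed_thresholds,
      min_separation = min_separation, seed = as.integer(seed)
    ),
    class = "classifier_config"
  )
}

#' Broadband NV photoluminescence feature map
#'
#' Per-pixel band area over the Raman-silent window (baseline `"none"`),
#' minus the per-cube dark offset estimated as the median of the 5%
#' dimmest pixels in that window. Broadband NV sideband emission
#' dominates this region; cell Raman bands do not reach into it.
#'
#' @param cube A [hyper_cube()] covering the PL window.
#' @param config A [classifier_config()].
#' @return An [intensity_map()].
#' @export
pl_feature <- function(cube, config = classifier_config()) {
  m <- band_map(cube, config$pl_window, baseline = "none")
  v <- as.numeric(m)
  dark <- median(v[v <= quantile(v, 0.05)])
  intensity_map(
    matrix(v - dark, nrow(m), ncol(m)),
    units = attr(m, "units")
  )
}

#' Robust per-pixel spectral noise estimate
#'
#' Estimates the per-channel noise of each pixel spectrum from the median
#' absolute successive difference along the spectral axis (scaled for
#' Gaussian consistency), which is insensitive to the smooth spectral
#' content itself.
#'
#' @param cube A [hyper_cube()].
#' @return An [intensity_map()] of per-pixel noise sigma (counts).
#' @export
pixel_noise <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  m <- matrix(cube$data, nrow = d[1] * d[2])
  dd <- abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])
  v <- apply(dd, 1, median) * 1.4826 / sqrt(2)
  intensity_map(matrix(v, d[1], d[2]), units = "counts")
}

#' Detect NV-luminescent pixels on a PL feature map
#'
#' Splits the PL feature values in two by exact two-means. The split is
#' computed on a noise-scaled, log-compressed copy of the values
#' (`log1p(pmax(x, 0) / sigma)`), which keeps a handful of very bright
#' aggregate pixels from absorbing the whole split so that dim single-fND
#' pixels are still separated from the background; the compression is
#' monotone, so it changes only where the boundary falls, never the
#' ordering. Pixels above the boundary are called luminescent only if the
#' raw between-group mean separation reaches `min_separation` times the
#' robust noise level of the map; otherwise an empty mask is returned
#' (false-positive guard on fND-free scans).
#'
#' @param pl_map An [intensity_map()] from [pl_feature()].
#' @param config A [classifier_config()].
#' @param noise_sd Optional noise level of the feature (counts * cm^-1);
#'   estimated as `mad(pl_map)` when `NULL`.
#' @return List with `mask` (logical matrix), `threshold` (raw feature
#'   units; `NA` if nothing detected), `separation`, `noise_sd`.
#' @export
detect_luminescent <- function(pl_map, config = classifier_config(),
                               noise_sd = NULL) {
  stopifnot(inherits(pl_map, "intensity_map"))
  v <- as.numeric(pl_map)
  sigma <- noise_sd %||% mad(v)
  if (config$threshold_mode == "fixed") {
    thr <- config$fixed_thresholds$pl
    mask <- matrix(v > thr, nrow(pl_map), ncol(pl_map))
    return(list(
      mask = mask, threshold = thr,
      separation = NA_real_, noise_sd = sigma
    ))
  }
  # compression knee at the false-positive guard level: values below
  # min_separation x noise are squashed toward 0, so the noise body stays
  # tight in the transformed space and the split lands between background
  # and genuine emitters rather than inside the noise distribution
  scale <- max(max(config$min_separation, 1) * sigma, .Machine$double.eps)
  u <- log1p(pmax(v, 0) / scale)
  tm <- two_means_1d(u)
  empty <- list(
    mask = matrix(FALSE, nrow(pl_map), ncol(pl_map)),
    threshold = NA_real_, separation = 0, noise_sd = sigma
  )
  if (tm$degenerate) {
    inform("PL split degenerate (constant feature): no luminescent pixels.")
    return(empty)
  }
  hi <- tm$labels == 1L
  separation <- abs(mean(v[hi]) - mean(v[!hi]))
  if (separation < config$min_separation * sigma) {
    inform(sprintf(
      "PL cluster separation %.3g below %g x noise (%.3g): no luminescent pixels.",
      separation, config$min_separation, sigma
    ))
    empty$separation <- separation
    return(empty)
  }
  list(
    mask = matrix(hi, nrow(pl_map), ncol(pl_map)),
    threshold = scale * expm1(tm$threshold),
    separation = separation,
    noise_sd = sigma
  )
}

# Reference C-H levels from the non-luminescent pixels: a two-means
# split separates the substrate-like and cell-like populations; the
# decision boundary for chemical localization is the midpoint between
# the substrate level and the cell population's lower quartile, and the
# noise is the substrate cluster's spread.
nonlum_ch_reference <- function(ch_nonlum) {
  tm <- two_means_1d(ch_nonlum)
  if (tm$degenerate) {
    med <- median(ch_nonlum)
    return(list(
      substrate = med, cell_q1 = med, boundary = med,
      noise = mad(ch_nonlum)
    ))
  }
  lo <- ch_nonlum[tm$labels == 0L]
  hi <- ch_nonlum[tm$labels == 1L]
  substrate <- mean(lo)
  cell_q1 <- quantile(hi, 0.25, names = FALSE)
  list(
    substrate = substrate, cell_q1 = cell_q1,
    boundary = (substrate + cell_q1) / 2,
    noise = mad(lo)
  )
}

#' Split luminescent pixels by C-H presence (intracellular vs not)
#'
#' Two-means on the C-H band score restricted to the luminescent pixels
#' groups them chemically; each of the two groups is then called
#' intracellular when its mean C-H level reaches the reference boundary
#' derived from the non-luminescent population (midpoint between the
#' substrate level and the cell population's lower quartile). The
#' reference comparison, rather than "high group = inside"
#' unconditionally, keeps chemically homogeneous groups intact: when all
#' emitters sit on the substrate (or all in the cell), the within-group
#' split only reflects NV brightness leakage, and both groups land on
#' the same side of the boundary. If the within-group separation is
#' below `min_separation` times the substrate-level C-H noise, pixels
#' are assigned against the boundary individually (fallback rule).
#'
#' @param mask Logical matrix of luminescent pixels (non-empty).
#' @param ch_map [intensity_map()] of chord-baselined C-H band areas.
#' @param config A [classifier_config()].
#' @return List of logical matrices `inside` and `outside`, plus
#'   `separation` and `fallback` (was the quartile rule used?).
#' @export
split_by_ch <- function(mask, ch_map, config = classifier_config()) {
  stopifnot(is.logical(mask), all(dim(mask) == dim(ch_map)))
  if (!any(mask)) abort("`mask` must contain at least one luminescent pixel.")
  v <- as.numeric(ch_map)
  sel <- as.vector(mask)
  ref <- nonlum_ch_reference(v[!sel])
  vals <- v[sel]
  if (config$threshold_mode == "fixed") {
    inside_sel <- vals > config$fixed_thresholds$ch
    fallback <- FALSE
    separation <- NA_real_
  } else if (length(vals) >= 2) {
    # same compression idea as the luminescence split: the knee sits at
    # min_separation x the substrate-level C-H noise, so the grouping
    # reflects the substrate/cell contrast instead of brightness leakage
    # within the intracellular scores; asinh keeps the sign of
    # chord-baselined values
    scale <- max(max(config$min_separation, 1) * ref$noise, .Machine$double.eps)
    tm <- two_means_1d(asinh(vals / scale))
    separation <- abs(mean(vals[tm$labels == 1L]) - mean(vals[tm$labels == 0L]))
    if (tm$degenerate) separation <- 0
    margin <- config$min_separation * ref$noise
    if (!tm$degenerate && separation >= margin) {
      group_means <- c(mean(vals[tm$labels == 0L]), mean(vals[tm$labels == 1L]))
      inside_sel <- (group_means >= ref$boundary)[tm$labels + 1L]
      fallback <- FALSE
    } else {
      inform("C-H split not separated: assigning pixels against the cell reference level.")
      inside_sel <- vals >= ref$boundary
      fallback <- TRUE
    }
  } else {
    inform("Single luminescent pixel: assigning against the cell reference level.")
    inside_sel <- vals >= ref$boundary
    fallback <- TRUE
    separation <- 0
  }
  inside <- outside <- matrix(FALSE, nrow(mask), ncol(mask))
  inside[mask] <- inside_sel
  outside[mask] <- !inside_sel
  list(
    inside = inside, outside = outside,
    separation = separation, fallback = fallback
  )
}

#' Split a luminescent group into low and high brightness grades
#'
#' Two-means on the PL feature within the group. A degenerate or weakly
#' separated split (below `min_separation` times the map noise), or a
#' single-pixel group, labels the whole group low.
#'
#' @param group_mask Logical matrix selecting one chemical group
#'   (non-empty).
#' @param pl_map [intensity_map()] PL feature.
#' @param config A [classifier_config()].
#' @param noise_sd Optional feature noise level; `mad(pl_map)` if `NULL`.
#' @return List of logical matrices `low` and `high`, plus `threshold`
#'   and `separation`.
#' @export
split_by_intensity <- function(group_mask, pl_map,
                               config = classifier_config(),
                               noise_sd = NULL) {
  stopifnot(is.logical(group_mask), all(dim(group_mask) == dim(pl_map)))
  if (!any(group_mask)) abort("`group_mask` must be non-empty.")
  v <- as.numeric(pl_map)
  sigma <- noise_sd %||% mad(v)
  vals <- v[group_mask]
  low <- high <- matrix(FALSE, nrow(pl_map), ncol(pl_map))
  if (config$threshold_mode == "fixed") {
    hi_sel <- vals > config$fixed_thresholds$grade
    low[group_mask] <- !hi_sel
    high[group_mask] <- hi_sel
    return(list(
      low = low, high = high,
      threshold = config$fixed_thresholds$grade, separation = NA_real_
    ))
  }
  if (length(vals) < 2) {
    low[group_mask] <- TRUE
    return(list(low = low, high = high, threshold = NA_real_, separation = 0))
  }
  tm <- two_means_1d(vals)
  if (tm$degenerate || tm$separation < config$min_separation * sigma) {
    low[group_mask] <- TRUE
    return(list(
      low = low, high = high,
      threshold = NA_real_, separation = tm$separation
    ))
  }
  hi_sel <- tm$labels == 1L
  low[group_mask] <- !hi_sel
  high[group_mask] <- hi_sel
  list(
    low = low, high = high,
    threshold = tm$threshold, separation = tm$separation
  )
}

#' Hierarchical five-class fND classification of a PL/Raman cube
#'
#' Composes the full single-scan pipeline in the fixed hierarchical
#' order: broadband NV luminescence detection ([pl_feature()] +
#' [detect_luminescent()]), chemical localization by C-H presence
#' ([split_by_ch()]), and brightness grading ([split_by_intensity()]
#' within each chemical group). Every pixel receives exactly one of the
#' five labels `NONLUM`, `EXTRA_LOW`, `EXTRA_HIGH`, `INTRA_LOW`,
#' `INTRA_HIGH`.
#'
#' @param cube A [hyper_cube()] covering both the PL and C-H windows.
#' @param config A [classifier_config()].
#' @return An object of class `fnd_classification`: list with `labels`
#'   (a [label_map()]), `report` (thresholds, separations, noise level,
#'   per-class pixel counts), `pl_map`, `ch_map`, `config`.
#' @examples
#' ph <- make_phantom(phantom_config(seed = 1))
#' cl <- classify_fnd(ph$cube, classifier_config(pl_window = c(1800, 2700)))
#' glance(cl)
#' @export
classify_fnd <- function(cube, config = classifier_config()) {
  stopifnot(inherits(cube, "hyper_cube"))
  pl <- pl_feature(cube, config)
  ch <- band_map(cube, config$ch_window, baseline = "linear_endpoints")
  det <- detect_luminescent(pl, config)

  lab <- matrix(1L, nrow(pl), ncol(pl)) # NONLUM
  report <- list(
    seed = config$seed,
    noise_sd = det$noise_sd,
    pl_threshold = det$threshold,
    pl_separation = det$separation,
    ch_separation = NA_real_,
    ch_fallback = FALSE,
    grade_threshold_inside = NA_real_,
    grade_threshold_outside = NA_real_
  )
  if (any(det$mask)) {
    sp <- split_by_ch(det$mask, ch, config)
    report$ch_separation <- sp$separation
    report$ch_fallback <- sp$fallback
    if (any(sp$outside)) {
      g <- split_by_intensity(sp$outside, pl, config, noise_sd = det$noise_sd)
      lab[g$low] <- 2L
      lab[g$high] <- 3L
      report$grade_threshold_outside <- g$threshold
    }
    if (any(sp$inside)) {
      g <- split_by_intensity(sp$inside, pl, config, noise_sd = det$noise_sd)
      lab[g$low] <- 4L
      lab[g$high] <- 5L
      report$grade_threshold_inside <- g$threshold
    }
  }
  labels <- label_map(lab, FND_LEVELS)
  report$class_counts <- stats::setNames(
    as.list(tabulate(lab, 5L)), FND_LEVELS
  )
  structure(
    list(
      labels = labels, report = report,
      pl_map = pl, ch_map = ch, config = config
    ),
    class = "fnd_classification"
  )
}

#' @export
print.fnd_classification <- function(x, ...) {
  cat("<fnd_classification>\n")
  print(x$labels)
  cat(sprintf(
    "  PL threshold %.4g (separation %.4g, noise %.4g)\n",
    x$report$pl_threshold %||% NA, x$report$pl_separation, x$report$noise_sd
  ))
  invisible(x)
}

#' @rdname classify_fnd
#' @param x An `fnd_classification`.
#' @param ... Unused.
#' @export
tidy.fnd_classification <- function(x, ...) {
  cnt <- label_counts(x$labels)
  pl <- as.numeric(x$pl_map)
  lab <- as.integer(x$labels)
  cnt$color <- unname(cluster_palette()[cnt$label])
  cnt$mean_pl <- vapply(
    seq_along(FND_LEVELS),
    function(i) if (any(lab == i)) mean(pl[lab == i]) else NA_real_,
    numeric(1)
  )
  cnt[, c("label", "color", "n_pixels", "mean_pl")]
}

#' @rdname classify_fnd
#' @export
glance.fnd_classification <- function(x, ...) {
  r <- x$report
  tibble(
    n_classes = sum(tabulate(as.integer(x$labels), 5L) > 0),
    n_luminescent = sum(as.integer(x$labels) != 1L),
    pl_threshold = r$pl_threshold %||% NA_real_,
    pl_separation = r$pl_separation,
    noise_sd = r$noise_sd,
    ch_fallback = r$ch_fallback
  )
}

#' Mean spectrum of each class present in a label map
#'
#' Channelwise mean of the pixel spectra per label; labels with no pixels
#' are omitted. Intracellular classes show the C-H stretching band in
#' their mean spectrum; extracellular classes do not.
#'
#' @param cube A [hyper_cube()].
#' @param labels A [label_map()] with the same spatial shape.
#' @return A tibble with columns `label`, `n_pixels`, `shift`,
#'   `wavelength`, `counts`.
#' @export
cluster_mean_spectra <- function(cube, labels) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(labels, "label_map"))
  d <- dim(cube$data)
  if (!all(dim(labels) == d[1:2])) abort("`labels` shape must match the cube.")
  lv <- attr(labels, "levels")
  m <- matrix(cube$data, nrow = d[1] * d[2])
  lab <- as.integer(labels)
  wl <- axis_wavelengths(cube$axis)
  purrr::map_dfr(seq_along(lv), function(i) {
    sel <- lab == i
    if (!any(sel)) return(NULL)
    tibble(
      label = lv[i], n_pixels = sum(sel),
      shift = cube$axis$shifts, wavelength = wl,
      counts = colMeans(m[sel, , drop = FALSE])
    )
  })
}
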