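# Fingerprint-region preprocessing: restrict to the window, subtract the
# chord through the window endpoints, then scale each pixel spectrum to
# unit band area. Pixels whose band area falls below a small floor
# (signal-free substrate pixels, where the area is pure noise around
# zero) are scaled by the floor instead, so that noise is not inflated
# into unit-area pseudo-spectra.
fingerprint_features <- function(cube, window) {
  x <- cube$axis$shifts
  idx <- window_channels(x, window)
  xi <- x[idx]
  d <- dim(cube$data)
  m <- matrix(cube$data[, , idx, drop = FALSE], nrow = d[1] * d[2])
  n <- length(xi)
  # chord endpoints averaged over a few channels: a single noisy edge
  # channel would tilt the whole chord and dominate the band area
  ne <- min(3L, n %/% 2)
  y_lo <- rowMeans(m[, seq_len(ne), drop = FALSE])
  y_hi <- rowMeans(m[, n - seq_len(ne) + 1, drop = FALSE])
  w <- (xi - xi[1]) / (xi[n] - xi[1])
  m <- m - (outer(y_lo, 1 - w) + outer(y_hi, w))
  dx <- diff(xi)
  wts <- c(dx / 2, 0) + c(0, dx / 2)
  area <- as.numeric(m %*% wts)
  # floor anchored near the top of the area distribution so that it sits
  # at the scale of genuine cell signal even when most pixels are bare
  # substrate (whose noise-level areas must not be inflated to unit area)
  floor_area <- max(0.25 * quantile(area, 0.9, names = FALSE), .Machine$double.eps)
  m <- m / pmax(area, floor_area)
  list(features = m, shifts = xi, area = area, floor = floor_area)
}

# k-means++ style seeding: first centre uniform, subsequent centres drawn
# with probability proportional to squared distance to the nearest
# chosen centre.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    centers[j] <- sample.int(n, 1, prob = p)
    d2j <- rowSums((X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, d2j)
  }
  X[centers, , drop = FALSE]
}

#' Classical KMCA organelle segmentation of the fingerprint region
#'
#' The comparison method: per-pixel spectra restricted to the
#' 700-1700 cm^-1 fingerprint region, chord-baselined, area-normalized,
#' then clustered by k-means (k-means++ seeding under the given seed,
#' Lloyd iterations, at most 300). Cluster ids are renumbered by
#' descending cluster size, so on a typical single-cell scan label 1 is
#' the substrate.
#'
#' @param cube A [hyper_cube()] whose axis covers the fingerprint region
#'   (i.e. recorded with the grating centred near 610 nm).
#' @param k Number of clusters (>= 1); default 4 (substrate, cytoplasm,
#'   nucleus, nucleolus).
#' @param seed Integer seed for the k-means++ seeding.
#' @param window Fingerprint window (cm^-1).
#' @return An object of class `kmca_segmentation`: `labels` (a
#'   [label_map()] with levels `"1"..."k"`), `centroids` (k x C matrix of
#'   mean preprocessed spectra), `shifts`, `sizes`, `k`, `tot_withinss`.
#' @export
kmca_segment <- function(cube, k = 4, seed = 1L, window = c(700, 1700)) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  if (k < 1) abort("`k` must be >= 1.")
  if (k > d[1] * d[2]) abort("`k` exceeds the number of pixels.")
  fp <- fingerprint_features(cube, window)
  X <- fp$features

  if (k == 1) {
    centroid <- matrix(colMeans(X), 1)
    labels <- label_map(matrix(1L, d[1], d[2]), "1")
    return(structure(
      list(
        labels = labels, centroids = centroid, shifts = fp$shifts,
        sizes = d[1] * d[2], k = 1L,
        tot_withinss = sum(sweep(X, 2, centroid[1, ])^2)
      ),
      class = "kmca_segmentation"
    ))
  }

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  init <- kmeanspp_centers(X, k)
  km <- tryCatch(
    kmeans(X, centers = init, iter.max = 300, algorithm = "Lloyd"),
    error = function(e) kmeans(X, centers = k, iter.max = 300, nstart = 5),
    warning = function(w) {
      suppressWarnings(
        kmeans(X, centers = init, iter.max = 300, algorithm = "Lloyd")
      )
    }
  )

  ord <- order(km$size, decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  lab <- matrix(relabel[km$cluster], d[1], d[2])
  structure(
    list(
      labels = label_map(lab, as.character(seq_len(k))),
      centroids = km$centers[ord, , drop = FALSE],
      shifts = fp$shifts,
      sizes = km$size[ord],
      k = as.integer(k),
      tot_withinss = km$tot.withinss
    ),
    class = "kmca_segmentation"
  )
}

#' @export
print.kmca_segmentation <- function(x, ...) {
  cat(sprintf(
    "<kmca_segmentation> k = %d, sizes: %s, tot.withinss = %.4g\n",
    x$k, paste(x$sizes, collapse = ", "), x$tot_withinss
  ))
  invisible(x)
}

#' @rdname kmca_segment
#' @param x A `kmca_segmentation`.
#' @param ... Unused.
#' @export
tidy.kmca_segmentation <- function(x, ...) {
  purrr::map_dfr(seq_len(x$k), function(i) {
    tibble(
      cluster = i, n_pixels = x$sizes[i],
      shift = x$shifts, intensity = x$centroids[i, ]
    )
  })
}

#' @rdname kmca_segment
#' @export
glance.kmca_segmentation <- function(x, ...) {
  tibble(
    k = x$k, tot_withinss = x$tot_withinss,
    largest = x$sizes[1], smallest = x$sizes[x$k]
  )
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; defined as 0 (with a warning) when both
#' masks are empty.
#'
#' @param a,b Logical matrices of the same shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), all(dim(a) == dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warn("Both masks empty: Dice defined as 0.")
    return(0)
  }
  2 * sum(a & b) / denom
}

#' Agreement between fingerprint KMCA nucleus cluster and the negative image
#'
#' Binarizes the C-H negative image inside the cell region by exact
#' two-means (the dark side is the nucleus candidate) and returns the
#' Dice overlap with the chosen fingerprint cluster(s).
#'
#' @param seg A `kmca_segmentation`.
#' @param nucleus_cluster_id Integer id(s) of the fingerprint cluster(s)
#'   covering the nucleus (and nucleolus).
#' @param negative The [negative_image()] of the same scan.
#' @param cell_mask Optional logical matrix restricting the dark-side
#'   thresholding to the cell; defaults to all pixels outside the largest
#'   fingerprint cluster (assumed substrate).
#' @return Dice coefficient in `[0, 1]`.
#' @export
nucleus_agreement <- function(seg, nucleus_cluster_id, negative,
                              cell_mask = NULL) {
  stopifnot(
    inherits(seg, "kmca_segmentation"),
    inherits(negative, "intensity_map"),
    all(dim(seg$labels) == dim(negative))
  )
  if (is.null(cell_mask)) {
    cell_mask <- matrix(as.integer(seg$labels) != 1L, nrow(negative), ncol(negative))
  }
  ref <- matrix(
    as.integer(seg$labels) %in% as.integer(nucleus_cluster_id),
    nrow(negative), ncol(negative)
  )
  vals <- as.numeric(negative)[cell_mask]
  if (length(vals) < 2) {
    warn("Cell region nearly empty: Dice defined as 0.")
    return(0)
  }
  # winsorize the bright tail so hot lipid-droplet pixels cannot absorb
  # the split; the nucleus/cytoplasm boundary sits far below it
  vals <- pmin(vals, quantile(vals, 0.95, names = FALSE))
  tm <- two_means_1d(vals)
  dark <- matrix(FALSE, nrow(negative), ncol(negative))
  if (tm$degenerate) {
    warn("Negative image constant over the cell: Dice defined as 0.")
    return(0)
  }
  dark[cell_mask] <- tm$labels == 0L
  dice_coefficient(dark, ref)
}

#' Best-match accuracy of a segmentation against ground-truth masks
#'
#' Assigns each truth region to a distinct cluster (exhaustive search
#' over injective assignments, i.e. Hungarian-style matching at the small
#' k used here) maximizing the number of correctly labeled pixels, and
#' returns the accuracy over the pixels covered by the truth masks.
#'
#' @param seg A `kmca_segmentation` (or a [label_map()]).
#' @param truth_masks Named list of disjoint logical matrices.
#' @return A list with `accuracy` and `mapping` (named integer vector
#'   truth-region -> cluster id).
#' @export
segmentation_accuracy <- function(seg, truth_masks) {
  labels <- if (inherits(seg, "kmca_segmentation")) seg$labels else seg
  lab <- as.integer(labels)
  k <- length(attr(labels, "levels"))
  regions <- names(truth_masks)
  # contingency: rows = regions, cols = clusters
  cont <- vapply(seq_len(k), function(j) {
    vapply(truth_masks, function(m) sum(lab[as.vector(m)] == j), numeric(1))
  }, numeric(length(regions)))
  cont <- matrix(cont, nrow = length(regions))
  total <- sum(vapply(truth_masks, sum, numeric(1)))
  if (length(regions) > k) abort("More truth regions than clusters.")
  best <- list(score = -1, assign = integer(0))
  search <- function(i, used, score, assign) {
    if (i > length(regions)) {
      if (score > best$score) best <<- list(score = score, assign = assign)
      return()
    }
    for (j in setdiff(seq_len(k), used)) {
      search(i + 1, c(used, j), score + cont[i, j], c(assign, j))
    }
  }
  search(1, integer(0), 0, integer(0))
  list(
    accuracy = best$score / total,
    mapping = stats::setNames(best$assign, regions)
  )
}
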