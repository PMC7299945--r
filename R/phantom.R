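# Region recipes: expected counts contributed by each endmember (unit
# peak height) in each scene region. The nucleus carries an elevated
# protein/DNA weight and a lipid weight at 20% of the cytoplasm's
# (reflecting the near-absence of lipids in the nucleus); the nucleolus
# is nucleus-like with 1.5x the protein weight; lipid droplets carry 5x
# the cytoplasmic lipid weight. Declared fixtures, not measurements.
PHANTOM_REGION_WEIGHTS <- list(
  substrate = c(caf2 = 300, water_oh = 100),
  cytoplasm = c(
    protein_ch = 180, lipid_ch = 120, water_oh = 90, fp_cytoplasm = 140
  ),
  nucleus = c(
    protein_ch = 300, lipid_ch = 24, water_oh = 90, fp_nucleus = 150
  ),
  nucleolus = c(
    protein_ch = 450, lipid_ch = 24, water_oh = 90, fp_nucleolus = 170
  ),
  droplet = c(
    protein_ch = 90, lipid_ch = 600, water_oh = 90, fp_droplet = 160
  )
)

#' Default fND placement table of the phantom
#'
#' Eight emitters: two low- and two high-grade internalized (nucleus and
#' cytoplasm), two low- and two high-grade on the substrate.
#'
#' @return A tibble with columns `id`, `row`, `col`, `inside`, `grade`.
#' @export
default_fnd_placements <- function() {
  tibble(
    id = 1:8,
    row = c(30, 40, 26, 36, 6, 58, 10, 55),
    col = c(30, 44, 38, 26, 8, 52, 56, 10),
    inside = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    grade = c("low", "low", "high", "high", "low", "low", "high", "high")
  )
}

#' Configuration of a synthetic PL/Raman cell phantom
#'
#' Describes a confocal scan of a single cell on a CaF2 substrate in
#' buffer, with nanodiamond point emitters: scene geometry (elliptical
#' cell, nucleus and nucleolus, circular lipid droplets), fND placements
#' and brightness grades, optics (Gaussian PSF), noise model
#' (Poisson shot noise plus Gaussian read noise) and the spectrograph
#' window (grating centre and span).
#'
#' @param height,width Image size in pixels.
#' @param pixel_size_um Pixel pitch (um); the default 0.5 um puts the
#'   0.7 px PSF sigma at roughly the 325 nm diffraction-limited lateral
#'   resolution.
#' @param cell_center,cell_radii Cell ellipse centre `(row, col)` and
#'   radii `(rows, cols)` in pixels.
#' @param nucleus_center,nucleus_radii Nucleus ellipse (must lie inside
#'   the cell).
#' @param nucleolus_center,nucleolus_radius Nucleolus disc (inside the
#'   nucleus).
#' @param droplet_centers Matrix-like of lipid-droplet centres (rows:
#'   droplets; columns: row, col); must lie in the cytoplasm.
#' @param droplet_radius Droplet radius in pixels.
#' @param fnd_placements Tibble with columns `id`, `row`, `col`, `inside`
#'   (logical: internalized or on the substrate) and `grade`
#'   (`"low"`/`"high"`).
#' @param grade_amplitude_ratio High-grade : low-grade brightness ratio
#'   (default 10).
#' @param fnd_snr Brightest-pixel PL-window band-area of a low-grade fND,
#'   in multiples of the reference band-area noise (default 20).
#' @param psf_sigma_px Gaussian PSF sigma in pixels.
#' @param integration_scale Multiplies all expected counts, emulating a
#'   longer per-pixel integration time (default 1). Fingerprint-region
#'   imaging requires substantially longer integration than combined
#'   PL/C-H imaging, so 610 nm-grating phantoms are typically generated
#'   with a value around 10.
#' @param shot_noise Apply Poisson shot noise?
#' @param read_noise_sd Gaussian read noise sigma (counts/channel).
#' @param ref_noise_sd Reference read-noise sigma (counts/channel) that
#'   defines the fND brightness unit via `fnd_snr`; kept separate from
#'   `read_noise_sd` so lowering the actual noise does not silently
#'   rescale the emitters.
#' @param excitation_nm Laser wavelength (nm).
#' @param grating_center_nm,grating_span_nm Spectrograph detection
#'   window. 610 nm keeps the fingerprint region; 680 nm trades it for
#'   the NV phonon sideband.
#' @param axis_step Master-axis channel spacing (cm^-1).
#' @param seed Integer seed; identical config + seed gives a bitwise
#'   identical cube.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 64, width = 64,
                           pixel_size_um = 0.5,
                           cell_center = c(34, 36), cell_radii = c(22, 17),
                           nucleus_center = c(36, 30), nucleus_radii = c(11, 9),
                           nucleolus_center = c(38, 31), nucleolus_radius = 3,
                           droplet_centers = rbind(
                             c(20, 26), c(46, 40), c(24, 46), c(28, 22)
                           ),
                           droplet_radius = 1.5,
                           fnd_placements = default_fnd_placements(),
                           grade_amplitude_ratio = 10,
                           fnd_snr = 20,
                           integration_scale = 1,
                           psf_sigma_px = 0.7,
                           shot_noise = TRUE,
                           read_noise_sd = 3,
                           ref_noise_sd = 3,
                           excitation_nm = 532,
                           grating_center_nm = 680,
                           grating_span_nm = 190,
                           axis_step = 6,
                           seed = 1L) {
  cfg <- list(
    height = height, width = width, pixel_size_um = pixel_size_um,
    cell_center = cell_center, cell_radii = cell_radii,
    nucleus_center = nucleus_center, nucleus_radii = nucleus_radii,
    nucleolus_center = nucleolus_center, nucleolus_radius = nucleolus_radius,
    droplet_centers = droplet_centers, droplet_radius = droplet_radius,
    fnd_placements = fnd_placements,
    grade_amplitude_ratio = grade_amplitude_ratio, fnd_snr = fnd_snr,
    integration_scale = integration_scale,
    psf_sigma_px = psf_sigma_px, shot_noise = shot_noise,
    read_noise_sd = read_noise_sd, ref_noise_sd = ref_noise_sd,
    excitation_nm = excitation_nm,
    grating_center_nm = grating_center_nm, grating_span_nm = grating_span_nm,
    axis_step = axis_step, seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

in_ellipse <- function(rows, cols, center, radii) {
  ((rows - center[1]) / radii[1])^2 + ((cols - center[2]) / radii[2])^2 <= 1
}

validate_phantom_config <- function(cfg) {
  p <- cfg$fnd_placements
  if (!all(c("id", "row", "col", "inside", "grade") %in% names(p))) {
    abort("`fnd_placements` needs columns id, row, col, inside, grade.")
  }
  if (any(p$row < 1 | p$row > cfg$height | p$col < 1 | p$col > cfg$width)) {
    abort("fND placements must lie within the image bounds.")
  }
  if (!all(p$grade %in% c("low", "high"))) {
    abort("fND `grade` must be \"low\" or \"high\".")
  }
  in_cell <- in_ellipse(p$row, p$col, cfg$cell_center, cfg$cell_radii)
  if (any(in_cell != p$inside)) {
    abort("fND `inside` flags disagree with the cell ellipse geometry.")
  }
  # nucleus inside cell, nucleolus inside nucleus (check extreme points)
  nc <- cfg$nucleus_center
  nr <- cfg$nucleus_radii
  ext <- rbind(
    nc + c(nr[1], 0), nc - c(nr[1], 0), nc + c(0, nr[2]), nc - c(0, nr[2])
  )
  if (!all(in_ellipse(ext[, 1], ext[, 2], cfg$cell_center, cfg$cell_radii))) {
    abort("Nucleus ellipse must lie inside the cell ellipse.")
  }
  oc <- cfg$nucleolus_center
  or <- cfg$nucleolus_radius
  ext2 <- rbind(oc + c(or, 0), oc - c(or, 0), oc + c(0, or), oc - c(0, or))
  if (!all(in_ellipse(ext2[, 1], ext2[, 2], nc, nr))) {
    abort("Nucleolus must lie inside the nucleus.")
  }
  dc <- cfg$droplet_centers
  for (i in seq_len(nrow(dc))) {
    if (!in_ellipse(dc[i, 1], dc[i, 2], cfg$cell_center, cfg$cell_radii) ||
        in_ellipse(dc[i, 1], dc[i, 2], nc, nr)) {
      abort("Lipid droplets must lie in the cytoplasm (inside cell, outside nucleus).")
    }
  }
  invisible(cfg)
}

phantom_masks <- function(cfg) {
  rows <- matrix(seq_len(cfg$height), cfg$height, cfg$width)
  cols <- matrix(seq_len(cfg$width), cfg$height, cfg$width, byrow = TRUE)
  cell <- in_ellipse(rows, cols, cfg$cell_center, cfg$cell_radii)
  nucleus_full <- in_ellipse(rows, cols, cfg$nucleus_center, cfg$nucleus_radii)
  nucleolus <- (rows - cfg$nucleolus_center[1])^2 +
    (cols - cfg$nucleolus_center[2])^2 <= cfg$nucleolus_radius^2
  droplets <- matrix(FALSE, cfg$height, cfg$width)
  dc <- cfg$droplet_centers
  for (i in seq_len(nrow(dc))) {
    droplets <- droplets |
      ((rows - dc[i, 1])^2 + (cols - dc[i, 2])^2 <= cfg$droplet_radius^2)
  }
  droplets <- droplets & cell & !nucleus_full
  list(
    substrate = !cell,
    cytoplasm = cell & !nucleus_full & !droplets,
    nucleus = nucleus_full & !nucleolus,
    nucleolus = nucleolus,
    droplets = droplets
  )
}

gaussian_psf_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  k / sum(k)
}

#' Generate a synthetic PL/Raman phantom cube with ground truth
#'
#' Builds the per-pixel expected spectrum as the weighted sum of the
#' region endmembers plus, at fND pixels, the calibrated NV emission
#' model blurred by the Gaussian PSF; truncates it to the configured
#' grating window; then applies Poisson shot noise and Gaussian read
#' noise. fND brightness is parameterized in detection units: a low-grade
#' emitter's brightest pixel carries a PL-window (1800-2700 cm^-1) band
#' area of `fnd_snr` times the read-noise-propagated band-area noise.
#'
#' @param config A [phantom_config()].
#' @return A list with elements
#'   \describe{
#'     \item{cube}{The [hyper_cube()] restricted to the grating window.}
#'     \item{truth}{Ground truth: `masks` (substrate, cytoplasm, nucleus,
#'       nucleolus, droplets), `fnd` (placement table with amplitudes),
#'       `nv_amplitude` (post-PSF NV amplitude image),
#'       `pl_noise_sd` (the band-area noise unit used for brightness),
#'       and `config`.}
#'   }
#' @examples
#' ph <- make_phantom(phantom_config(seed = 7))
#' ph$cube
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  validate_phantom_config(config)
  cfg <- config
  masks <- phantom_masks(cfg)

  shifts <- seq(100, 7700, by = cfg$axis_step)
  axis <- spectral_axis(shifts, cfg$excitation_nm)
  em_names <- setdiff(endmember_names(), "nv_emission")
  E <- vapply(
    em_names, endmember, numeric(length(shifts)),
    shifts = shifts, excitation_nm = cfg$excitation_nm
  )

  npx <- cfg$height * cfg$width
  W <- matrix(0, npx, length(em_names), dimnames = list(NULL, em_names))
  region_of <- c(
    substrate = "substrate", cytoplasm = "cytoplasm",
    nucleus = "nucleus", nucleolus = "nucleolus", droplets = "droplet"
  )
  for (m in names(masks)) {
    w <- PHANTOM_REGION_WEIGHTS[[region_of[[m]]]]
    W[as.vector(masks[[m]]), names(w)] <-
      matrix(w, sum(masks[[m]]), length(w), byrow = TRUE)
  }
  expected <- W %*% t(E) # npx x C

  # NV emission, normalized so its PL-window band area is 1
  nv <- endmember("nv_emission", shifts, cfg$excitation_nm)
  pl_win <- c(1800, 2700)
  idx <- which(shifts >= pl_win[1] & shifts <= pl_win[2])
  nv_unit <- nv / trapz(shifts[idx], nv[idx])

  kernel <- gaussian_psf_kernel(cfg$psf_sigma_px)
  n_pl <- length(idx)
  # noise of the PL-window trapezoid band area, propagated from the
  # per-channel read noise; the brightness unit uses the fixed reference
  # noise so that changing the noise settings does not silently rescale
  # the emitters
  pl_noise_sd <- cfg$read_noise_sd * cfg$axis_step * sqrt(n_pl)
  pl_ref_noise <- cfg$ref_noise_sd * cfg$axis_step * sqrt(n_pl)
  amp_low <- cfg$fnd_snr * pl_ref_noise / max(kernel)
  fnd <- cfg$fnd_placements
  fnd$amplitude <- ifelse(
    fnd$grade == "high", amp_low * cfg$grade_amplitude_ratio, amp_low
  )
  amp_img <- matrix(0, cfg$height, cfg$width)
  for (i in seq_len(nrow(fnd))) {
    amp_img[fnd$row[i], fnd$col[i]] <- amp_img[fnd$row[i], fnd$col[i]] +
      fnd$amplitude[i]
  }
  if (nrow(fnd) > 0) {
    amp_blur <- EBImage::filter2(amp_img, kernel, boundary = "replicate")
    amp_blur <- pmax(amp_blur, 0) # clip FFT ringing of the convolution
    expected <- expected + as.vector(amp_blur) %o% nv_unit
  } else {
    amp_blur <- amp_img
  }

  expected <- expected * cfg$integration_scale
  full <- hyper_cube(
    array(expected, dim = c(cfg$height, cfg$width, length(shifts))),
    axis,
    pixel_size_um = cfg$pixel_size_um,
    metadata = list(phantom_seed = cfg$seed)
  )
  cube <- crop_to_window(full, cfg$grating_center_nm, cfg$grating_span_nm)

  # noise (seeded; RNG state restored on exit)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(cfg$seed)
  d <- cube$data
  if (cfg$shot_noise) {
    d[] <- rpois(length(d), lambda = d)
  }
  if (cfg$read_noise_sd > 0) {
    d <- d + rnorm(length(d), sd = cfg$read_noise_sd)
  }
  cube$data <- d

  list(
    cube = cube,
    truth = list(
      masks = masks,
      fnd = fnd,
      nv_amplitude = amp_blur,
      pl_noise_sd = pl_noise_sd,
      config = cfg
    )
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# 3x3 box dilation (one-pixel ring) used for PSF-tolerant scoring
dilate_ring <- function(mask) {
  out <- mask
  h <- nrow(mask)
  w <- ncol(mask)
  shift <- function(m, dr, dc) {
    res <- matrix(FALSE, h, w)
    r_src <- max(1, 1 - dr):min(h, h - dr)
    c_src <- max(1, 1 - dc):min(w, w - dc)
    res[r_src + dr, c_src + dc] <- m[r_src, c_src]
    res
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr != 0 || dc != 0) out <- out | shift(mask, dr, dc)
  }
  out
}

#' PSF-tolerant detection scores against a point-emitter truth mask
#'
#' Point emitters are blurred by the PSF, so detections in the one-pixel
#' ring around a true emitter pixel are neither rewarded nor punished:
#' precision counts false positives only outside the dilated truth mask,
#' recall is the fraction of truth pixels detected.
#'
#' @param detected,truth Logical `H x W` matrices.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
detection_scores <- function(detected, truth) {
  stopifnot(
    is.logical(detected), is.logical(truth),
    all(dim(detected) == dim(truth))
  )
  tp <- sum(detected & truth)
  fp <- sum(detected & !dilate_ring(truth))
  fn <- sum(truth & !detected)
  tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (sum(truth) == 0) 1 else tp / sum(truth)
  )
}

#' Score a classification against phantom ground truth
#'
#' Detection precision/recall (PSF-ring tolerant, see
#' [detection_scores()]) over the true fND pixels, plus in/out
#' (intracellular vs extracellular) and brightness-grade accuracy over
#' the detected true fND pixels.
#'
#' @param classification An `fnd_classification` from [classify_fnd()],
#'   or a `label_map` over the five-class scheme.
#' @param truth The `truth` element of [make_phantom()] output.
#' @return A one-row tibble: `precision`, `recall`, `inout_accuracy`,
#'   `grade_accuracy`, `n_fnd`.
#' @export
phantom_recovery <- function(classification, truth) {
  labels <- if (inherits(classification, "fnd_classification")) {
    classification$labels
  } else {
    classification
  }
  lv <- attr(labels, "levels")
  lab_chr <- matrix(lv[labels], nrow(labels), ncol(labels))
  detected <- lab_chr != "NONLUM"
  truth_mask <- matrix(FALSE, nrow(labels), ncol(labels))
  fnd <- truth$fnd
  truth_mask[cbind(fnd$row, fnd$col)] <- TRUE
  det <- detection_scores(detected, truth_mask)

  hit <- detected[cbind(fnd$row, fnd$col)]
  lab_fnd <- lab_chr[cbind(fnd$row, fnd$col)]
  inout_ok <- (lab_fnd %in% c("INTRA_LOW", "INTRA_HIGH")) == fnd$inside
  grade_ok <- (lab_fnd %in% c("EXTRA_HIGH", "INTRA_HIGH")) == (fnd$grade == "high")
  tibble(
    precision = det$precision,
    recall = det$recall,
    inout_accuracy = if (any(hit)) mean(inout_ok[hit]) else NA_real_,
    grade_accuracy = if (any(hit)) mean(grade_ok[hit]) else NA_real_,
    n_fnd = nrow(fnd)
  )
}
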