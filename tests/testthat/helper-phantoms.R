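# Phantoms reused across test files, generated once per run.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# default classification scene: 680 nm grating, both placements, both grades
default_phantom <- function() {
  cached("default", make_phantom(phantom_config(seed = 1)))
}

# fingerprint scene: 610 nm grating, longer integration, no fNDs
fingerprint_phantom <- function() {
  cached("fingerprint", make_phantom(phantom_config(
    grating_center_nm = 610, grating_span_nm = 190,
    integration_scale = 4, seed = 2,
    fnd_placements = default_fnd_placements()[0, ]
  )))
}

# noiseless variant of the default scene
noiseless_phantom <- function() {
  cached("noiseless", make_phantom(phantom_config(
    seed = 1, shot_noise = FALSE, read_noise_sd = 0
  )))
}

# noiseless cell-only scene (no emitters): pure non-negative Raman spectra
noiseless_cell_phantom <- function() {
  cached("noiseless_nofnd", make_phantom(phantom_config(
    seed = 1, shot_noise = FALSE, read_noise_sd = 0,
    fnd_placements = default_fnd_placements()[0, ]
  )))
}

default_classification <- function() {
  cached("classification", suppressMessages(classify_fnd(default_phantom()$cube)))
}

# a small 24x24 scene (geometry scaled down from the default)
small_config <- function(seed = 1, ...) {
  phantom_config(
    height = 24, width = 24,
    cell_center = c(13, 13), cell_radii = c(8, 6),
    nucleus_center = c(14, 12), nucleus_radii = c(4, 3),
    nucleolus_center = c(15, 12), nucleolus_radius = 1,
    droplet_centers = rbind(c(8, 10)), droplet_radius = 1,
    fnd_placements = tibble::tibble(
      id = 1:4, row = c(13, 17, 3, 21), col = c(13, 17, 3, 20),
      inside = c(TRUE, TRUE, FALSE, FALSE),
      grade = c("low", "high", "low", "high")
    ),
    seed = seed, ...
  )
}

# a tiny analytic cube: Gaussian C-H band whose amplitude varies per pixel
gaussian_cube <- function(amplitudes = matrix(1, 2, 2),
                          center = 2920, sigma = 30,
                          shifts = seq(2600, 3200, by = 4)) {
  axis <- spectral_axis(shifts)
  h <- nrow(amplitudes)
  w <- ncol(amplitudes)
  band <- exp(-(shifts - center)^2 / (2 * sigma^2))
  data <- array(0, dim = c(h, w, length(shifts)))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    data[i, j, ] <- amplitudes[i, j] * band
  }
  hyper_cube(data, axis)
}

# brute-force oracle for the optimal 1-d two-cluster split
brute_force_two_means <- function(values) {
  x <- sort(values)
  n <- length(x)
  best <- list(sse = Inf, i = NA)
  for (i in seq_len(n - 1)) {
    lo <- x[1:i]
    hi <- x[(i + 1):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best$sse - 1e-12) best <- list(sse = sse, i = i)
  }
  best
}
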