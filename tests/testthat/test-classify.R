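# positions for a 20-emitter single-grade scene, spread over cell and
# substrate, each at least 4 px from the others and from the image edge
twenty_placements <- function(cfg = phantom_config()) {
  rows <- c(6, 6, 6, 14, 14, 14, 22, 22, 50, 50, 54, 58, 58, 34, 36, 40, 30, 26, 44, 46)
  cols <- c(8, 20, 52, 6, 40, 58, 6, 56, 6, 58, 30, 16, 44, 34, 44, 30, 24, 36, 26, 44)
  tibble::tibble(
    id = seq_along(rows), row = rows, col = cols,
    inside = ramanfnd:::in_ellipse(rows, cols, cfg$cell_center, cfg$cell_radii),
    grade = "low"
  )
}

test_that("pl_feature isolates NV brightness from the cell Raman signal", {
  # noiseless emitter-free scene: the feature vanishes (up to band tails)
  pl0 <- pl_feature(noiseless_cell_phantom()$cube)
  expect_lt(max(abs(pl0)), 1e-3)

  ph <- default_phantom()
  pl <- pl_feature(ph$cube)
  noise <- mad(as.numeric(pl))
  # emitter-free pixels sit at the noise floor (the dark-offset
  # convention biases the whole map up by ~2 sigma, within the floor)
  expect_lt(abs(median(pl[ph$truth$masks$substrate])), 3 * noise)
  expect_lt(abs(median(pl[ph$truth$masks$cytoplasm])), 3 * noise)
  fnd <- ph$truth$fnd
  vals <- pl[cbind(fnd$row, fnd$col)]
  # high-grade emitters are brighter than low-grade ones
  expect_gt(min(vals[fnd$grade == "high"]), max(vals[fnd$grade == "low"]))

  # linearity: doubling the emitter brightness doubles the feature
  mk <- function(snr) make_phantom(phantom_config(
    fnd_snr = snr, shot_noise = FALSE, read_noise_sd = 0, seed = 1
  ))
  pa <- pl_feature(mk(20)$cube)
  pb <- pl_feature(mk(40)$cube)
  at <- cbind(fnd$row, fnd$col)
  expect_equal(pb[at], 2 * pa[at], tolerance = 1e-9)
})

test_that("detect_luminescent guards against false positives", {
  # fND-free phantom: no luminescent pixels
  ph0 <- make_phantom(phantom_config(
    seed = 3, fnd_placements = default_fnd_placements()[0, ]
  ))
  det0 <- suppressMessages(detect_luminescent(pl_feature(ph0$cube)))
  expect_false(any(det0$mask))

  # all-zero map: degenerate, empty mask
  d0 <- suppressMessages(detect_luminescent(intensity_map(matrix(0, 8, 8))))
  expect_false(any(d0$mask))

  # 20 emitters at 50x noise: exactly those pixels, up to the PSF ring
  pl20 <- twenty_placements()
  ph <- make_phantom(phantom_config(fnd_placements = pl20, fnd_snr = 50, seed = 4))
  det <- detect_luminescent(pl_feature(ph$cube))
  truth <- matrix(FALSE, 64, 64)
  truth[cbind(pl20$row, pl20$col)] <- TRUE
  sc <- detection_scores(det$mask, truth)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
})

test_that("split_by_ch localizes emitters chemically", {
  cfg <- classifier_config()
  # all emitters on the substrate -> all outside
  out_only <- dplyr::filter(default_fnd_placements(), !inside)
  ph_out <- make_phantom(phantom_config(fnd_placements = out_only, seed = 7))
  det <- detect_luminescent(pl_feature(ph_out$cube))
  ch <- band_map(ph_out$cube, cfg$ch_window, "linear_endpoints")
  sp <- suppressMessages(split_by_ch(det$mask, ch, cfg))
  expect_false(any(sp$inside))
  expect_true(any(sp$outside))

  # all emitters in the cytoplasm -> all inside
  in_only <- dplyr::filter(default_fnd_placements(), inside)
  ph_in <- make_phantom(phantom_config(fnd_placements = in_only, seed = 8))
  det_i <- detect_luminescent(pl_feature(ph_in$cube))
  ch_i <- band_map(ph_in$cube, cfg$ch_window, "linear_endpoints")
  sp_i <- suppressMessages(split_by_ch(det_i$mask, ch_i, cfg))
  expect_false(any(sp_i$outside))
  expect_true(any(sp_i$inside))

  expect_error(split_by_ch(matrix(FALSE, 4, 4), intensity_map(matrix(0, 4, 4))), "one")
})

test_that("split_by_intensity separates grades and falls back to low", {
  pl <- intensity_map(matrix(c(rep(0, 12), 5, 5, 50, 50), 4, 4))
  grp <- matrix(FALSE, 4, 4)
  grp[13:16] <- TRUE
  si <- split_by_intensity(grp, pl, noise_sd = 0)
  expect_equal(which(si$low), 13:14)
  expect_equal(which(si$high), 15:16)

  # single-pixel group: low by the fallback rule
  one <- matrix(FALSE, 4, 4)
  one[16] <- TRUE
  s1 <- split_by_intensity(one, pl, noise_sd = 0)
  expect_equal(which(s1$low), 16L)
  expect_false(any(s1$high))

  # weakly separated group: everything low
  pl2 <- intensity_map(matrix(c(rep(0, 12), 100, 101, 100, 101), 4, 4))
  s2 <- split_by_intensity(grp, pl2, noise_sd = 50)
  expect_true(all(s2$low[grp]))
})

test_that("classify_fnd yields the five-class partition on the default phantom", {
  ph <- default_phantom()
  cl <- default_classification()
  counts <- label_counts(cl$labels)
  expect_setequal(counts$label, c("NONLUM", "EXTRA_LOW", "EXTRA_HIGH", "INTRA_LOW", "INTRA_HIGH"))
  # all five classes are populated and partition the image
  expect_true(all(counts$n_pixels > 0))
  expect_equal(sum(counts$n_pixels), prod(dim(cl$labels)))
  expect_equal(glance(cl)$n_classes, 5)

  # fND-free phantom: only the non-luminescent class
  ph0 <- make_phantom(phantom_config(
    seed = 3, fnd_placements = default_fnd_placements()[0, ]
  ))
  cl0 <- suppressMessages(classify_fnd(ph0$cube))
  expect_equal(glance(cl0)$n_classes, 1)
  expect_true(all(as.integer(cl0$labels) == 1L))

  # report carries thresholds and class counts
  expect_true(is.finite(cl$report$pl_threshold))
  expect_equal(sum(unlist(cl$report$class_counts)), 64 * 64)
  td <- tidy(cl)
  expect_equal(td$color[td$label == "INTRA_LOW"], "#FFFF00")
})

test_that("fixed-threshold mode is monotone in emitter brightness", {
  cfg <- classifier_config(
    threshold_mode = "fixed",
    fixed_thresholds = list(pl = 1000, ch = 5000, grade = 20000)
  )
  base <- noiseless_phantom()
  cl1 <- classify_fnd(base$cube, cfg)
  brighter <- make_phantom(phantom_config(
    seed = 1, shot_noise = FALSE, read_noise_sd = 0, fnd_snr = 40
  ))
  cl2 <- classify_fnd(brighter$cube, cfg)
  lum1 <- as.integer(cl1$labels) != 1L
  lum2 <- as.integer(cl2$labels) != 1L
  # no pixel is demoted from luminescent to non-luminescent
  expect_true(all(lum2[lum1]))
})

test_that("cluster mean spectra conserve mass and show C-H only inside", {
  ph <- default_phantom()
  cl <- default_classification()
  sp <- cluster_mean_spectra(ph$cube, cl$labels)

  # single-label map: the overall mean spectrum
  all1 <- label_map(matrix(1L, 64, 64), "ALL")
  g <- cluster_mean_spectra(ph$cube, all1)
  expect_equal(g$counts, colMeans(matrix(ph$cube$data, nrow = 64 * 64)))

  # count-weighted average of class means equals the global mean
  wide <- tidyr::pivot_wider(
    sp[, c("label", "shift", "counts")],
    names_from = "label", values_from = "counts"
  )
  n <- vapply(split(sp$n_pixels, sp$label), `[`, numeric(1), 1)
  lv <- setdiff(names(wide), "shift")
  agg <- as.matrix(wide[, lv]) %*% n[lv] / sum(n[lv])
  expect_equal(as.numeric(agg), g$counts, tolerance = 1e-12)

  # intracellular classes carry the C-H band, extracellular do not
  area <- vapply(split(sp, sp$label), function(d) {
    band_integral(d[order(d$shift), ], c(2800, 2980), "linear_endpoints")
  }, numeric(1))
  expect_gt(min(area[c("INTRA_LOW", "INTRA_HIGH")]),
            5 * max(area[c("EXTRA_LOW", "EXTRA_HIGH")]))
  expect_lt(max(area[c("EXTRA_LOW", "EXTRA_HIGH")]), 0.2 * min(area[c("INTRA_LOW", "INTRA_HIGH")]))
})

test_that("classification recovers phantom ground truth across seeds", {
  res <- purrr::map_dfr(1:5, function(s) {
    ph <- make_phantom(phantom_config(seed = s))
    cl <- suppressMessages(classify_fnd(ph$cube))
    phantom_recovery(cl, ph$truth)
  })
  expect_gte(mean(res$precision), 0.95)
  expect_gte(mean(res$recall), 0.95)
  expect_gte(mean(res$inout_accuracy), 0.95)
  expect_gte(mean(res$grade_accuracy), 0.95)
})
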