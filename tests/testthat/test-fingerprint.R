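test_that("fingerprint preprocessing yields unit-area spectra above the floor", {
  ph <- fingerprint_phantom()
  fp <- ramanfnd:::fingerprint_features(ph$cube, c(700, 1700))
  dx <- diff(fp$shifts)
  wts <- c(dx / 2, 0) + c(0, dx / 2)
  areas <- as.numeric(fp$features %*% wts)
  above <- fp$area > fp$floor
  expect_gt(sum(above), 1000)
  expect_equal(areas[above], rep(1, sum(above)), tolerance = 1e-9)
  # floored (signal-free) pixels are not inflated
  expect_true(all(abs(areas[!above]) <= 1 + 1e-9))
})

test_that("kmca_segment is deterministic and degenerates gracefully", {
  ph <- fingerprint_phantom()
  s1 <- kmca_segment(ph$cube, k = 4, seed = 3)
  s2 <- kmca_segment(ph$cube, k = 4, seed = 3)
  expect_identical(as.integer(s1$labels), as.integer(s2$labels))
  # sizes sorted descending, labels renumbered accordingly
  expect_true(all(diff(s1$sizes) <= 0))
  expect_equal(sum(s1$sizes), prod(dim(s1$labels)))

  # k = 1: single cluster, centroid equals the global normalized mean
  s0 <- kmca_segment(ph$cube, k = 1)
  expect_equal(unique(as.integer(s0$labels)), 1L)
  fp <- ramanfnd:::fingerprint_features(ph$cube, c(700, 1700))
  expect_equal(as.numeric(s0$centroids[1, ]), colMeans(fp$features))

  expect_error(kmca_segment(ph$cube, k = 0), ">= 1")
  expect_error(kmca_segment(ph$cube, k = 1e6), "pixels")
})

test_that("fingerprint KMCA recovers the organelle structure", {
  ph <- fingerprint_phantom()
  seg <- kmca_segment(ph$cube, k = 4, seed = 3)
  acc <- segmentation_accuracy(
    seg, ph$truth$masks[c("substrate", "cytoplasm", "nucleus", "nucleolus")]
  )
  expect_gte(acc$accuracy, 0.9)
  # best-match assignment is injective
  expect_equal(anyDuplicated(acc$mapping), 0L)
})

test_that("dice_coefficient handles the standard cases", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  b <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(dice_coefficient(a, b), 2 * 1 / 3)
  expect_warning(
    z <- dice_coefficient(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty"
  )
  expect_equal(z, 0)
})

test_that("negative-image dark region agrees with the fingerprint nucleus cluster", {
  ph <- fingerprint_phantom()
  seg <- kmca_segment(ph$cube, k = 4, seed = 3)
  nucmask <- ph$truth$masks$nucleus | ph$truth$masks$nucleolus
  ov <- vapply(1:4, function(j) sum((as.integer(seg$labels) == j) & nucmask), numeric(1))
  nid <- which.max(ov)
  neg <- negative_image(ph$cube)
  d <- nucleus_agreement(seg, nid, neg, cell_mask = !ph$truth$masks$substrate)
  expect_gte(d, 0.8)
  # the default cell mask (complement of the largest cluster) agrees too
  expect_gte(nucleus_agreement(seg, nid, neg), 0.8)
})

test_that("segmentation accuracy is invariant to label permutation", {
  ph <- fingerprint_phantom()
  seg <- kmca_segment(ph$cube, k = 4, seed = 3)
  masks <- ph$truth$masks[c("substrate", "cytoplasm", "nucleus", "nucleolus")]
  acc <- segmentation_accuracy(seg, masks)
  # permute cluster ids and recompute
  perm <- c(3L, 1L, 4L, 2L)
  permuted <- label_map(
    matrix(perm[as.integer(seg$labels)], nrow(seg$labels), ncol(seg$labels)),
    attr(seg$labels, "levels")
  )
  acc2 <- segmentation_accuracy(permuted, masks)
  expect_equal(acc2$accuracy, acc$accuracy)
})
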