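test_that("identical config and seed give bitwise-identical cubes", {
  a <- make_phantom(small_config(seed = 5))
  b <- make_phantom(small_config(seed = 5))
  expect_identical(a$cube$data, b$cube$data)
  c <- make_phantom(small_config(seed = 6))
  expect_false(identical(a$cube$data, c$cube$data))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(3)
  set.seed(123)
  invisible(make_phantom(small_config(seed = 9)))
  expect_identical(runif(3), r1)
})

test_that("noiseless pixel spectra equal the weighted endmember sums", {
  ph <- noiseless_phantom()
  cube <- ph$cube
  shifts <- cube$axis$shifts
  recipes <- ramanfnd:::PHANTOM_REGION_WEIGHTS
  expected_for <- function(region) {
    w <- recipes[[region]]
    rowSums(vapply(
      names(w), function(nm) w[nm] * endmember(nm, shifts), numeric(length(shifts))
    ))
  }
  # pick one pixel per region outside every fND's PSF support
  px <- list(substrate = c(2, 2), cytoplasm = c(20, 40), nucleus = c(42, 28))
  for (r in names(px)) {
    got <- as.numeric(cube$data[px[[r]][1], px[[r]][2], ])
    expect_equal(got, expected_for(r), tolerance = 1e-9, label = r)
  }
})

test_that("truth masks partition the scene consistently", {
  ph <- default_phantom()
  mk <- ph$truth$masks
  total <- Reduce(`+`, lapply(mk, function(m) m * 1))
  expect_true(all(total == 1)) # disjoint and exhaustive
  # nucleolus inside nucleus's full ellipse, droplets inside the cell
  expect_true(all(!(mk$nucleolus & mk$substrate)))
  expect_true(all(!(mk$droplets & mk$substrate)))
  # every fND record maps to a pixel with positive blurred amplitude
  fnd <- ph$truth$fnd
  expect_true(all(ph$truth$nv_amplitude[cbind(fnd$row, fnd$col)] > 0))
  expect_equal(
    fnd$amplitude[fnd$grade == "high"][1],
    10 * fnd$amplitude[fnd$grade == "low"][1]
  )
})

test_that("config invariants are enforced with descriptive errors", {
  expect_error(
    phantom_config(fnd_placements = tibble::tibble(
      id = 1, row = 99, col = 3, inside = FALSE, grade = "low"
    )),
    "bounds"
  )
  expect_error(
    phantom_config(fnd_placements = tibble::tibble(
      id = 1, row = 34, col = 36, inside = FALSE, grade = "low"
    )),
    "disagree"
  )
  expect_error(phantom_config(nucleus_radii = c(30, 30)), "inside the cell")
  expect_error(phantom_config(nucleolus_center = c(10, 10)), "nucleus")
  expect_error(phantom_config(droplet_centers = rbind(c(36, 30))), "cytoplasm")
  expect_error(
    phantom_config(fnd_placements = tibble::tibble(
      id = 1, row = 6, col = 8, inside = FALSE, grade = "medium"
    )),
    "grade"
  )
})

test_that("the 680 nm grating loses the fingerprint region, 610 nm keeps it", {
  ph680 <- default_phantom()
  expect_gt(min(ph680$cube$axis$shifts), 1600)
  ph610 <- fingerprint_phantom()
  sh <- ph610$cube$axis$shifts
  expect_lt(min(sh), 700)
  expect_true(any(sh >= 700 & sh <= 1700))
  expect_gt(max(sh), 3400) # water band still visible at 610 nm
})

test_that("halving the read noise never decreases detection recall", {
  for (s in 1:5) {
    rec <- vapply(c(3, 1.5), function(noise) {
      ph <- make_phantom(phantom_config(seed = s, read_noise_sd = noise))
      cl <- suppressMessages(classify_fnd(ph$cube))
      phantom_recovery(cl, ph$truth)$recall
    }, numeric(1))
    expect_gte(rec[2], rec[1])
  }
})
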