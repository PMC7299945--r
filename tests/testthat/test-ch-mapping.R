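test_that("negative image shows the nucleus dark, positive bright", {
  ph <- default_phantom()
  mk <- ph$truth$masks
  neg <- negative_image(ph$cube)
  pos <- positive_image(ph$cube)

  expect_lt(mean(neg[mk$nucleus]), mean(neg[mk$cytoplasm]))
  expect_gt(mean(pos[mk$nucleus]), mean(pos[mk$cytoplasm]))

  # nucleus/cytoplasm contrast ratio in the negative image is strong
  expect_lt(mean(neg[mk$nucleus]) / mean(neg[mk$cytoplasm]), 0.6)
  # the positive-image contrast is weaker than the (inverse) negative one
  expect_lt(
    mean(pos[mk$nucleus]) / mean(pos[mk$cytoplasm]),
    mean(neg[mk$cytoplasm]) / mean(neg[mk$nucleus])
  )

  # nucleus-contrast signs are opposite between the two maps
  neg_contrast <- mean(neg[mk$nucleus]) - mean(neg[mk$cytoplasm])
  pos_contrast <- mean(pos[mk$nucleus]) - mean(pos[mk$cytoplasm])
  expect_lt(neg_contrast * pos_contrast, 0)
})

test_that("pure-lipid pixels dominate the negative window at equal C-H area", {
  shifts <- seq(2600, 3200, by = 2)
  lip <- endmember("lipid_ch", shifts)
  pro <- endmember("protein_ch", shifts)
  full <- c(2800, 3030)
  sp <- function(y) tibble::tibble(shift = shifts, counts = y)
  # scale both to equal full-band area, then compare the lipid sub-band
  lip <- lip / band_integral(sp(lip), full)
  pro <- pro / band_integral(sp(pro), full)
  expect_gt(
    band_integral(sp(lip), c(2800, 2935), "linear_endpoints"),
    band_integral(sp(pro), c(2800, 2935), "linear_endpoints")
  )
})

test_that("C-H maps vanish on C-H-free cubes and are deterministic", {
  shifts <- seq(2600, 3200, by = 4)
  flat <- hyper_cube(
    array(5, dim = c(3, 3, length(shifts))), spectral_axis(shifts)
  )
  expect_equal(max(abs(negative_image(flat))), 0)
  expect_equal(max(abs(positive_image(flat))), 0)
  expect_equal(max(abs(full_ch_image(flat))), 0)

  ph <- default_phantom()
  expect_identical(
    as.numeric(negative_image(ph$cube)), as.numeric(negative_image(ph$cube))
  )
})

test_that("sub-band windows tile inside the full C-H window", {
  ph <- noiseless_cell_phantom()
  # plain integrals: full window dominates each sub-band exactly
  f0 <- band_map(ph$cube, c(2800, 3030), "none")
  expect_true(all(f0 - band_map(ph$cube, c(2800, 2935), "none") >= -1e-9))
  expect_true(all(f0 - band_map(ph$cube, c(2930, 3010), "none") >= -1e-9))
  # chord-baselined maps agree to a small fraction of the dynamic range
  fc <- full_ch_image(ph$cube)
  tol <- 1e-3 * diff(range(fc))
  expect_true(all(fc - negative_image(ph$cube) >= -tol))
  expect_true(all(fc - positive_image(ph$cube) >= -tol))
})

test_that("full C-H image separates cell from bare substrate", {
  ph <- default_phantom()
  mk <- ph$truth$masks
  fc <- full_ch_image(ph$cube)
  expect_gt(mean(fc[mk$cytoplasm]), 5 * mean(fc[mk$substrate]))
})
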