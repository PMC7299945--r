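test_that("band_integral handles flat and Gaussian spectra analytically", {
  shifts <- seq(2000, 3600, by = 2)
  zero <- tibble::tibble(shift = shifts, counts = 0)
  expect_equal(band_integral(zero, c(2500, 3000)), 0)

  flat <- tibble::tibble(shift = shifts, counts = 1)
  w <- 3000 - 2500
  expect_equal(band_integral(flat, c(2500, 3000)), w)
  # chord subtraction removes a constant exactly
  expect_equal(band_integral(flat, c(2500, 3000), "linear_endpoints"), 0)

  # Gaussian closed form: A * sigma * sqrt(2*pi) within 0.1%
  a <- 7
  sigma <- 20
  g <- tibble::tibble(
    shift = shifts, counts = a * exp(-(shifts - 2800)^2 / (2 * sigma^2))
  )
  expect_equal(
    band_integral(g, c(2800 - 5 * sigma, 2800 + 5 * sigma)),
    a * sigma * sqrt(2 * pi),
    tolerance = 1e-3
  )
})

test_that("band_integral rejects bad windows", {
  sp <- tibble::tibble(shift = seq(100, 200, 10), counts = 1)
  expect_error(band_integral(sp, c(150, 120)), "lo < hi")
  expect_error(band_integral(sp, c(50, 150)), "outside")
  expect_error(band_integral(sp, c(100, 300)), "outside")
  expect_error(band_integral(sp, c(101, 105)), "2 channels")
})

test_that("band_map matches per-pixel band_integral and is linear", {
  amp <- matrix(c(1, 2, 3, 4), 2, 2)
  cube <- gaussian_cube(amp)
  m <- band_map(cube, c(2800, 3030))
  expect_s3_class(m, "intensity_map")
  expect_equal(dim(m), c(2, 2))
  # identical spectra scaled by amplitude: map proportional to amplitude
  expect_equal(as.numeric(m) / as.numeric(m)[1], as.numeric(amp))
  # single pixel agrees with band_integral
  one <- gaussian_cube(matrix(5, 1, 1))
  expect_equal(
    as.numeric(band_map(one, c(2800, 3030))),
    band_integral(pixel_spectrum(one, 1, 1), c(2800, 3030))
  )
  # linearity in the cube with baseline none
  cube2 <- gaussian_cube(amp, center = 2860)
  both <- cube
  both$data <- cube$data + cube2$data
  expect_equal(
    as.numeric(band_map(both, c(2800, 3030))),
    as.numeric(band_map(cube, c(2800, 3030))) +
      as.numeric(band_map(cube2, c(2800, 3030)))
  )
})

test_that("normalize_map clips percentiles and maps to [0, 1]", {
  set.seed(7)
  m <- intensity_map(matrix(runif(400), 20, 20))
  n0 <- normalize_map(m, 0, 100)
  expect_equal(min(n0), 0)
  expect_equal(max(n0), 1)
  expect_equal(attr(n0, "units"), "normalized")

  # already-[0,1] map with clip 0/100 is only affinely rescaled to full range
  flat01 <- intensity_map(matrix(seq(0, 1, length.out = 100), 10, 10))
  expect_equal(as.numeric(normalize_map(flat01, 0, 100)), as.numeric(flat01))

  # a single hot pixel must not compress the body of the histogram
  v <- matrix(runif(400), 20, 20)
  v[1, 1] <- 100 * max(v)
  nh <- normalize_map(intensity_map(v), 1, 99)
  body <- as.numeric(nh)[-1]
  expect_gt(diff(range(body)), 0.5)

  expect_warning(out <- normalize_map(intensity_map(matrix(3, 4, 4))), "Constant")
  expect_true(all(out == 0.5))
  expect_error(normalize_map(m, 50, 40), "clip")
})
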