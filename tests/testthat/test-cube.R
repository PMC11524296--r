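make_refs <- function(nr, nc, p, white = 1000, dark = 100) {
  reference_frames(white = array(white, c(nr, nc, p)),
                   dark = array(dark, c(nr, nc, p)))
}

test_that("reflectance calibration satisfies (I - D)/(W - D)", {
  g <- wavelength_grid(seq(900, 1000, length.out = 4))
  refs <- make_refs(3, 3, 4)
  as_cube <- function(v) hypercube(array(v, c(3, 3, 4)), g)
  expect_equal(calibrate_reflectance(as_cube(1000), refs)$data,
               array(1, c(3, 3, 4)))
  expect_equal(calibrate_reflectance(as_cube(100), refs)$data,
               array(0, c(3, 3, 4)))
  expect_equal(calibrate_reflectance(as_cube(550), refs)$data,
               array(0.5, c(3, 3, 4)))
})

test_that("calibration is invariant to a common positive rescaling", {
  g <- wavelength_grid(seq(900, 1000, length.out = 4))
  set.seed(1)
  raw <- array(runif(3 * 3 * 4, 200, 900), c(3, 3, 4))
  refs <- make_refs(3, 3, 4)
  r1 <- calibrate_reflectance(hypercube(raw, g), refs)$data
  refs2 <- reference_frames(white = 7 * refs$white, dark = 7 * refs$dark)
  r2 <- calibrate_reflectance(hypercube(7 * raw, g), refs2)$data
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("degenerate white = dark pixels are reported by location", {
  g <- wavelength_grid(seq(900, 1000, length.out = 4))
  refs <- make_refs(3, 3, 4)
  refs$white[2, 3, 1] <- refs$dark[2, 3, 1]
  cube <- hypercube(array(500, c(3, 3, 4)), g)
  expect_error(calibrate_reflectance(cube, refs),
               "line 2, sample 3, band 1")
})

test_that("scan-line references broadcast across all lines", {
  g <- wavelength_grid(seq(900, 1000, length.out = 4))
  set.seed(2)
  white_line <- array(runif(1 * 3 * 4, 900, 1100), c(1, 3, 4))
  dark_line <- array(runif(1 * 3 * 4, 50, 80), c(1, 3, 4))
  raw <- array(runif(5 * 3 * 4, 200, 800), c(5, 3, 4))
  r <- calibrate_reflectance(hypercube(raw, g),
                             reference_frames(white_line, dark_line))
  i <- 4; j <- 2; b <- 3
  expect_equal(r$data[i, j, b],
               (raw[i, j, b] - dark_line[1, j, b]) /
                 (white_line[1, j, b] - dark_line[1, j, b]))
})

test_that("mask thresholding is boundary-inclusive on the chosen statistic", {
  g <- wavelength_grid(seq(900, 1000, length.out = 4))
  data <- array(0, c(2, 2, 4))
  data[1, 1, ] <- 0.5      # included
  data[1, 2, ] <- 0.45     # boundary: included
  data[2, 1, ] <- 0.449    # excluded
  cube <- hypercube(data, g, reflectance = TRUE)
  m <- make_mask(cube, threshold = 0.45)
  expect_identical(unclass(m)[1:2, 1:2],
                   matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  expect_false(attr(m, "empty"))

  empty <- make_mask(hypercube(array(0, c(2, 2, 4)), g, reflectance = TRUE))
  expect_true(attr(empty, "empty"))
  expect_error(extract_roi_mean(hypercube(array(0, c(2, 2, 4)), g,
                                          reflectance = TRUE), empty),
               "empty ROI")
})

test_that("single-band mask statistic is available", {
  g <- wavelength_grid(seq(900, 1000, length.out = 4))
  data <- array(0.1, c(2, 2, 4))
  data[1, 1, 3] <- 0.9
  cube <- hypercube(data, g, reflectance = TRUE)
  m <- make_mask(cube, threshold = 0.45, statistic = "band", band = 3)
  expect_identical(sum(m), 1L)
})

test_that("ROI mean is the per-band arithmetic mean of masked pixels", {
  g <- wavelength_grid(seq(900, 1000, length.out = 4))
  data <- array(9, c(2, 2, 4))
  data[1, 1, ] <- c(0.2, 0.2, 0.2, 0.2)
  data[2, 1, ] <- c(0.4, 0.4, 0.4, 0.4)
  cube <- hypercube(data, g, reflectance = TRUE)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  sp <- extract_roi_mean(cube, mask)
  expect_equal(sp$values, rep(0.3, 4), ignore_attr = TRUE)
  expect_equal(sp$n_pixels, 2L)
})

test_that("a simulated scene calibrates, masks and averages back to truth", {
  cfg <- small_config(cube_noise_sd = 0)
  sim <- simulate_cube(list(lcc = 2.0, lwc = 0.6), cfg)
  refl <- calibrate_reflectance(sim$cube, sim$refs)
  m <- make_mask(refl, threshold = 0.45)
  expect_identical(unclass(m)[, ], sim$mask)
  sp <- extract_roi_mean(refl, m)
  expect_equal(sp$values, sim$spectrum, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sp$n_pixels, sum(sim$mask))
})

test_that("a background-only scene yields an empty mask and empty-ROI error", {
  cfg <- small_config()
  sim <- simulate_cube(list(lcc = 1, lwc = 0.4), cfg,
                       canopy = matrix(FALSE, 8, 8))
  refl <- calibrate_reflectance(sim$cube, sim$refs)
  m <- make_mask(refl)
  expect_true(attr(m, "empty"))
  expect_error(extract_roi_mean(refl, m), "empty ROI")
  expect_error(simulate_cube(list(lcc = 1, lwc = 0.4),
                             small_config(scene_dim = c(1L, 5L))),
               "at least 2x2")
})
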