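poly_set <- function(n_bands = 40, coefs = c(3, 2, 0.5)) {
  g <- default_grid(n_bands)
  i <- seq_len(n_bands)
  x <- coefs[1] + coefs[2] * i + coefs[3] * i^2
  spectra_set(rbind(x, 2 * x), g, ids = c("p1", "p2"))
}

test_that("SG smoothing passes polynomials up to its order unchanged", {
  ss <- poly_set()
  out <- sg_smooth(ss, window = 11, polyorder = 2, deriv = 0)
  expect_lt(max(abs(out$matrix - ss$matrix)), 1e-8)   # includes band edges
})

test_that("SG derivative of a constant spectrum is zero", {
  g <- default_grid(30)
  ss <- spectra_set(matrix(5, 1, 30), g)
  out <- sg_smooth(ss, window = 11, polyorder = 2, deriv = 1)
  expect_lt(max(abs(out$matrix)), 1e-12)
})

test_that("SG smoothing attenuates additive noise", {
  set.seed(3)
  g <- default_grid(200)
  smooth_sig <- sin(seq(0, 4 * pi, length.out = 200))
  noisy <- smooth_sig + rnorm(200, 0, 0.05)
  ss <- spectra_set(rbind(noisy), g)
  out <- sg_smooth(ss, window = 11, polyorder = 2)
  expect_lt(sd(out$matrix[1, ] - smooth_sig), sd(noisy - smooth_sig))
})

test_that("SG validates its window specification", {
  ss <- poly_set(20)
  expect_error(sg_smooth(ss, window = 4), "odd")
  expect_error(sg_smooth(ss, window = 21), "odd|exceeds")
  expect_error(sg_smooth(ss, window = 31), "exceeds")
  expect_error(sg_smooth(ss, window = 11, polyorder = 11), "polyorder")
  expect_error(sg_smooth(ss, window = 11, polyorder = 2, deriv = 3), "deriv")
})

test_that("SNV standardizes each spectrum to mean 0 and population sd 1", {
  set.seed(5)
  g <- default_grid(50)
  ss <- spectra_set(matrix(runif(4 * 50, 0.2, 0.9), 4, 50), g)
  out <- snv(ss)
  expect_equal(rowMeans(out$matrix), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sqrt(rowMeans(out$matrix^2)), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("SNV is invariant to per-spectrum affine scatter", {
  set.seed(6)
  g <- default_grid(50)
  x <- runif(50, 0.2, 0.9)
  ss <- spectra_set(rbind(x, 3 * x + 0.7), g, ids = c("a", "b"))
  out <- snv(ss)
  expect_equal(out$matrix["a", ], out$matrix["b", ], tolerance = 1e-12)
})

test_that("SNV of a two-band spectrum matches hand standardization", {
  g <- wavelength_grid(c(1000, 1100))
  out <- snv(spectra_set(rbind(c(0, 1)), g))
  # population sd of {0, 1} is 0.5, so the output is {-1, +1}
  expect_equal(out$matrix[1, ], c(-1, 1), ignore_attr = TRUE)
  expect_error(snv(spectra_set(rbind(c(0.4, 0.4)), g)), "zero-variance")
})

test_that("MSC removes affine scatter against the reference exactly", {
  set.seed(7)
  g <- default_grid(60)
  r <- 0.5 + 0.3 * sin(seq(0, pi, length.out = 60))
  ss <- spectra_set(rbind(r, 2 * r + 0.1), g, ids = c("ref", "scat"))
  out <- msc(ss, reference = r)
  expect_equal(out$matrix["ref", ], r, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(out$matrix["scat", ], r, tolerance = 1e-10, ignore_attr = TRUE)
  co <- attr(out, "coef")
  expect_equal(unname(co["ref", ]), c(1, 0), tolerance = 1e-10)
  expect_equal(unname(co["scat", ]), c(2, 0.1), tolerance = 1e-10)
})

test_that("MSC tightens equal-trait samples generated with scatter", {
  cfg <- small_config(noise_sd = 0, scatter_gain_sd = 0.08,
                      scatter_offset_sd = 0.03)
  truth <- data.frame(sample_id = sprintf("s%d", 1:8), group = "D0",
                      lcc = 1.5, lwc = 0.5)
  ss <- simulate_spectra(truth, cfg)
  before <- mean(dist(ss$matrix))
  after <- mean(dist(msc(ss)$matrix))
  expect_lt(after, before)
})

test_that("a frozen MSC reference transforms prediction data without leakage", {
  cfg <- small_config(seed = 9)
  ss <- simulate_spectra(simulate_traits(cfg), cfg)
  cal <- subset_spectra(ss, samples = ss$ids[1:20])
  prd <- subset_spectra(ss, samples = ss$ids[21:30])
  cal_m <- msc(cal)
  ref <- attr(cal_m, "reference")
  expect_equal(ref, colMeans(cal$matrix), ignore_attr = TRUE)
  p1 <- msc(prd, reference = ref)
  # transforming again with the same frozen reference is idempotent in it
  p2 <- msc(prd, reference = attr(p1, "reference"))
  expect_identical(attr(p1, "reference"), ref)
  expect_equal(p1$matrix, p2$matrix, tolerance = 1e-12)
  # dispatcher wires the frozen reference through `state`
  p3 <- apply_preprocess(prd, "msc", state = cal_m)
  expect_equal(p3$matrix, p1$matrix, tolerance = 1e-12)
})
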