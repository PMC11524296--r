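test_that("R-squared and RMSE reproduce hand-computed values", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)          # 1 - 1/2
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))   # sqrt(12.5)
  expect_equal(rmse(c(1, 5, -2), c(1, 5, -2) + 0.3), 0.3)  # constant error
})

test_that("metric edge cases raise informative errors", {
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(r_squared(1, 1), "two observations")
  expect_error(r_squared(1:3, 1:4), "length mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("metrics agree with a streaming oracle on random vectors", {
  set.seed(70)
  for (rep in 1:20) {
    n <- sample(3:50, 1)
    y <- rnorm(n); yhat <- y + rnorm(n, 0, 0.5)
    oracle <- streaming_metrics(y, yhat)
    expect_equal(r_squared(y, yhat), oracle$r2, tolerance = 1e-10)
    expect_equal(rmse(y, yhat), oracle$rmse, tolerance = 1e-10)
  }
})

test_that("the stratified split reproduces 126/54 and is seed-stable", {
  cfg <- synthetic_config(seed = 2)
  ss <- simulate_spectra(simulate_traits(cfg), cfg)
  plan <- split_calibration_prediction(ss, 0.7, seed = 11)
  expect_length(plan$calibration_ids, 126L)
  expect_length(plan$prediction_ids, 54L)
  expect_length(intersect(plan$calibration_ids, plan$prediction_ids), 0L)
  expect_setequal(c(plan$calibration_ids, plan$prediction_ids), ss$ids)
  # per-group counts within one sample of 0.7 * 36 = 25.2
  per_group <- table(ss$meta$group[ss$ids %in% plan$calibration_ids])
  expect_true(all(per_group >= 25 & per_group <= 26))
  plan2 <- split_calibration_prediction(ss, 0.7, seed = 11)
  expect_identical(plan, plan2)
  plan3 <- split_calibration_prediction(ss, 0.7, seed = 12)
  expect_false(identical(plan$calibration_ids, plan3$calibration_ids))
})

test_that("degenerate split plans are rejected where they break evaluation", {
  cfg <- small_config()
  ss <- simulate_spectra(simulate_traits(cfg), cfg)
  expect_error(split_calibration_prediction(ss, 0), "fraction")
  full <- split_calibration_prediction(ss, 1)
  expect_length(full$prediction_ids, 0L)
  expect_error(run_pipeline(ss, targets = "lcc", selectors = "full",
                            calibration_fraction = 1),
               "empty prediction set")
  # a singleton group cannot be stratified
  tiny <- subset_spectra(ss, samples = ss$ids[c(1, 7:12)])
  expect_error(split_calibration_prediction(tiny), "at least 2 samples")
})

test_that("the evaluation grid reports every requested combination", {
  cfg <- small_config(seed = 4)
  ss <- simulate_spectra(simulate_traits(cfg), cfg)
  rep <- run_pipeline(
    ss, targets = c("lcc", "lwc"), preprocess_methods = c("none", "sg"),
    selectors = c("full", "cars"), models = "plsr",
    cars_args = list(n_runs = 15, cv_folds = 5), seed = 2)
  df <- rep$report
  expect_equal(nrow(df), 2 * 2 * 2)
  expect_named(df, c("index", "preprocessing", "selector", "n_bands",
                     "model", "r2_c", "rmse_c", "r2_p", "rmse_p",
                     "status", "note"))
  expect_true(all(df$status == "ok"))
  expect_true(all(df$r2_c <= 1 & df$rmse_c >= 0, na.rm = TRUE))
  # identity selector keeps the full grid
  expect_true(all(df$n_bands[df$selector == "full"] == 64L))
  # CARS rows record the selection's size
  key <- "lcc.sg.cars"
  expect_equal(df$n_bands[df$index == "LCC" & df$preprocessing == "sg" &
                            df$selector == "cars"],
               length(rep$selections[[key]]$selected_indices))
})

test_that("a failing grid cell is reported without aborting the run", {
  cfg <- small_config(seed = 5)
  ss <- simulate_spectra(simulate_traits(cfg), cfg)
  rep <- run_pipeline(ss, targets = "lcc", preprocess_methods = "none",
                      selectors = c("spa", "full"), models = "plsr",
                      spa_args = list(k_max = 1000), seed = 1)
  df <- rep$report
  expect_identical(df$status[df$selector == "spa"], "failed")
  expect_match(df$note[df$selector == "spa"], "k_max")
  expect_identical(df$status[df$selector == "full"], "ok")
})

test_that("band selection does not catastrophically hurt prediction", {
  cfg <- small_config(seed = 6)
  ss <- simulate_spectra(simulate_traits(cfg), cfg)
  rep <- run_pipeline(ss, targets = c("lcc", "lwc"),
                      preprocess_methods = "sg",
                      selectors = c("full", "cars"), models = "plsr",
                      cars_args = list(n_runs = 25, cv_folds = 5), seed = 3)
  df <- rep$report
  for (tr in c("LCC", "LWC")) {
    full_r2 <- df$r2_p[df$index == tr & df$selector == "full"]
    sel_r2 <- df$r2_p[df$index == tr & df$selector == "cars"]
    expect_gte(sel_r2, full_r2 - 0.05)
  }
})

test_that("pipeline reports are reproducible under fixed seeds", {
  cfg <- small_config(seed = 8)
  ss <- simulate_spectra(simulate_traits(cfg), cfg)
  args <- list(ss, targets = "lwc", preprocess_methods = "sg",
               selectors = "cars", models = "plsr",
               cars_args = list(n_runs = 10, cv_folds = 5),
               split_seed = 4L, seed = 5L)
  r1 <- do.call(run_pipeline, args)
  r2 <- do.call(run_pipeline, args)
  expect_identical(r1$report, r2$report)
})

test_that("published reference wavelength lists load with expected shape", {
  ref <- reference_wavelengths()
  expect_named(ref, c("method", "trait", "wavelength_nm"))
  counts <- with(ref, table(method, trait))
  expect_equal(counts["spa", "lcc"], 10L, ignore_attr = TRUE)
  expect_equal(counts["spa", "lwc"], 13L, ignore_attr = TRUE)
  expect_equal(counts["cars", "lcc"], 53L, ignore_attr = TRUE)
  expect_equal(counts["cars", "lwc"], 29L, ignore_attr = TRUE)
  expect_true(all(ref$wavelength_nm >= 870 & ref$wavelength_nm <= 1720))
  expect_error(band_retention_pct(c(500, 900)), "outside the grid")
})
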