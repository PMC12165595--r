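make_refl <- function(grid, values, organ = "trachea") {
  spectra_set(grid, values,
              data.frame(pair_id = 1L, organ = organ,
                         acq_index = seq_len(NCOL(values))),
              stage = "reflectance")
}

test_that("wavelength lookup interpolates linearly and hits grid points exactly", {
  grid <- c(seq(530, 559, 1), 560, 562, seq(563, 590, 1))
  vals <- rep(1, length(grid))
  vals[grid == 560] <- 2; vals[grid == 562] <- 4
  s <- make_refl(grid, vals)
  expect_equal(value_at_wavelength(s, 561), 3)
  expect_equal(value_at_wavelength(s, 562), 4)   # exact hit, stored value
  expect_error(value_at_wavelength(s, 529.9), class = "airwayspec_range_error")
  expect_error(value_at_wavelength(s, 600), class = "airwayspec_range_error")
})

test_that("interpolation error on a sampled Gaussian respects the curvature bound", {
  pitch <- 0.5
  grid <- seq(500, 620, by = pitch)
  f <- function(l) exp(-(l - 561)^2 / (2 * 9^2))
  s <- make_refl(grid, f(grid))
  # |linear interp - f| <= pitch^2 / 8 * max|f''|; max|f''| = 1/sigma^2
  bound <- pitch^2 / 8 * (1 / 81)
  for (lam in c(543.25, 557.71, 561.23, 577.9)) {
    expect_lt(abs(value_at_wavelength(s, lam) - f(lam)), bound * 1.01)
  }
})

test_that("reference correction maps white to 1, dark to 0, midpoints to 0.5", {
  grid <- seq(530, 590, by = 1)
  dark <- 100 + sin(grid / 7)
  white <- dark + 900 + 10 * cos(grid / 11)
  refs <- reference_set(grid, dark, white)
  meta <- data.frame(pair_id = 1L, organ = "trachea", acq_index = 1:3)
  raw <- spectra_set(grid, cbind(white, dark, dark + 0.5 * (white - dark)), meta)
  refl <- reference_correct(raw, refs)
  expect_equal(refl$values[, 1], rep(1, length(grid)))
  expect_equal(refl$values[, 2], rep(0, length(grid)))
  expect_equal(refl$values[, 3], rep(0.5, length(grid)))
})

test_that("degenerate references are fatal in-band, flagged out-of-band", {
  grid <- seq(470, 850, by = 2)
  dark <- rep(100, length(grid))
  white <- dark + 1000
  white[grid == 800] <- dark[grid == 800] - 5   # outside the analysis band
  refs <- reference_set(grid, dark, white)
  meta <- data.frame(pair_id = 1L, organ = "trachea", acq_index = 1L)
  raw <- spectra_set(grid, matrix(500, length(grid), 1), meta)
  refl <- reference_correct(raw, refs)
  expect_true(is.nan(refl$values[grid == 800, 1]))
  expect_error(value_at_wavelength(refl, 800), class = "airwayspec_range_error")
  expect_equal(value_at_wavelength(refl, 561), 0.4)

  # in-band violation cannot even construct a reference_set
  white2 <- dark + 1000
  white2[grid == 560] <- dark[grid == 560]
  expect_error(reference_set(grid, dark, white2),
               class = "airwayspec_validation_error")
})

test_that("peak normalization pins 561 nm to one and is idempotent", {
  grid <- seq(530, 590, by = 0.7)  # 561 not on this grid
  vals <- cbind(0.8 + 0.001 * (grid - 530), rep(0.37, length(grid)))
  refl <- make_refl(grid, vals)
  norm <- peak_normalize(refl)
  expect_equal(as.numeric(value_at_wavelength(norm, 561)), c(1, 1),
               tolerance = 1e-12)
  expect_equal(norm$values[, 2], rep(1, length(grid)))  # constant -> all ones
  norm2 <- peak_normalize(norm)
  expect_equal(norm2$values, norm$values)

  bad <- make_refl(grid, matrix(-0.1, length(grid), 1))
  expect_error(peak_normalize(bad), class = "airwayspec_normalization_error")
})

test_that("a flat normalized spectrum yields the featureless vector (1, 1)", {
  grid <- seq(530, 590, by = 1)
  norm <- peak_normalize(make_refl(grid, matrix(0.6, length(grid), 1)))
  fx <- extract_features(norm)
  expect_equal(fx$r543, 1)
  expect_equal(fx$r578, 1)
  expect_identical(fx$organ, "trachea")  # metadata carried through
})

test_that("features are invariant to overall intensity scale", {
  cfg <- simulation_config(n_pairs = 1, n_per_organ = 2, seed = 3)
  sim <- simulate_cohort(cfg)
  ds <- sim$dataset
  fx <- compute_features(ds)
  for (c0 in c(0.2, 7.5)) {
    scaled <- spectra_dataset(
      spectra_set(ds$spectra$wavelength, ds$spectra$values * c0,
                  ds$spectra$meta),
      reference_set(ds$references$wavelength, ds$references$dark * c0,
                    ds$references$white * c0))
    expect_equal(compute_features(scaled)[, c("r543", "r578")],
                 fx[, c("r543", "r578")], tolerance = 1e-12)
  }
})

test_that("a deeper 543 nm trough strictly lowers r543", {
  grid <- seq(470, 850, by = 0.5)
  cfg <- simulation_config()
  shallow <- model_reflectance(grid, 0.20, 0.30, cfg)
  deep <- model_reflectance(grid, 0.30, 0.30, cfg)
  meta <- data.frame(pair_id = 1L, organ = c("trachea", "esophagus"),
                     acq_index = 1L)
  refl <- spectra_set(grid, cbind(shallow, deep), meta, stage = "reflectance")
  fx <- extract_features(peak_normalize(refl))
  expect_lt(fx$r543[2], fx$r543[1])
  # r578 moves only through the shared 561 nm renormalization (< 2%)
  expect_equal(fx$r578[2], fx$r578[1], tolerance = 0.02)
})

test_that("noiseless simulated features match the closed-form model", {
  cfg <- simulation_config(n_pairs = 1, n_per_organ = 3, seed = 5,
                           noise_rel = 0, organ_depth_sd = 0,
                           spectrum_depth_sd = 0)
  sim <- simulate_cohort(cfg)
  fx <- compute_features(sim$dataset)
  gt <- sim$ground_truth
  for (i in seq_len(nrow(fx))) {
    expected <- oracle_features(gt$d543[i], gt$d578[i])
    expect_equal(fx$r543[i], expected[["r543"]], tolerance = 1e-6)
    expect_equal(fx$r578[i], expected[["r578"]], tolerance = 1e-6)
  }
})
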