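test_that("LWC follows from fresh and dry weight", {
  expect_equal(lwc_from_weights(10, 2), 80)
  expect_equal(lwc_from_weights(4.0000, 1.0000), 75)
  expect_equal(lwc_from_weights(c(10, 4), c(2, 1)), c(80, 75))
  expect_error(lwc_from_weights(5, 5), "strictly below")
  expect_error(lwc_from_weights(5, 6), "strictly below")
  expect_error(lwc_from_weights(5, 0), "positive")
})

test_that("sampled LWC respects bounds, CV and determinism", {
  cfg <- synthetic_config(seed = 10)
  tr <- sample_lwc(cfg)
  expect_equal(nrow(tr), 154)
  expect_true(all(tr$lwc_percent >= cfg$lwc_min & tr$lwc_percent <= cfg$lwc_max))
  expect_identical(sample_lwc(cfg), tr)

  big <- synthetic_config(n = 10000, seed = 11)
  v <- sample_lwc(big)$lwc_percent
  cv <- 100 * sd(v) / mean(v)
  expect_lt(abs(cv - 4.58), 0.5)
  expect_lt(abs(mean(v) - 78.24), 0.3)
})

test_that("infeasible LWC configurations are rejected", {
  expect_error(synthetic_config(lwc_mean = 60, lwc_min = 64.94), "outside")
  expect_error(synthetic_config(lwc_min = 90, lwc_max = 70), "lwc_min")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
})

test_that("reflectance at a water band decreases with LWC", {
  cfg <- synthetic_config(noise_sd = 0)
  lo <- simulate_spectrum(70, cfg)
  hi <- simulate_spectrum(88, cfg)
  r970 <- function(sp) sp$reflectance[sp$wavelength_nm == 970]
  expect_gt(r970(lo), r970(hi))
  # and broadly across the NIR plateau (global amplitude decline)
  nir <- function(sp) mean(sp$reflectance[sp$wavelength_nm %in% 750:1100])
  expect_gt(nir(lo), nir(hi))
})

test_that("the noiseless spectrum equals the closed-form expression", {
  cfg <- synthetic_config(noise_sd = 0)
  got <- simulate_spectrum(cfg$lwc_mean, cfg)
  # independent evaluation of the documented generator formula
  wl <- cfg$grid
  vis <- 0.055 + 0.05 * exp(-0.5 * ((wl - 554) / 28)^2) -
    cfg$pigment_depths[1] * exp(-0.5 * ((wl - 460) / 40)^2) -
    cfg$pigment_depths[2] * exp(-0.5 * ((wl - 668) / 28)^2)
  shape <- vis +
    cfg$amp * (1 / (1 + exp(-(wl - 718) / 16))) *
      (0.25 + 0.75 / (1 + exp((wl - 1650) / 220)))
  absorb <- rowSums(sapply(seq_along(cfg$centers_nm), function(i) {
    cfg$depths[i] * exp(-0.5 * ((wl - cfg$centers_nm[i]) / cfg$widths_nm[i])^2)
  }))
  expect_equal(got$reflectance, shape * (1 - absorb), tolerance = 1e-12)
})

test_that("band noise has the expected half-normal mean deviation", {
  cfg <- synthetic_config(noise_sd = 0.005)
  clean <- simulate_spectrum(78, synthetic_config(noise_sd = 0))
  noisy <- simulate_spectrum(78, cfg, noise_seed = 123)
  mad <- mean(abs(noisy$reflectance - clean$reflectance))
  expect_lt(abs(mad - 0.005 * sqrt(2 / pi)), 0.0005)
})

test_that("out-of-range LWC and unphysical depths are rejected", {
  cfg <- synthetic_config(noise_sd = 0)
  expect_error(simulate_spectrum(50, cfg), "outside config bounds")
  deep <- synthetic_config(
    noise_sd = 0,
    depths = c(1.5, 1.5, 1.5, 1.5), widths_nm = c(300, 300, 300, 300)
  )
  expect_error(simulate_spectrum(78, deep), "unphysical")
})

test_that("datasets are reproducible pure functions of the config", {
  cfg <- synthetic_config(seed = 12)
  ds1 <- make_dataset(cfg)
  expect_equal(dim(spectra_matrix(ds1$spectra)), c(154, 2151))
  expect_identical(spectra_ids(ds1$spectra), ds1$traits$sample_id)
  ds2 <- make_dataset(cfg)
  expect_identical(ds1$spectra, ds2$spectra)
  expect_identical(ds1$traits, ds2$traits)
  # round-trip through the JSON config serialization
  js <- jsonlite::toJSON(unclass(cfg), digits = NA, auto_unbox = TRUE)
  cfg2 <- do.call(synthetic_config, jsonlite::fromJSON(js))
  expect_identical(make_dataset(cfg2)$spectra, ds1$spectra)
  # different seed, different data
  expect_false(identical(make_dataset(synthetic_config(seed = 13))$spectra, ds1$spectra))
})

test_that("planted index signals hit the target R-squared", {
  cfg <- synthetic_config(
    seed = 14,
    planted = list(list(form = "DVI", wavelengths = c(698, 1274))),
    planted_r2 = 0.8
  )
  ds <- make_dataset(cfg)
  idx <- two_band_index(ds$spectra, "DVI", 698, 1274)
  r2 <- cor(idx$value, ds$traits$lwc_percent)^2
  expect_gt(r2, 0.7)
  expect_lt(r2, 0.9)
  expect_identical(ds$ground_truth$planted[[1]]$wavelengths, c(698, 1274))

  expect_error(
    synthetic_config(planted = list(list(form = "DVI", wavelengths = c(698, 3000)))),
    "off-grid"
  )
})
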