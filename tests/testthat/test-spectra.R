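test_that("write/read round-trip preserves values bit-for-bit", {
  sp <- random_spectra(3, c(500, 501, 502, 503, 504), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, path)
  back <- read_spectra(path)
  expect_identical(back$wavelength_nm, sp$wavelength_nm)
  expect_equal(as.matrix(back[-1]), as.matrix(sp[-1]), tolerance = 0)
  expect_identical(spectra_ids(back), spectra_ids(sp))
})

test_that("reading rejects malformed tables and reports the offender", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,S1,S2", "500,0.4,abc", "501,0.5,0.6"), path)
  expect_error(read_spectra(path), "S2")

  writeLines(c("foo,S1", "500,0.4"), path)
  expect_error(read_spectra(path), "wavelength_nm")

  tr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,lwc_percent", "A,80", "A,75"), tr)
  expect_error(read_traits(tr), "duplicate")
})

test_that("sample alignment drops one-sided samples with a warning", {
  sp <- random_spectra(3, 500:504, seed = 2)
  traits <- tibble::tibble(sample_id = c("S1", "S2", "S9"), lwc_percent = c(80, 75, 70))
  expect_warning(out <- align_samples(sp, traits), "S3")
  expect_setequal(spectra_ids(out$spectra), c("S1", "S2"))
  expect_identical(out$traits$sample_id, spectra_ids(out$spectra))

  none <- tibble::tibble(sample_id = c("X1", "X2"), lwc_percent = c(80, 75))
  expect_error(align_samples(sp, none), "no overlapping")
})

test_that("default trimming removes the edge and water-vapour windows", {
  sp <- random_spectra(2, 350:2500, seed = 3)
  trimmed <- trim_spectra(sp)
  # integer wavelengths in 400-1354, 1445-1776, 1950-2400
  expect_equal(nrow(trimmed), 955 + 332 + 451)
  expect_equal(nrow(trimmed), 1738)
  expect_false(any(trimmed$wavelength_nm < 400 | trimmed$wavelength_nm > 2400))
  expect_false(any(trimmed$wavelength_nm >= 1355 & trimmed$wavelength_nm <= 1444))
  expect_false(any(trimmed$wavelength_nm >= 1777 & trimmed$wavelength_nm <= 1949))

  seg <- spectra_segments(trimmed)
  expect_equal(seg$start_nm, c(400, 1445, 1950))
  expect_equal(seg$end_nm, c(1354, 1776, 2400))
  expect_equal(sum(seg$n_bands), nrow(trimmed))
})

test_that("trimming is idempotent and respects non-overlapping grids", {
  sp <- random_spectra(2, 350:2500, seed = 4)
  once <- trim_spectra(sp)
  expect_identical(trim_spectra(once), once)

  inside <- random_spectra(2, 400:1300, seed = 5)
  expect_identical(trim_spectra(inside), inside)

  gone <- random_spectra(2, 1800:1900, seed = 6)
  expect_error(trim_spectra(gone), "empty spectra")
})

test_that("morphological smoothing matches hand-evaluated cases", {
  # constant signal is a fixed point
  expect_equal(morph_smooth(rep(0.4, 9), 3), rep(0.4, 9))

  # single upward spike on a flat baseline: opening removes it, closing
  # keeps it, so the average halves the amplitude
  spike <- c(0.2, 0.2, 0.2, 0.2 + 0.01, 0.2, 0.2, 0.2)
  sm <- morph_smooth(spike, 3)
  expect_equal(sm[4], 0.2 + 0.005)
  expect_equal(sm[-4], rep(0.2, 6))

  # monotone ramp: unchanged except <= (width-1)/2 samples at each edge
  ramp <- seq(0.1, 0.9, length.out = 21)
  sm <- morph_smooth(ramp, 7)
  interior <- 4:18
  expect_equal(sm[interior], ramp[interior])
})

test_that("smoothed output stays within the rolling min/max envelope", {
  set.seed(8)
  for (width in c(3, 5, 7)) {
    x <- runif(60)
    sm <- morph_smooth(x, width)
    lo <- lwcspec:::roll_extreme(x, width, min)
    hi <- lwcspec:::roll_extreme(x, width, max)
    expect_true(all(sm >= lo - 1e-12 & sm <= hi + 1e-12))
  }
})

test_that("smoothing validates width and segment length", {
  expect_error(morph_smooth(runif(10), 4), "odd")
  expect_error(morph_smooth(runif(5), 7), "exceeds")
  sp <- random_spectra(2, c(500:520, 600:604), seed = 9) # segments 21 + 5
  expect_error(smooth_spectra(sp, 7), "shortest segment")
  expect_silent(sm <- smooth_spectra(sp, 5))
  expect_equal(dim(sm), dim(sp))
})

test_that("resampling interpolates onto the integer grid", {
  sp <- toy_spectra(c(0.2, 0.4, 0.6, 0.3, 0.5, 0.7), c(500, 502, 504))
  # 2 nm input spacing: odd wavelengths are linear interpolants
  rs <- resample_spectra(sp, 500:504)
  expect_equal(rs$wavelength_nm, 500:504)
  expect_equal(rs$S1, c(0.2, 0.3, 0.4, 0.5, 0.6))
})

test_that("group averaging collapses repeated scans", {
  sp <- toy_spectra(c(0.2, 0.4, 0.4, 0.6, 1.0, 1.0), c(500, 501))
  avg <- average_spectra(sp, c("a", "a", "b"))
  expect_equal(sort(spectra_ids(avg)), c("a", "b"))
  expect_equal(avg$a, c(0.3, 0.5))
  expect_equal(avg$b, c(1.0, 1.0))
})
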