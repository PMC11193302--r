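test_that("pearson_r matches a from-scratch covariance oracle", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 4)), "constant")
  expect_error(pearson_r(c(1, 2, NA, NA), c(1, 2, 3, 4)), ">= 3")
})

test_that("critical_r inverts the t test", {
  # table value for alpha = 0.05, df = 2
  expect_equal(critical_r(0.05, 4), 0.950, tolerance = 5e-4)
  # threshold vanishes as alpha -> 1 and grows as alpha shrinks
  expect_lt(critical_r(0.999999, 20), 1e-4)
  expect_gt(critical_r(0.001, 20), critical_r(0.05, 20))
  # at n = 154 the 0.01-level threshold is 0.2074, not the 0.201
  # sometimes quoted (that value corresponds to n near 165)
  expect_equal(critical_r(0.01, 154), 0.20700, tolerance = 1e-4)
  expect_lt(abs(critical_r(0.01, 164) - 0.201), 5e-4)
  expect_error(critical_r(0.01, 3), ">= 4")
  expect_error(critical_r(1.2, 30), "alpha")
})

test_that("corr_1d finds a self-correlated band and screens monotonically", {
  sp <- random_spectra(30, c(960, 970, 980, 990), seed = 31)
  traits <- tibble::tibble(
    sample_id = spectra_ids(sp),
    lwc_percent = as.numeric(as.matrix(sp[sp$wavelength_nm == 970, -1]))
  )
  scr <- corr_1d(sp, traits)
  expect_equal(scr$r[scr$wavelength_nm == 970], 1)
  # stricter alpha selects a subset of the looser screen
  loose <- corr_1d(sp, traits, alpha = 0.05)
  strict <- corr_1d(sp, traits, alpha = 0.01)
  expect_true(all(
    scr$wavelength_nm[strict$significant] %in% scr$wavelength_nm[loose$significant]
  ))
})

test_that("corr_1d over a stack reports per-order summaries", {
  sp <- random_spectra(20, 500:540, seed = 32)
  traits <- random_traits(spectra_ids(sp), seed = 33)
  stack <- fod_stack(sp, c(0, 0.8))
  tbl <- corr_1d(stack, traits)
  expect_setequal(unique(tbl$order), c(0, 0.8))
  summ <- corr_1d_summary(tbl)
  expect_equal(nrow(summ), 2)
  expect_true(all(summ$max_abs_r <= 1))
})

test_that("two-band maps equal the brute-force oracle including tie-breaks", {
  wl <- seq(500, 590, by = 10)
  sp <- random_spectra(25, wl, seed = 41)
  traits <- random_traits(spectra_ids(sp), seed = 42)
  for (form in c("RVI", "NDVI", "DVI")) {
    got <- corr_map_2d(sp, traits, form)
    oracle <- oracle_scan_2d(sp, traits, form)
    merged <- merge(got$map, oracle$map, by = c("lambda1", "lambda2"),
                    suffixes = c("_got", "_oracle"))
    expect_equal(nrow(merged), length(wl)^2 - length(wl))
    expect_lt(max(abs(merged$r_got - merged$r_oracle), na.rm = TRUE), 1e-12)
    expect_identical(is.na(merged$r_got), is.na(merged$r_oracle))
    expect_equal(got$best$lambda1, oracle$best$lambda1)
    expect_equal(got$best$lambda2, oracle$best$lambda2)
    expect_equal(got$best$r, oracle$best$r, tolerance = 1e-12)
  }
})

test_that("DVI maps are antisymmetric and ties resolve lexicographically", {
  sp <- random_spectra(15, seq(700, 740, by = 10), seed = 43)
  traits <- random_traits(spectra_ids(sp), seed = 44)
  m <- corr_map_2d(sp, traits, "DVI")$map
  swapped <- merge(m, m, by.x = c("lambda1", "lambda2"), by.y = c("lambda2", "lambda1"))
  expect_equal(swapped$r.x, -swapped$r.y, tolerance = 1e-14)
  # the reported best of an antisymmetric pair is the lexicographically
  # smaller ordered pair
  best <- corr_map_2d(sp, traits, "DVI")$best
  twin_r <- m$r[m$lambda1 == best$lambda2 & m$lambda2 == best$lambda1]
  expect_equal(abs(twin_r), abs(best$r))
  expect_true(best$lambda1 < best$lambda2)
})

test_that("three-band searches equal the brute-force oracle on a toy grid", {
  wl <- seq(500, 570, by = 10)
  sp <- random_spectra(20, wl, seed = 45)
  traits <- random_traits(spectra_ids(sp), seed = 46)
  for (form in paste0("3BI-", 1:7)) {
    got <- corr_search_3d(sp, traits, form,
      range = range(wl), stride = 10, refine = FALSE, keep_map = TRUE
    )
    oracle <- oracle_scan_3d(sp, traits, form)
    expect_equal(got$lambda1, oracle$lambda1)
    expect_equal(got$lambda2, oracle$lambda2)
    expect_equal(got$lambda3, oracle$lambda3)
    expect_equal(got$r, oracle$r, tolerance = 1e-12)
    map <- attr(got, "map")
    expect_equal(nrow(map), length(wl)^3)
    expect_true(all(abs(map$r) <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("searches respect strides, ranges and degenerate inputs", {
  sp <- random_spectra(12, 500:520, seed = 47)
  traits <- random_traits(spectra_ids(sp), seed = 48)
  expect_error(corr_search_3d(sp, traits, "3BI-1", range = c(500, 520), stride = 30),
    "fewer than 3")
  expect_error(corr_map_2d(sp, traits, "DVI", range = c(900, 950)), "does not overlap")
  # constant trait is rejected up-front
  const <- tibble::tibble(sample_id = spectra_ids(sp), lwc_percent = rep(80, 12))
  expect_error(corr_1d(sp, const), "constant")
})

test_that("pairwise deletion matches the oracle when samples are degenerate", {
  wl <- c(500, 510, 520, 530)
  set.seed(49)
  vals <- matrix(runif(4 * 30, 0.1, 0.9), nrow = 30)
  vals[1:6, 2] <- 0 # RVI with lambda2 = 510 degenerate for 6 samples
  sp <- as_spectra(vals, wavelengths = wl)
  traits <- random_traits(spectra_ids(sp), seed = 50)
  got <- corr_map_2d(sp, traits, "RVI", min_valid = 10)
  oracle <- oracle_scan_2d(sp, traits, "RVI", min_valid = 10L)
  merged <- merge(got$map, oracle$map, by = c("lambda1", "lambda2"))
  expect_lt(max(abs(merged$r.x - merged$r.y), na.rm = TRUE), 1e-12)
  n_at <- got$map$n_valid[got$map$lambda2 == 510 & got$map$lambda1 != 510]
  expect_true(all(n_at == 24))
})

test_that("maps are invariant to sample order and trait affine rescaling", {
  wl <- seq(600, 650, by = 10)
  sp <- random_spectra(18, wl, seed = 51)
  traits <- random_traits(spectra_ids(sp), seed = 52)
  base <- corr_map_2d(sp, traits, "NDVI")$map
  perm <- sample(seq_along(spectra_ids(sp)))
  sp_perm <- sp[c("wavelength_nm", spectra_ids(sp)[perm])]
  affine <- traits
  affine$lwc_percent <- 3.7 * affine$lwc_percent - 12
  again <- corr_map_2d(sp_perm, affine, "NDVI")$map
  expect_equal(base$r, again$r, tolerance = 1e-12)
})

test_that("permutation screening is calibrated to alpha", {
  sp <- random_spectra(60, seq(400, 1200, by = 10), seed = 53)
  traits <- random_traits(spectra_ids(sp), seed = 54)
  out <- screen_permutation_test(sp, traits, alpha = 0.05, n_perm = 100, seed = 55)
  B <- length(sp$wavelength_nm)
  tol3sigma <- 3 * sqrt(B * 0.05 * 0.95)
  expect_lt(abs(mean(out$n_significant) - 0.05 * B), tol3sigma)
})
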