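# fixture builders shared across test files

# small wide spectra tibble from an explicit samples x bands matrix
toy_spectra <- function(values, wavelengths, ids = NULL) {
  values <- matrix(values, ncol = length(wavelengths), byrow = TRUE)
  as_spectra(values,
    wavelengths = wavelengths,
    sample_ids = ids %||% paste0("S", seq_len(nrow(values)))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random smooth-ish spectra on an arbitrary grid, seeded
random_spectra <- function(n_samples, wavelengths, seed = 1) {
  set.seed(seed)
  vals <- matrix(runif(n_samples * length(wavelengths), 0.05, 0.9),
    nrow = n_samples
  )
  as_spectra(vals, wavelengths = wavelengths)
}

random_traits <- function(ids, seed = 1) {
  set.seed(seed)
  tibble::tibble(sample_id = ids, lwc_percent = runif(length(ids), 65, 92))
}

# small, fast synthetic configuration: short grid, fewer samples
small_config <- function(seed = 1, ...) {
  synthetic_config(
    n = 40, grid = 400:1350,
    centers_nm = c(970, 1200), widths_nm = c(35, 45),
    depths = c(0.08, 0.09), depth_slopes = c(0.0056, 0.005),
    seed = seed, ...
  )
}

# pure-R brute-force two-band scan: the independent oracle for cpp_search_2d
oracle_scan_2d <- function(spectra, traits, form, eps = 1e-10, min_valid = 10L) {
  wl <- spectra$wavelength_nm
  y <- traits$lwc_percent[match(spectra_ids(spectra), traits$sample_id)]
  best <- NULL
  rows <- list()
  for (l1 in wl) {
    for (l2 in wl) {
      if (l1 == l2) next
      tbl <- two_band_index(spectra, form, l1, l2, eps = eps)
      ok <- tbl$valid & is.finite(tbl$value)
      r <- if (sum(ok) >= min_valid && sd(tbl$value[ok]) > 0 && sd(y[ok]) > 0) {
        cor(tbl$value[ok], y[ok])
      } else {
        NA_real_
      }
      rows[[length(rows) + 1L]] <-
        data.frame(lambda1 = l1, lambda2 = l2, r = r, n_valid = sum(ok))
      if (!is.na(r) && (is.null(best) || abs(r) > abs(best$r) + 1e-12)) {
        best <- data.frame(lambda1 = l1, lambda2 = l2, r = r, n_valid = sum(ok))
      }
    }
  }
  list(map = do.call(rbind, rows), best = best)
}

# pure-R brute-force three-band scan
oracle_scan_3d <- function(spectra, traits, form, eps = 1e-10, min_valid = 10L) {
  wl <- spectra$wavelength_nm
  y <- traits$lwc_percent[match(spectra_ids(spectra), traits$sample_id)]
  best <- NULL
  for (l1 in wl) for (l2 in wl) for (l3 in wl) {
    if (l1 == l2 || l1 == l3 || l2 == l3) next
    tbl <- three_band_index(spectra, form, l1, l2, l3, eps = eps)
    ok <- tbl$valid & is.finite(tbl$value)
    if (sum(ok) < min_valid) next
    if (sd(tbl$value[ok]) == 0 || sd(y[ok]) == 0) next
    r <- cor(tbl$value[ok], y[ok])
    if (is.null(best) || abs(r) > abs(best$r) + 1e-12) {
      best <- data.frame(
        lambda1 = l1, lambda2 = l2, lambda3 = l3,
        r = r, n_valid = sum(ok)
      )
    }
  }
  best
}

# Gamma closed form for the G-L weights, the independent oracle for the
# multiplicative recurrence; negative arguments are handled through the
# reflection identity via lgamma plus an explicit sign, and the poles at
# nonpositive integers give weight 0 (lgamma -> Inf)
gl_weights_gamma <- function(v, M) {
  vapply(0:M, function(m) {
    z <- v - m + 1
    lg <- lgamma(v + 1) - lgamma(m + 1) - suppressWarnings(lgamma(z))
    s <- if (z > 0 || z == floor(z)) 1 else (-1)^ceiling(-z)
    (-1)^m * s * exp(lg)
  }, numeric(1))
}
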