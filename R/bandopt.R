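#' Pearson correlation with pairwise deletion
#'
#' Product-moment correlation after dropping pairs with non-finite entries.
#' Degenerate inputs (fewer than 3 complete pairs, or a constant vector) are
#' an error: in the band searches such combinations are *excluded* rather
#' than propagated as NaN.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_lwc("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop_lwc("need >= 3 complete pairs, got %d", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_lwc("constant input: correlation undefined")
  stats::cor(x, y)
}

#' Two-tailed critical correlation at significance level alpha
#'
#' Inverts the t-test of a Pearson coefficient: with `n` samples the
#' statistic \eqn{t = r\sqrt{(n-2)/(1-r^2)}} has `n - 2` degrees of freedom,
#' so the critical value is \eqn{r_c = t_c / \sqrt{t_c^2 + n - 2}} with
#' \eqn{t_c} the two-tailed t quantile. Note: some field studies print a
#' slightly different threshold for their stated n (e.g. 0.201 at the 0.01
#' level, which corresponds to n of about 165 rather than 154); this
#' function always computes from the actual `n`.
#'
#' @param alpha two-tailed significance level in (0, 1).
#' @param n number of samples, `>= 4`.
#' @return critical `|r|` threshold.
#' @export
critical_r <- function(alpha, n) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop_lwc("alpha must be in (0, 1)")
  n <- as.integer(n)
  if (is.na(n) || n < 4L) stop_lwc("n must be >= 4")
  tc <- stats::qt(1 - alpha / 2, df = n - 2L)
  tc / sqrt(tc^2 + n - 2L)
}

#' Per-band correlation between spectra and a trait
#'
#' Computes the Pearson correlation of every band's (possibly derivative)
#' reflectance with the trait and flags bands whose `|r|` reaches the
#' critical value at level `alpha`. Applied to an [fod_stack()], the result
#' carries an `order` column; see [corr_1d_summary()] for the per-order
#' maximum `|r|` and significant-band counts.
#'
#' @param x spectra tibble or `fod_stack`.
#' @param traits trait tibble aligned to the spectra sample ids.
#' @param alpha significance level for the screen (default 0.01).
#' @return tibble `wavelength_nm, r, n, significant` (plus `order` for a
#'   stack). Bands with undefined correlation (constant reflectance) have
#'   `r = NA` and `significant = FALSE`.
#' @export
corr_1d <- function(x, traits, alpha = 0.01) {
  if (inherits(x, "fod_stack")) {
    return(purrr::map2_dfr(
      x, attr(x, "orders"),
      function(sp, v) dplyr::mutate(corr_1d(sp, traits, alpha), order = v, .before = 1)
    ))
  }
  y <- align_trait_values(x, traits)
  X <- spectra_matrix(x)
  sds <- apply(X, 2, stats::sd)
  r <- rep(NA_real_, ncol(X))
  if (stats::sd(y) == 0) stop_lwc("trait is constant: correlation undefined")
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], y))
  crit <- critical_r(alpha, length(y))
  tibble::tibble(
    wavelength_nm = x$wavelength_nm,
    r = r,
    n = length(y),
    significant = !is.na(r) & abs(r) >= crit
  )
}

#' @rdname corr_1d
#' @param tbl output of `corr_1d()` on a stack.
#' @export
corr_1d_summary <- function(tbl) {
  grp <- if ("order" %in% names(tbl)) "order" else character()
  dplyr::summarise(
    dplyr::group_by(tbl, dplyr::across(dplyr::all_of(grp))),
    max_abs_r = max(abs(.data$r), na.rm = TRUE),
    n_significant = sum(.data$significant),
    .groups = "drop"
  )
}

align_trait_values <- function(spectra, traits) {
  ids <- spectra_ids(spectra)
  pos <- match(ids, traits$sample_id)
  if (anyNA(pos)) stop_lwc("traits missing sample(s): %s", paste(ids[is.na(pos)], collapse = ", "))
  y <- traits$lwc_percent[pos]
  if (any(!is.finite(y))) stop_lwc("trait values must be finite")
  y
}

strided_bands <- function(wavelengths, range, stride) {
  lo <- max(min(wavelengths), range[1])
  hi <- min(max(wavelengths), range[2])
  if (lo > hi) stop_lwc("search range [%g, %g] does not overlap the grid", range[1], range[2])
  cand <- intersect(seq(lo, hi, by = stride), wavelengths)
  if (!length(cand)) stop_lwc("no grid wavelengths at stride %g within [%g, %g]", stride, range[1], range[2])
  cand
}

form_code_2d <- function(form) match(form, TWO_BAND_FORMS) - 1L
form_code_3d <- function(form) match(form, THREE_BAND_FORMS) - 1L

#' Exhaustive two-band correlation map
#'
#' Evaluates a two-band index form at every ordered pair of distinct
#' wavelengths on a strided grid and correlates it with the trait. The best
#' combination is the `argmax |r|` over valid pairs, ties broken by the
#' lexicographically smallest `(lambda1, lambda2)` (the scan order). Pairs
#' whose index is degenerate for too many samples (`n_valid < min_valid`)
#' are excluded.
#'
#' @inheritParams corr_1d
#' @param spectra spectra tibble (raw or FOD-transformed).
#' @param form `"RVI"`, `"NDVI"` or `"DVI"`.
#' @param range length-2 wavelength window in nm; default the full grid.
#' @param stride grid stride in nm (default 1).
#' @param eps denominator degeneracy guard.
#' @param min_valid minimum contributing samples per pair.
#' @param keep_map store the full map (long tibble) in the result.
#' @return object of class `"corr_map"`: list with `best` (one-row tibble
#'   `form, lambda1, lambda2, r, n_valid, significant`) and, if kept, `map`
#'   (`lambda1, lambda2, r, n_valid`).
#' @export
corr_map_2d <- function(spectra, traits, form, range = NULL, stride = 1,
                        alpha = 0.01, eps = 1e-10, min_valid = 10L,
                        keep_map = TRUE) {
  form <- match.arg(form, TWO_BAND_FORMS)
  if (stride < 1) stop_lwc("stride must be >= 1 nm")
  y <- align_trait_values(spectra, traits)
  wl <- spectra$wavelength_nm
  range <- range %||% range(wl)
  bands <- strided_bands(wl, range, stride)
  if (length(bands) < 2L) stop_lwc("no valid pairs: fewer than 2 bands in the search range")
  idx <- match(bands, wl)
  res <- cpp_search_2d(
    spectra_matrix(spectra), y, idx, idx, as.numeric(bands), as.numeric(bands),
    form_code_2d(form), eps, as.integer(min_valid), keep_map
  )
  if (res$best_i < 1) stop_lwc("all band pairs invalid for form %s", form)
  best <- tibble::tibble(
    form = form,
    lambda1 = bands[res$best_i],
    lambda2 = bands[res$best_j],
    r = res$best_r,
    n_valid = res$best_n,
    significant = abs(res$best_r) >= critical_r(alpha, res$best_n)
  )
  out <- list(best = best, form = form, alpha = alpha, stride = stride, bands = bands)
  if (keep_map) {
    out$map <- tibble::tibble(
      lambda1 = rep(bands, each = length(bands)),
      lambda2 = rep(bands, times = length(bands)),
      r = as.numeric(t(res$map_r)),
      n_valid = as.numeric(t(res$map_n))
    )
  }
  structure(out, class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "2-band scan, form %s, %d bands (stride %g nm)\nbest: %s(%d, %d)  r = %.4f  (n = %d)\n",
    x$form, length(x$bands), x$stride, b$form, b$lambda1, b$lambda2, b$r, b$n_valid
  ))
  invisible(x)
}

#' @export
tidy.corr_map <- function(x, ...) {
  if (is.null(x$map)) stop_lwc("map was not stored; rerun with keep_map = TRUE")
  x$map
}

#' Exhaustive three-band correlation search
#'
#' Scans all ordered triples of pairwise-distinct wavelengths on a strided
#' grid for a three-band index form, maximizing `|r|` with the trait
#' (lexicographic tie-break, scan order). With `refine = TRUE` the coarse
#' optimum is re-searched at 1 nm within `stride` nm of each selected band.
#' The 3-D map is streamed (running best only) unless `keep_map = TRUE`,
#' which is supported for small grids only.
#'
#' @inheritParams corr_map_2d
#' @param form one of `"3BI-1"` .. `"3BI-7"`.
#' @param range search window, default 400--1300 nm.
#' @param stride coarse stride in nm, default 5.
#' @param refine logical: 1 nm local refinement around the coarse optimum.
#' @return object of class `"band_combo"`: one-row tibble
#'   `form, lambda1, lambda2, lambda3, r, n_valid, significant`, with the
#'   coarse best and (optionally) the full coarse map as attributes.
#' @export
corr_search_3d <- function(spectra, traits, form, range = c(400, 1300),
                           stride = 5, refine = TRUE, alpha = 0.01,
                           eps = 1e-10, min_valid = 10L, keep_map = FALSE) {
  form <- match.arg(form, THREE_BAND_FORMS)
  if (stride < 1) stop_lwc("stride must be >= 1 nm")
  y <- align_trait_values(spectra, traits)
  wl <- spectra$wavelength_nm
  bands <- strided_bands(wl, range, stride)
  if (length(bands) < 3L) stop_lwc("no valid triples: fewer than 3 bands in the search range")
  X <- spectra_matrix(spectra)
  code <- form_code_3d(form)
  idx <- match(bands, wl)
  run <- function(b1, b2, b3, keep) {
    cpp_search_3d(
      X, y, match(b1, wl), match(b2, wl), match(b3, wl),
      as.numeric(b1), as.numeric(b2), as.numeric(b3),
      code, eps, as.integer(min_valid), keep
    )
  }
  res <- run(bands, bands, bands, keep_map)
  if (res$best_i < 1) stop_lwc("all band triples invalid for form %s", form)
  coarse <- c(bands[res$best_i], bands[res$best_j], bands[res$best_k])
  best_r <- res$best_r
  best_wl <- coarse
  best_n <- res$best_n
  if (refine) {
    local <- lapply(coarse, function(w) {
      b <- intersect((w - stride):(w + stride), wl)
      b[b >= range[1] & b <= range[2]]
    })
    ref <- run(local[[1]], local[[2]], local[[3]], FALSE)
    if (ref$best_i >= 1 && abs(ref$best_r) > abs(best_r) + 1e-12) {
      best_wl <- c(local[[1]][ref$best_i], local[[2]][ref$best_j], local[[3]][ref$best_k])
      best_r <- ref$best_r
      best_n <- ref$best_n
    }
  }
  out <- tibble::tibble(
    form = form,
    lambda1 = best_wl[1], lambda2 = best_wl[2], lambda3 = best_wl[3],
    r = best_r,
    n_valid = best_n,
    significant = abs(best_r) >= critical_r(alpha, best_n)
  )
  attr(out, "coarse") <- tibble::tibble(
    lambda1 = coarse[1], lambda2 = coarse[2], lambda3 = coarse[3], r = res$best_r
  )
  if (keep_map) {
    nb <- length(bands)
    attr(out, "map") <- tibble::tibble(
      lambda1 = rep(bands, times = nb * nb),
      lambda2 = rep(rep(bands, each = nb), times = nb),
      lambda3 = rep(bands, each = nb * nb),
      r = res$map_r,
      n_valid = res$map_n
    )
  }
  class(out) <- c("band_combo", class(out))
  out
}

#' Permutation calibration of the significance screen
#'
#' Repeatedly permutes the trait, recomputes the per-band correlation screen
#' and counts bands passing `|r| >= critical_r(alpha, n)`. Under the null the
#' mean significant fraction should match `alpha`.
#'
#' @inheritParams corr_1d
#' @param spectra spectra tibble.
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @return tibble with one row per permutation: `perm, n_significant, fraction`.
#' @export
screen_permutation_test <- function(spectra, traits, alpha = 0.01,
                                    n_perm = 200L, seed = 1L) {
  y <- align_trait_values(spectra, traits)
  X <- scale(spectra_matrix(spectra))
  n <- length(y)
  crit <- critical_r(alpha, n)
  counts <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      yp <- as.numeric(scale(sample(y)))
      r <- as.numeric(crossprod(X, yp)) / (n - 1)
      sum(abs(r) >= crit, na.rm = TRUE)
    }, numeric(1))
  })
  tibble::tibble(
    perm = seq_len(n_perm),
    n_significant = counts,
    fraction = counts / ncol(X)
  )
}
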