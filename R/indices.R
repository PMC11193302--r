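#' Spectral index catalogue
#'
#' Two families of indices are supported:
#'
#' * **Fixed moisture indices (MIs)** — twelve literature two-band water
#'   indices with fixed wavelengths (WI, WBI, FWBI, SRWI-1/2, MSI, MSI-1,
#'   NDI-1, NDVI, NDWI, NDWI-Hyp, NDMI), always computed from raw (order-0,
#'   trimmed, smoothed) reflectance.
#' * **Optimization forms** — generic two-band forms (`RVI = R1/R2`,
#'   `NDVI = (R1-R2)/(R1+R2)`, `DVI = R1-R2`) and seven three-band forms
#'   (`3BI-1` .. `3BI-7`) whose wavelengths are free and chosen by
#'   correlation optimization ([corr_map_2d()], [corr_search_3d()]).
#'
#' Samples whose denominator magnitude falls below `eps` are flagged
#' `valid = FALSE` rather than dropped, and are excluded pairwise from
#' downstream correlations.
#'
#' @name index-catalogue
NULL

TWO_BAND_FORMS <- c("RVI", "NDVI", "DVI")
THREE_BAND_FORMS <- paste0("3BI-", 1:7)

#' The twelve fixed moisture-index definitions
#'
#' @return tibble with columns `index_name`, `formula` (display string) and
#'   `wavelengths_nm` (list column).
#' @export
moisture_index_catalog <- function() {
  tibble::tribble(
    ~index_name, ~formula, ~wavelengths_nm,
    "WI", "R900/R970", c(900, 970),
    "WBI", "R970/R900", c(970, 900),
    "FWBI", "R900/min(R930..R980)", c(900, 930:980),
    "SRWI-1", "R858/R1240", c(858, 1240),
    "SRWI-2", "R1070/R1340", c(1070, 1340),
    "MSI", "R1600/R820", c(1600, 820),
    "MSI-1", "R870/R1350", c(870, 1350),
    "NDI-1", "(R850-R1650)/(R850+R1650)", c(850, 1650),
    "NDVI", "(R858-R648)/(R858+R648)", c(858, 648),
    "NDWI", "(R858-R2130)/(R858+R2130)", c(858, 2130),
    "NDWI-Hyp", "(R1070-R1200)/(R1070+R1200)", c(1070, 1200),
    "NDMI", "(R1649-R1722)/(R1649+R1722)", c(1649, 1722)
  )
}

# reflectance row-vector(s) at given wavelengths; errors when off-grid
reflectance_at <- function(spectra, wl, context = "index") {
  pos <- match(wl, spectra$wavelength_nm)
  if (anyNA(pos)) {
    stop_lwc(
      "%s: wavelength(s) %s not on the grid",
      context, paste(wl[is.na(pos)], collapse = ", ")
    )
  }
  m <- as.matrix(spectra[pos, -1, drop = FALSE])
  rownames(m) <- wl
  m
}

index_values_tbl <- function(spectra, name, value, valid) {
  tibble::tibble(
    sample_id = spectra_ids(spectra),
    index_name = name,
    value = unname(ifelse(valid, value, NA_real_)),
    valid = unname(valid)
  )
}

#' Compute the twelve fixed moisture indices
#'
#' Evaluates the full moisture-index catalogue on a raw reflectance table.
#' All required wavelengths must be on the grid; missing ones produce an
#' error naming the uncomputable indices.
#'
#' @inheritParams validate_spectra
#' @param eps denominator degeneracy guard.
#' @return long tibble `sample_id, index_name, value, valid` with 12 indices
#'   per sample.
#' @export
moisture_indices <- function(spectra, eps = 1e-10) {
  cat <- moisture_index_catalog()
  missing <- purrr::map_lgl(cat$wavelengths_nm, function(wl) {
    !all(wl %in% spectra$wavelength_nm)
  })
  if (any(missing)) {
    stop_lwc(
      "grid lacks wavelengths for: %s",
      paste(cat$index_name[missing], collapse = ", ")
    )
  }
  R <- function(wl) as.numeric(reflectance_at(spectra, wl))
  ratio <- function(a, b) {
    valid <- abs(b) >= eps
    index_list(ifelse(valid, a / b, NA_real_), valid)
  }
  ndiff <- function(a, b) ratio(a - b, a + b)
  fwbi_min <- apply(reflectance_at(spectra, 930:980), 2, min)
  defs <- list(
    "WI" = ratio(R(900), R(970)),
    "WBI" = ratio(R(970), R(900)),
    "FWBI" = ratio(R(900), fwbi_min),
    "SRWI-1" = ratio(R(858), R(1240)),
    "SRWI-2" = ratio(R(1070), R(1340)),
    "MSI" = ratio(R(1600), R(820)),
    "MSI-1" = ratio(R(870), R(1350)),
    "NDI-1" = ndiff(R(850), R(1650)),
    "NDVI" = ndiff(R(858), R(648)),
    "NDWI" = ndiff(R(858), R(2130)),
    "NDWI-Hyp" = ndiff(R(1070), R(1200)),
    "NDMI" = ndiff(R(1649), R(1722))
  )
  purrr::imap_dfr(defs, function(d, nm) index_values_tbl(spectra, nm, d$value, d$valid))
}

index_list <- function(value, valid) list(value = value, valid = valid)

# core two-band arithmetic shared by the tibble interface and the searches
eval_two_band <- function(r1, r2, form, eps = 1e-10) {
  switch(form,
    RVI = index_list(ifelse(abs(r2) >= eps, r1 / r2, NA_real_), abs(r2) >= eps),
    NDVI = {
      den <- r1 + r2
      index_list(ifelse(abs(den) >= eps, (r1 - r2) / den, NA_real_), abs(den) >= eps)
    },
    DVI = index_list(r1 - r2, rep(TRUE, length(r1))),
    stop_lwc("unknown two-band form '%s'", form)
  )
}

# core three-band arithmetic for 3BI-1 .. 3BI-7
eval_three_band <- function(r1, r2, r3, form, eps = 1e-10) {
  guard <- function(num, den) {
    ok <- abs(den) >= eps
    index_list(ifelse(ok, num / den, NA_real_), ok)
  }
  switch(form,
    "3BI-1" = guard(r1, r2 * r3),
    "3BI-2" = guard(r1, r2 + r3),
    "3BI-3" = guard(r1 - r2, r2 + r3),
    "3BI-4" = guard(r1 - r2, r2 - r3),
    "3BI-5" = guard(r2 + r3, r1),
    "3BI-6" = guard(r1 - r2, (r1 - r2) - (r2 - r3)),
    "3BI-7" = index_list((r1 - r2) - (r2 - r3), rep(TRUE, length(r1))),
    stop_lwc("unknown three-band form '%s'", form)
  )
}

#' Two-band optimization-form index
#'
#' @inheritParams moisture_indices
#' @param form one of `"RVI"`, `"NDVI"`, `"DVI"`.
#' @param lambda1,lambda2 wavelengths in nm, on the grid.
#' @return tibble `sample_id, index_name, value, valid`.
#' @export
two_band_index <- function(spectra, form, lambda1, lambda2, eps = 1e-10) {
  form <- match.arg(form, TWO_BAND_FORMS)
  R <- reflectance_at(spectra, c(lambda1, lambda2), context = form)
  d <- eval_two_band(R[1, ], R[2, ], form, eps)
  index_values_tbl(spectra, sprintf("%s(%d,%d)", form, lambda1, lambda2), d$value, d$valid)
}

#' Three-band optimization-form index
#'
#' @inheritParams two_band_index
#' @param form one of `"3BI-1"` .. `"3BI-7"`.
#' @param lambda1,lambda2,lambda3 pairwise-distinct wavelengths in nm.
#' @return tibble `sample_id, index_name, value, valid`.
#' @export
three_band_index <- function(spectra, form, lambda1, lambda2, lambda3, eps = 1e-10) {
  form <- match.arg(form, THREE_BAND_FORMS)
  wl <- c(lambda1, lambda2, lambda3)
  if (anyDuplicated(wl)) stop_lwc("%s: wavelengths must be pairwise distinct", form)
  R <- reflectance_at(spectra, wl, context = form)
  d <- eval_three_band(R[1, ], R[2, ], R[3, ], form, eps)
  index_values_tbl(
    spectra, sprintf("%s(%d,%d,%d)", form, lambda1, lambda2, lambda3),
    d$value, d$valid
  )
}
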