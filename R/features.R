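#' Band optimization and feature assembly for the model grid
#'
#' `optimize_lwc_features()` performs every selection step of the workflow on
#' the *calibration* samples only (leakage-safe): the single-band
#' significance screens on the raw and FOD spectra, the two-band index
#' optimizations on raw and FOD reflectance, and the seven three-band index
#' optimizations on the selected FOD order within the three-band window.
#' `assemble_features()` then materializes any of the nine feature matrices
#' for *all* samples from the stored selections.
#'
#' The nine feature-set kinds are:
#'
#' | kind                  | columns                                             |
#' |-----------------------|-----------------------------------------------------|
#' | `raw_bands`           | sensitive raw-reflectance bands (alpha screen)      |
#' | `fod_bands`           | sensitive bands at the selected FOD order           |
#' | `moisture`            | the 12 fixed moisture indices                       |
#' | `two_band`            | best RVI + NDVI + DVI on raw reflectance            |
#' | `fwbi_two_band`       | FWBI + the single best raw two-band index           |
#' | `two_band_fod`        | best RVI + NDVI + DVI at the selected FOD order     |
#' | `fwbi_two_band_fod`   | FWBI + the single best FOD two-band index           |
#' | `three_band_fod`      | the 7 optimized three-band indices (selected order) |
#' | `fwbi_three_band_fod` | FWBI + the single best three-band index             |
#'
#' @name feature-assembly
NULL

FEATURE_KINDS <- c(
  "raw_bands", "fod_bands", "moisture", "two_band", "fwbi_two_band",
  "two_band_fod", "fwbi_two_band_fod", "three_band_fod", "fwbi_three_band_fod"
)

#' @rdname feature-assembly
#' @param spectra preprocessed (trimmed, smoothed) raw spectra tibble.
#' @param stack an [fod_stack()] built from `spectra`.
#' @param traits trait tibble for all samples.
#' @param train_ids calibration sample ids; every selection uses only these.
#' @param alpha significance level for the band screens.
#' @param fod_order FOD order used for the FOD feature sets; `NULL` selects
#'   the nonzero order with the largest single-band `|r|` on the calibration
#'   set.
#' @param two_band_stride stride (nm) of the two-band scans over the full
#'   trimmed grid.
#' @param three_band_range,three_band_stride,refine three-band search window
#'   (default 400--1300 nm), coarse stride (default 5 nm) and 1 nm local
#'   refinement.
#' @param max_bands cap on the number of sensitive bands kept per screen
#'   (top `|r|`), keeping the single-band feature sets desk-sized.
#' @param min_valid,eps see [corr_map_2d()].
#' @return object of class `"lwc_search"` holding the selections and the
#'   data needed by [assemble_features()].
#' @export
optimize_lwc_features <- function(spectra, stack, traits, train_ids,
                                  alpha = 0.01, fod_order = NULL,
                                  two_band_stride = 1,
                                  three_band_range = c(400, 1300),
                                  three_band_stride = 5, refine = TRUE,
                                  max_bands = 200L, min_valid = 10L,
                                  eps = 1e-10) {
  ids <- spectra_ids(spectra)
  if (!all(train_ids %in% ids)) stop_lwc("train_ids not all present in spectra")
  tr_spectra <- spectra[c("wavelength_nm", train_ids)]
  tr_traits <- traits[traits$sample_id %in% train_ids, ]

  screen_bands <- function(sp) {
    scr <- corr_1d(sp, tr_traits, alpha)
    sig <- scr[scr$significant, ]
    if (!nrow(sig)) stop_lwc("no band passes the alpha = %g screen", alpha)
    sig <- sig[order(-abs(sig$r)), ]
    sort(utils::head(sig$wavelength_nm, max_bands))
  }
  raw_sensitive <- screen_bands(tr_spectra)

  orders <- attr(stack, "orders")
  train_stack_tbl <- corr_1d(
    subset_stack(stack, train_ids), tr_traits, alpha
  )
  order_summary <- corr_1d_summary(train_stack_tbl)
  if (is.null(fod_order)) {
    nz <- order_summary[order_summary$order > 0, ]
    fod_order <- nz$order[which.max(nz$max_abs_r)]
  }
  if (!fod_order %in% orders) stop_lwc("fod_order %.1f not in the stack", fod_order)
  fod_sp <- stack[[format_order(fod_order)]]
  tr_fod <- fod_sp[c("wavelength_nm", train_ids)]
  fod_sensitive <- screen_bands(tr_fod)

  scan2 <- function(sp) {
    purrr::map_dfr(TWO_BAND_FORMS, function(f) {
      corr_map_2d(sp, tr_traits, f,
        stride = two_band_stride, alpha = alpha,
        eps = eps, min_valid = min_valid, keep_map = FALSE
      )$best
    })
  }
  two_band_raw <- scan2(tr_spectra)
  two_band_fod <- scan2(tr_fod)

  three_band <- purrr::map_dfr(THREE_BAND_FORMS, function(f) {
    tibble::as_tibble(corr_search_3d(
      tr_fod, tr_traits, f,
      range = three_band_range, stride = three_band_stride,
      refine = refine, alpha = alpha, eps = eps, min_valid = min_valid
    ))
  })

  structure(
    list(
      spectra = spectra, fod_spectra = fod_sp, traits = traits,
      train_ids = train_ids, alpha = alpha, fod_order = fod_order,
      order_summary = order_summary,
      raw_sensitive = raw_sensitive, fod_sensitive = fod_sensitive,
      two_band_raw = two_band_raw, two_band_fod = two_band_fod,
      three_band = three_band
    ),
    class = "lwc_search"
  )
}

subset_stack <- function(stack, ids) {
  out <- lapply(stack, function(sp) sp[c("wavelength_nm", ids)])
  structure(out, orders = attr(stack, "orders"), class = "fod_stack")
}

#' @export
print.lwc_search <- function(x, ...) {
  cat(sprintf(
    paste0(
      "LWC band-optimization results (calibration n = %d, alpha = %g)\n",
      "  FOD order: %.1f\n",
      "  sensitive bands: %d raw, %d FOD\n",
      "  best two-band (raw): %s(%d,%d) r = %.3f\n",
      "  best two-band (FOD): %s(%d,%d) r = %.3f\n",
      "  best three-band:     %s(%d,%d,%d) r = %.3f\n"
    ),
    length(x$train_ids), x$alpha, x$fod_order,
    length(x$raw_sensitive), length(x$fod_sensitive),
    best_of(x$two_band_raw)$form, best_of(x$two_band_raw)$lambda1,
    best_of(x$two_band_raw)$lambda2, best_of(x$two_band_raw)$r,
    best_of(x$two_band_fod)$form, best_of(x$two_band_fod)$lambda1,
    best_of(x$two_band_fod)$lambda2, best_of(x$two_band_fod)$r,
    best_of(x$three_band)$form, best_of(x$three_band)$lambda1,
    best_of(x$three_band)$lambda2, best_of(x$three_band)$lambda3,
    best_of(x$three_band)$r
  ))
  invisible(x)
}

best_of <- function(combos) combos[which.max(abs(combos$r)), ]

fwbi_values <- function(spectra) {
  mi <- moisture_indices(spectra)
  mi[mi$index_name == "FWBI", c("sample_id", "value")]
}

band_features <- function(spectra, bands, prefix) {
  m <- t(reflectance_at(spectra, bands, context = "sensitive bands"))
  colnames(m) <- sprintf("%s_%d", prefix, bands)
  dplyr::bind_cols(tibble::tibble(sample_id = spectra_ids(spectra)), tibble::as_tibble(m))
}

combo_features <- function(spectra, combos) {
  cols <- purrr::pmap(combos, function(form, lambda1, lambda2, ...) {
    extra <- list(...)
    tbl <- if (is.null(extra$lambda3) || is.na(extra$lambda3)) {
      two_band_index(spectra, form, lambda1, lambda2)
    } else {
      three_band_index(spectra, form, lambda1, lambda2, extra$lambda3)
    }
    stats::setNames(tbl[, c("sample_id", "value")], c("sample_id", tbl$index_name[1]))
  })
  purrr::reduce(cols, dplyr::left_join, by = "sample_id")
}

#' Materialize one of the nine feature matrices
#'
#' @param search an `"lwc_search"` from [optimize_lwc_features()].
#' @param kind one of the nine feature-set kinds (see [feature-assembly]).
#' @return tibble with `sample_id` plus one column per feature, for all
#'   samples (calibration and validation).
#' @export
assemble_features <- function(search, kind) {
  stopifnot(inherits(search, "lwc_search"))
  kind <- match.arg(kind, FEATURE_KINDS)
  sp <- search$spectra
  with_fwbi <- function(tbl) dplyr::left_join(
    stats::setNames(fwbi_values(sp), c("sample_id", "FWBI")), tbl,
    by = "sample_id"
  )
  mi_wide <- function() {
    tidyr::pivot_wider(
      moisture_indices(sp)[c("sample_id", "index_name", "value")],
      names_from = "index_name", values_from = "value"
    )
  }
  switch(kind,
    raw_bands = band_features(sp, search$raw_sensitive, "R"),
    fod_bands = band_features(search$fod_spectra, search$fod_sensitive, "FOD"),
    moisture = mi_wide(),
    two_band = combo_features(sp, search$two_band_raw),
    fwbi_two_band = with_fwbi(combo_features(sp, best_of(search$two_band_raw))),
    two_band_fod = combo_features(search$fod_spectra, search$two_band_fod),
    fwbi_two_band_fod = with_fwbi(combo_features(search$fod_spectra, best_of(search$two_band_fod))),
    three_band_fod = combo_features(search$fod_spectra, search$three_band),
    fwbi_three_band_fod = with_fwbi(combo_features(search$fod_spectra, best_of(search$three_band)))
  )
}

#' @rdname assemble_features
#' @return `assemble_all_features()`: named list of the nine feature tibbles.
#' @export
assemble_all_features <- function(search) {
  stats::setNames(lapply(FEATURE_KINDS, assemble_features, search = search), FEATURE_KINDS)
}
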