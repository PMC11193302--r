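#' Spectra and trait tables
#'
#' `lwcspec` represents a set of reflectance spectra as a *wide tibble*: the
#' first column, `wavelength_nm`, holds the shared integer wavelength grid in
#' nanometres (strictly increasing), and every remaining column holds one
#' sample's reflectance aligned to that grid. Trait tables are tibbles with
#' columns `sample_id` and `lwc_percent` (leaf water content, percent of fresh
#' mass). All user-facing functions take these tibbles first and return
#' tibbles, so pipelines chain with the pipe.
#'
#' Wavelength windows removed during preprocessing split the grid into
#' contiguous *segments* (maximal runs at 1 nm spacing); operations that rely
#' on uniform spacing (smoothing, derivatives) are applied per segment.
#'
#' @name spectra-format
NULL

#' Validate a wide spectra tibble
#'
#' Checks the invariants of the wide spectra format: a strictly increasing
#' integer `wavelength_nm` first column, unique sample columns, and finite
#' numeric reflectance. Raw (underivatized) reflectance is additionally
#' required to lie in `[0, 1.5]` when `raw = TRUE`.
#'
#' @param spectra wide spectra tibble (see [spectra-format]).
#' @param raw logical; enforce the raw-reflectance range check.
#' @return `spectra`, invisibly, if valid; otherwise an error.
#' @export
validate_spectra <- function(spectra, raw = FALSE) {
  if (!is.data.frame(spectra) || ncol(spectra) < 2L) {
    stop_lwc("spectra must be a data frame with a wavelength_nm column and >= 1 sample column")
  }
  if (names(spectra)[1] != "wavelength_nm") {
    stop_lwc("first column of a spectra table must be 'wavelength_nm', got '%s'", names(spectra)[1])
  }
  wl <- spectra$wavelength_nm
  if (!is_wholenumber(wl)) stop_lwc("wavelength_nm must be finite integer nanometres")
  if (any(diff(wl) <= 0)) stop_lwc("wavelength_nm must be strictly increasing")
  ids <- names(spectra)[-1]
  if (anyDuplicated(ids)) stop_lwc("duplicate sample ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(spectra[-1])
  if (!is.numeric(vals)) stop_lwc("reflectance values must be numeric")
  if (any(!is.finite(vals))) stop_lwc("reflectance values must be finite")
  if (raw && (min(vals) < 0 || max(vals) > 1.5)) {
    stop_lwc("raw reflectance out of range [0, 1.5] (min %.4g, max %.4g)", min(vals), max(vals))
  }
  invisible(spectra)
}

#' Build a spectra tibble from a samples-by-bands matrix
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   wavelengths in columns (colnames = nm).
#' @param wavelengths integer wavelengths; defaults to numeric column names.
#' @param sample_ids sample labels; default rownames or `S1..Sn`.
#' @return wide spectra tibble.
#' @export
as_spectra <- function(values, wavelengths = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  wavelengths <- wavelengths %||% as.integer(colnames(values))
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("S", seq_len(nrow(values)))
  if (length(wavelengths) != ncol(values)) stop_lwc("wavelengths length != ncol(values)")
  out <- tibble::as_tibble(t(values), .name_repair = "minimal")
  names(out) <- sample_ids
  out <- dplyr::bind_cols(tibble::tibble(wavelength_nm = as.integer(round(wavelengths))), out)
  validate_spectra(out)
  out
}

#' Extract the samples-by-bands matrix from a spectra tibble
#'
#' @inheritParams validate_spectra
#' @return numeric matrix, rows = samples (rownames = ids), columns = bands
#'   (colnames = wavelength in nm).
#' @export
spectra_matrix <- function(spectra) {
  m <- t(as.matrix(spectra[-1]))
  colnames(m) <- spectra$wavelength_nm
  m
}

#' @rdname spectra_matrix
#' @export
spectra_ids <- function(spectra) names(spectra)[-1]

#' Contiguous wavelength segments of a spectra grid
#'
#' A segment is a maximal run of wavelengths at exactly 1 nm spacing. Window
#' removal (see [trim_spectra()]) leaves several segments; smoothing and
#' derivative operators never bridge the gaps between them.
#'
#' @inheritParams validate_spectra
#' @return tibble with columns `segment`, `start_nm`, `end_nm`, `n_bands`.
#' @export
spectra_segments <- function(spectra) {
  wl <- spectra$wavelength_nm
  brk <- c(0L, cumsum(diff(wl) != 1L))
  runs <- split(wl, brk)
  tibble::tibble(
    segment = seq_along(runs),
    start_nm = unname(vapply(runs, min, numeric(1))),
    end_nm = unname(vapply(runs, max, numeric(1))),
    n_bands = unname(lengths(runs))
  )
}

# segment index (1-based run id) per band, used by per-segment operators
segment_index <- function(wavelengths) {
  c(0L, cumsum(diff(wavelengths) != 1L)) + 1L
}

#' Read spectra (and optionally traits) from delimited text
#'
#' Spectra files are wide CSVs whose first column is `wavelength_nm` and whose
#' remaining columns are sample ids; trait files have columns
#' `sample_id,lwc_percent`. When both paths are given, the two tables are
#' aligned on sample id: samples present in only one file are dropped with a
#' warning, and an error is raised if no sample is shared.
#'
#' @param path path to the wide spectra CSV.
#' @param trait_path optional path to the trait CSV.
#' @return with `trait_path`: a list with elements `spectra` and `traits`
#'   (aligned); otherwise the spectra tibble alone.
#' @export
read_spectra <- function(path, trait_path = NULL) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (names(raw)[1] != "wavelength_nm") {
    stop_lwc("'%s': first column must be 'wavelength_nm', got '%s'", path, names(raw)[1])
  }
  raw <- parse_numeric_columns(raw, path)
  validate_spectra(raw)
  raw$wavelength_nm <- as.integer(round(raw$wavelength_nm))
  if (is.null(trait_path)) return(raw)
  traits <- read_traits(trait_path)
  align_samples(raw, traits)
}

# parse every column (except named exceptions) with R's correctly rounded
# strtod so decimal text of >= 17 significant digits round-trips bit-for-bit;
# the first offending cell of a non-numeric column is named in the error
parse_numeric_columns <- function(df, path, except = character()) {
  for (nm in setdiff(names(df), except)) {
    parsed <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(parsed) & !is.na(df[[nm]]))
    if (length(bad)) {
      stop_lwc(
        "'%s': non-numeric value '%s' in column %s, row %d",
        path, df[[nm]][bad[1]], nm, bad[1]
      )
    }
    df[[nm]] <- parsed
  }
  df
}

#' @rdname read_spectra
#' @param trait file path for `read_traits`.
#' @export
read_traits <- function(path) {
  tr <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("sample_id", "lwc_percent") %in% names(tr))) {
    stop_lwc("'%s': trait table needs columns sample_id, lwc_percent", path)
  }
  tr <- parse_numeric_columns(tr, path, except = "sample_id")
  tr$sample_id <- as.character(tr$sample_id)
  if (anyDuplicated(tr$sample_id)) stop_lwc("'%s': duplicate sample ids in trait table", path)
  if (!is.numeric(tr$lwc_percent) || any(!is.finite(tr$lwc_percent))) {
    stop_lwc("'%s': lwc_percent must be finite numeric", path)
  }
  tibble::as_tibble(tr[c("sample_id", "lwc_percent")])
}

#' Align a spectra table and a trait table on sample id
#'
#' @inheritParams validate_spectra
#' @param traits trait tibble (`sample_id`, `lwc_percent`).
#' @return list with aligned `spectra` and `traits` (same ids, same order).
#' @export
align_samples <- function(spectra, traits) {
  ids_s <- spectra_ids(spectra)
  common <- intersect(ids_s, traits$sample_id)
  if (!length(common)) stop_lwc("no overlapping samples between spectra and traits")
  dropped <- setdiff(union(ids_s, traits$sample_id), common)
  if (length(dropped)) {
    rlang::warn(sprintf(
      "dropping %d sample(s) present in only one table: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  list(
    spectra = spectra[c("wavelength_nm", common)],
    traits = traits[match(common, traits$sample_id), ]
  )
}

#' Write spectra / trait tables
#'
#' Writers emit the same CSV dialect the readers accept; doubles are written
#' in shortest round-trip representation, so a write/read cycle reproduces
#' values bit-for-bit.
#'
#' @inheritParams validate_spectra
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  validate_spectra(spectra)
  readr::write_csv(full_precision(spectra), path)
  invisible(path)
}

# 17 significant digits: enough decimal text to reproduce any double
# bit-for-bit on re-parse
full_precision <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(function(x) is.double(x) && !is.integer(x)),
    function(x) sprintf("%.17g", x)
  ))
}

#' @rdname write_spectra
#' @param traits trait tibble.
#' @export
write_traits <- function(traits, path) {
  readr::write_csv(full_precision(traits), path)
  invisible(path)
}

#' Default removal windows for field canopy spectra
#'
#' Noisy instrument edges (350--399 and 2401--2500 nm) and the two strong
#' atmospheric water-vapour regions (1355--1444 and 1777--1949 nm), all
#' inclusive on both ends.
#'
#' @return tibble with columns `start_nm`, `end_nm`.
#' @export
default_trim_windows <- function() {
  tibble::tibble(
    start_nm = c(350, 1355, 1777, 2401),
    end_nm = c(399, 1444, 1949, 2500)
  )
}

#' Remove wavelength windows from a spectra table
#'
#' Drops every band whose wavelength falls inside any removal window
#' (inclusive on both ends) and leaves the remaining grid split into
#' contiguous segments. With the default windows a full 350--2500 nm grid is
#' reduced to 400--2400 nm minus the two interior water-vapour regions
#' (1738 bands). Trimming is idempotent.
#'
#' @inheritParams validate_spectra
#' @param windows tibble of `start_nm`, `end_nm` removal windows.
#' @return trimmed spectra tibble.
#' @export
trim_spectra <- function(spectra, windows = default_trim_windows()) {
  validate_spectra(spectra)
  if (any(windows$start_nm > windows$end_nm)) stop_lwc("window start_nm > end_nm")
  wl <- spectra$wavelength_nm
  drop <- rep(FALSE, length(wl))
  for (i in seq_len(nrow(windows))) {
    drop <- drop | (wl >= windows$start_nm[i] & wl <= windows$end_nm[i])
  }
  if (all(drop)) stop_lwc("empty spectra: all %d bands fall inside removal windows", length(wl))
  spectra[!drop, ]
}

#' Resample spectra to a 1 nm integer grid
#'
#' Linear interpolation onto an integer grid (ASD export convention). Input
#' wavelengths need not be integer or evenly spaced; the target grid is
#' clipped to the observed wavelength range (no extrapolation).
#'
#' @inheritParams validate_spectra
#' @param grid target integer wavelengths; default `350:2500`.
#' @return spectra tibble on the intersected integer grid.
#' @export
resample_spectra <- function(spectra, grid = 350:2500) {
  wl <- spectra$wavelength_nm
  grid <- grid[grid >= min(wl) & grid <= max(wl)]
  if (!length(grid)) stop_lwc("resampling grid does not overlap the observed wavelengths")
  cols <- lapply(spectra[-1], function(y) stats::approx(wl, y, xout = grid)$y)
  dplyr::bind_cols(tibble::tibble(wavelength_nm = as.integer(grid)), tibble::as_tibble(cols))
}

#' Average spectra by sample group
#'
#' Helper for collapsing repeated scans: columns sharing a group label are
#' replaced by their band-wise mean.
#'
#' @inheritParams validate_spectra
#' @param groups character vector, one group label per sample column.
#' @return spectra tibble with one column per group.
#' @export
average_spectra <- function(spectra, groups) {
  ids <- spectra_ids(spectra)
  if (length(groups) != length(ids)) stop_lwc("groups must have one label per sample column")
  vals <- as.matrix(spectra[-1])
  by <- split(seq_along(ids), groups)
  means <- vapply(by, function(j) rowMeans(vals[, j, drop = FALSE]), numeric(nrow(vals)))
  dplyr::bind_cols(spectra["wavelength_nm"], tibble::as_tibble(as.data.frame(means)))
}
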