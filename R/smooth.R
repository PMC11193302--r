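#' Morphological smoothing of a single spectrum
#'
#' Grey-scale morphological filter with a flat (line) structuring element:
#' the smoothed signal is the elementwise mean of the morphological opening
#' (erosion then dilation) and closing (dilation then erosion). Opening
#' shaves positive spikes, closing fills negative ones, and their average is
#' a symmetric edge-preserving smoother whose output is always bounded by the
#' rolling min/max of the input over the structuring window. Edges are
#' handled by reflection.
#'
#' @param x numeric vector (one contiguous spectrum segment).
#' @param width odd structuring-element width in bands, `>= 3`, at most
#'   `length(x)`.
#' @return numeric vector, same length as `x`.
#' @export
morph_smooth <- function(x, width = 7L) {
  width <- as.integer(width)
  if (width %% 2L == 0L || width < 3L) stop_lwc("width must be an odd integer >= 3, got %d", width)
  if (width > length(x)) stop_lwc("width %d exceeds segment length %d", width, length(x))
  erode <- function(v) roll_extreme(v, width, min)
  dilate <- function(v) roll_extreme(v, width, max)
  opening <- dilate(erode(x))
  closing <- erode(dilate(x))
  (opening + closing) / 2
}

#' Morphological smoothing of a spectra table
#'
#' Applies [morph_smooth()] to every sample, independently within each
#' contiguous wavelength segment (smoothing never bridges removed windows).
#'
#' @inheritParams validate_spectra
#' @param width odd structuring-element width in bands; must not exceed the
#'   shortest segment.
#' @return smoothed spectra tibble with the same grid and sample columns.
#' @export
smooth_spectra <- function(spectra, width = 7L) {
  validate_spectra(spectra)
  seg <- segment_index(spectra$wavelength_nm)
  shortest <- min(tabulate(seg))
  if (as.integer(width) > shortest) {
    stop_lwc("width %d exceeds the shortest segment (%d bands)", as.integer(width), shortest)
  }
  out <- spectra
  for (j in seq_along(out)[-1]) {
    out[[j]] <- unlist(
      lapply(split(out[[j]], seg), morph_smooth, width = width),
      use.names = FALSE
    )
  }
  out
}

#' Trim and smooth in one call
#'
#' Standard preprocessing for field canopy spectra: resample to the 1 nm
#' integer grid if needed, remove the default noisy/atmospheric windows, then
#' smooth morphologically. Trimming precedes smoothing so the filter never
#' spans a removed region.
#'
#' @inheritParams validate_spectra
#' @param windows removal windows, as in [trim_spectra()].
#' @param smooth_width odd smoothing width in bands; `NULL` skips smoothing.
#' @return preprocessed spectra tibble.
#' @export
preprocess_spectra <- function(spectra, windows = default_trim_windows(), smooth_width = 7L) {
  wl <- spectra$wavelength_nm
  if (!all(diff(wl) == 1)) spectra <- resample_spectra(spectra)
  out <- trim_spectra(spectra, windows)
  if (!is.null(smooth_width)) out <- smooth_spectra(out, smooth_width)
  out
}
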