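#' End-to-end LWC estimation pipeline
#'
#' Runs the complete workflow on aligned spectra and traits: 70/30
#' calibration/validation split, preprocessing (1 nm resampling if needed,
#' default window trimming, morphological smoothing), the FOD stack, all
#' band/index optimizations on the calibration subset, assembly of the nine
#' feature matrices, and the feature-set x learner model grid.
#'
#' @inheritParams optimize_lwc_features
#' @param spectra raw spectra tibble (untrimmed is fine).
#' @param traits aligned trait tibble.
#' @param seed master seed driving the split and the learners.
#' @param train_fraction calibration fraction, default 0.70.
#' @param orders FOD orders for the stack, default 0 to 2 step 0.2.
#' @param smooth_width morphological smoothing width (bands); NULL to skip.
#' @param configs learner configs for [run_model_grid()].
#' @param ... passed on to [optimize_lwc_features()].
#' @return object of class `"lwc_pipeline"`: list with `split`, `search`,
#'   `features`, `grid`.
#' @export
lwc_pipeline <- function(spectra, traits, seed = 1L, train_fraction = 0.7,
                         orders = seq(0, 2, by = 0.2), smooth_width = 7L,
                         configs = NULL, ...) {
  aligned <- align_samples(spectra, traits)
  pre <- preprocess_spectra(aligned$spectra, smooth_width = smooth_width)
  split <- split_dataset(spectra_ids(pre), train_fraction, seed)
  stack <- fod_stack(pre, orders)
  search <- optimize_lwc_features(pre, stack, aligned$traits, split$train, ...)
  features <- assemble_all_features(search)
  grid <- run_model_grid(features, aligned$traits, split, configs, seed = seed)
  structure(
    list(split = split, search = search, features = features, grid = grid),
    class = "lwc_pipeline"
  )
}

#' @export
print.lwc_pipeline <- function(x, ...) {
  print(x$search)
  print(x$grid)
  invisible(x)
}
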