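#' Plot spectra, optionally coloured by the trait
#'
#' @inheritParams validate_spectra
#' @param traits optional trait tibble; colours lines by LWC.
#' @param alpha line transparency.
#' @return a ggplot object.
#' @export
plot_spectra <- function(spectra, traits = NULL, alpha = 0.6) {
  long <- tidyr::pivot_longer(spectra, -"wavelength_nm",
    names_to = "sample_id", values_to = "reflectance"
  )
  if (!is.null(traits)) {
    long <- dplyr::left_join(long, traits, by = "sample_id")
    p <- ggplot2::ggplot(long, ggplot2::aes(
      .data$wavelength_nm, .data$reflectance,
      group = .data$sample_id, colour = .data$lwc_percent
    )) +
      ggplot2::scale_colour_viridis_c(name = "LWC (%)")
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(
      .data$wavelength_nm, .data$reflectance, group = .data$sample_id
    ))
  }
  p + ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
    ggplot2::theme_minimal()
}

#' Heatmap of a two-band correlation map
#'
#' @param object a `"corr_map"` from [corr_map_2d()] with a stored map.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.corr_map <- function(object, ...) {
  if (is.null(object$map)) stop_lwc("map was not stored; rerun with keep_map = TRUE")
  ggplot2::ggplot(object$map, ggplot2::aes(.data$lambda1, .data$lambda2, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::geom_point(
      data = object$best, ggplot2::aes(.data$lambda1, .data$lambda2),
      inherit.aes = FALSE, shape = 4, size = 2
    ) +
    ggplot2::labs(
      x = expression(lambda[1] ~ "(nm)"), y = expression(lambda[2] ~ "(nm)"),
      fill = "r", title = sprintf("%s correlation map", object$form)
    ) +
    ggplot2::theme_minimal()
}

#' Validation accuracy across the model grid
#'
#' @param object a `"lwc_model_grid"`.
#' @param metric column to display (default `"r2_val"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lwc_model_grid <- function(object, metric = "r2_val", ...) {
  ggplot2::ggplot(object$reports, ggplot2::aes(
    .data$data_type, .data[[metric]], fill = .data$method
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}
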