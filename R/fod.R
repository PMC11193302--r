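#' Grunwald-Letnikov fractional-derivative weights
#'
#' The v-order G-L derivative of a uniformly sampled signal is the weighted
#' sum \eqn{f^{(v)}(x) \approx \sum_{m} c_m f(x - m)} (unit step), with
#' generalized-binomial weights
#' \eqn{c_m = (-1)^m \Gamma(v+1) / (m!\,\Gamma(v-m+1))}. The weights are
#' generated by the numerically stable multiplicative recurrence
#' `c_0 = 1`, `c_m = c_{m-1} * (m - 1 - v) / m`, which is algebraically
#' identical to the Gamma closed form but avoids poles at integer orders.
#' At `v = 1` the weights reduce to `1, -1, 0, ...` (first backward
#' difference) and at `v = 2` to `1, -2, 1, 0, ...`.
#'
#' @param v fractional order, in `[0, 2]`.
#' @param M truncation length; weights `c_0 .. c_M` are returned.
#' @return numeric vector of `M + 1` weights, with attributes `v` and class
#'   `"gl_weights"`.
#' @export
gl_weights <- function(v, M) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 2) {
    stop_lwc("order v must be a single value in [0, 2]")
  }
  M <- as.integer(M)
  if (is.na(M) || M < 0L) stop_lwc("M must be a non-negative integer")
  w <- numeric(M + 1L)
  w[1] <- 1
  if (M > 0L) {
    for (m in seq_len(M)) w[m + 1L] <- w[m] * (m - 1 - v) / m
  }
  structure(w, v = v, class = "gl_weights")
}

#' @export
print.gl_weights <- function(x, ...) {
  cat(sprintf("G-L weights, order v = %g, c_0..c_%d\n", attr(x, "v"), length(x) - 1L))
  print(unclass(x), ...)
  invisible(x)
}

#' G-L fractional derivative of one contiguous signal
#'
#' Left-truncated G-L sum with unit step: the output at index `k` (0-based)
#' is \eqn{\sum_{m=0}^{k} c_m f(k-m)} — the convolution of the signal with
#' the G-L weights, truncated at the segment start (finite lower terminal).
#' No padding is used, so the first few output values are order-dependent
#' "warm-up" values built from a shortened history. `v = 0` returns the input
#' unchanged.
#'
#' @param x numeric vector on a uniform grid (one segment).
#' @param v fractional order in `[0, 2]`.
#' @return numeric vector, same length as `x`.
#' @export
gl_derivative <- function(x, v) {
  if (!length(x)) stop_lwc("empty segment")
  if (v == 0) return(x)
  w <- as.numeric(gl_weights(v, length(x) - 1L))
  # lower-triangular Toeplitz convolution, truncated at the segment start
  as.numeric(gl_toeplitz(w) %*% x)
}

# L x L lower-triangular Toeplitz matrix of G-L weights
gl_toeplitz <- function(w) {
  L <- length(w)
  idx <- outer(seq_len(L), seq_len(L), "-") + 1L # row - col + 1
  T <- matrix(0, L, L)
  keep <- idx >= 1L
  T[keep] <- w[idx[keep]]
  T
}

#' Fractional-order derivative of a spectra table
#'
#' Differentiates every sample at order `v`, independently within each
#' contiguous 1 nm segment (derivatives never bridge removed windows; the
#' G-L sum assumes uniform spacing). Order 0 is a verbatim copy.
#'
#' @inheritParams validate_spectra
#' @param v fractional order in `[0, 2]`.
#' @return spectra tibble of differentiated reflectance on the same grid.
#' @export
fod_spectra <- function(spectra, v) {
  validate_spectra(spectra)
  if (v == 0) return(spectra)
  seg <- segment_index(spectra$wavelength_nm)
  vals <- as.matrix(spectra[-1])
  out <- vals
  for (s in unique(seg)) {
    rows <- which(seg == s)
    w <- as.numeric(gl_weights(v, length(rows) - 1L))
    out[rows, ] <- gl_toeplitz(w) %*% vals[rows, , drop = FALSE]
  }
  dplyr::bind_cols(spectra["wavelength_nm"], tibble::as_tibble(as.data.frame(out)))
}

#' A stack of FOD-transformed spectra over several orders
#'
#' Differentiates the spectra at each requested order (default 0 to 2 in
#' steps of 0.2, eleven orders). The result is a named list of spectra
#' tibbles, one per order, sharing the source grid and sample ids; use
#' [tidy.fod_stack()] for a long-format view.
#'
#' @inheritParams validate_spectra
#' @param orders numeric vector of orders within `[0, 2]`.
#' @return object of class `"fod_stack"`: named list of spectra tibbles, with
#'   attribute `orders`.
#' @export
fod_stack <- function(spectra, orders = seq(0, 2, by = 0.2)) {
  if (any(orders < 0 | orders > 2)) stop_lwc("all orders must lie in [0, 2]")
  orders <- round(orders, 10)
  sets <- lapply(orders, function(v) fod_spectra(spectra, v))
  names(sets) <- format_order(orders)
  structure(sets, orders = orders, class = "fod_stack")
}

format_order <- function(v) sprintf("%g", v)

#' @export
print.fod_stack <- function(x, ...) {
  cat(sprintf(
    "FOD stack: %d order(s) [%s], %d samples x %d bands\n",
    length(x), paste(names(x), collapse = ", "),
    length(spectra_ids(x[[1]])), nrow(x[[1]])
  ))
  invisible(x)
}

#' Tidy an FOD stack into long format
#'
#' @param x an object of class `"fod_stack"`.
#' @param ... unused.
#' @return tibble with columns `order`, `wavelength_nm`, `sample_id`, `value`.
#' @export
tidy.fod_stack <- function(x, ...) {
  purrr::map2_dfr(x, attr(x, "orders"), function(sp, v) {
    long <- tidyr::pivot_longer(sp, -"wavelength_nm",
      names_to = "sample_id", values_to = "value"
    )
    dplyr::mutate(long, order = v, .before = 1)
  })
}
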