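#' Leaf water content from fresh and dry weight
#'
#' `LWC = (FW - DW) / FW * 100` (percent of fresh mass). Vectorized.
#'
#' @param fresh_g,dry_g fresh and dry weights in grams, `fresh_g > dry_g > 0`.
#' @return LWC in percent.
#' @export
lwc_from_weights <- function(fresh_g, dry_g) {
  if (any(!is.finite(fresh_g)) || any(!is.finite(dry_g))) stop_lwc("weights must be finite")
  if (any(dry_g <= 0)) stop_lwc("dry weight must be positive")
  if (any(dry_g >= fresh_g)) stop_lwc("dry weight must be strictly below fresh weight")
  (fresh_g - dry_g) / fresh_g * 100
}

#' Configuration for the synthetic canopy-spectra generator
#'
#' The generator is phenomenological, not a radiative-transfer model: a
#' parametric vegetation baseline (low visible reflectance with a green peak
#' near 554 nm, a sigmoidal red edge near 718 nm, a NIR plateau and a
#' declining SWIR) is multiplied by a water term
#' `1 - sum_i depth_i(LWC) * exp(-((lambda - c_i) / w_i)^2 / 2)` with
#' absorption features near 970, 1200, 1450 and 1940 nm whose depths grow
#' linearly with LWC, and by a global amplitude that *decreases* linearly
#' with LWC. Per-sample nuisance terms emulate field variability that does
#' not carry water information: a multiplicative canopy-structure gain, a
#' smooth additive baseline drift (offset + linear slope), and band-wise
#' Gaussian noise.
#'
#' Default LWC statistics (n = 154, min 64.94, max 91.54, CV 4.58 percent)
#' match a typical spring-wheat field campaign; the mean is the min/max
#' midpoint (78.24) since only min/max/CV are commonly reported.
#'
#' @param n number of samples.
#' @param lwc_mean,lwc_cv,lwc_min,lwc_max LWC distribution: truncated normal
#'   with mean `lwc_mean` percent and standard deviation
#'   `lwc_cv / 100 * lwc_mean`, truncated to `[lwc_min, lwc_max]`.
#' @param centers_nm,widths_nm,depths,depth_slopes water absorption features:
#'   Gaussian centers (nm), widths (sd, nm), fractional depths at the mean
#'   LWC, and depth increase per percent LWC.
#' @param amp NIR plateau amplitude (reflectance units).
#' @param amp_slope fractional global amplitude decrease per percent LWC.
#' @param gain_sd per-sample sd of the multiplicative gain field (canopy
#'   structure / viewing geometry proxy).
#' @param gain_corr_nm correlation scale of the gain field in nm: the field
#'   is a smooth random curve (spline through independent knots spaced
#'   `gain_corr_nm / 2` apart), so it is locally flat at the few-nm scale
#'   but varies across spectral regions. A flat (rank-one) gain would make
#'   every wide-band contrast collinear; the smooth field keeps single bands
#'   masked while leaving band combinations identifiable.
#' @param depth_jitter_sd per-sample sd of a common multiplicative jitter on
#'   all absorption depths: leaf-level variability in the water features that
#'   carries no LWC information.
#' @param pigment_depths,pigment_sd mean depths of the carotenoid-like blue
#'   well (460 nm) and chlorophyll-like red well (668 nm) in the visible,
#'   and their relative per-sample sd. Pigment variability is independent of
#'   LWC; it gives visible bands sample-to-sample structure of their own, as
#'   field canopies have.
#' @param baseline_offset_sd,baseline_slope_sd per-sample additive drift:
#'   offset sd (reflectance) and slope sd (reflectance per 1000 nm).
#' @param noise_sd band-wise additive Gaussian noise sd (reflectance units).
#' @param noise_corr_nm spectral correlation scale of the band noise
#'   (Gaussian kernel sd, nm). Spectrometer noise on a 1 nm interpolated
#'   grid is smooth over a few nm (detector sampling plus interpolation);
#'   0 gives independent noise per band. The marginal per-band sd stays
#'   `noise_sd` either way.
#' @param grid integer wavelength grid in nm.
#' @param planted optional list of planted index signals, each a list with
#'   elements `form` (a two- or three-band form id), `wavelengths` (2 or 3
#'   nm values on the grid) and optional `weight` (default 1). When given,
#'   the trait is re-generated as a linear function of the (standardized,
#'   weighted) planted index values plus Gaussian noise scaled so the
#'   population R-squared of trait on the planted predictor is `planted_r2`.
#' @param planted_r2 target R-squared for planted signals.
#' @param seed integer seed; every generator output is a pure function of
#'   the configuration (seed included).
#' @return object of class `"lwc_synth_config"` (a named list).
#' @export
synthetic_config <- function(n = 154L,
                             lwc_mean = 78.24, lwc_cv = 4.58,
                             lwc_min = 64.94, lwc_max = 91.54,
                             centers_nm = c(970, 1200, 1450, 1940),
                             widths_nm = c(35, 45, 60, 90),
                             depths = c(0.08, 0.09, 0.30, 0.45),
                             depth_slopes = c(0.0056, 0.005, 0.006, 0.006),
                             amp = 0.48, amp_slope = 0.004,
                             gain_sd = 0.02, gain_corr_nm = 600,
                             depth_jitter_sd = 0.20,
                             pigment_depths = c(0.018, 0.020),
                             pigment_sd = 0.5,
                             baseline_offset_sd = 0.032,
                             baseline_slope_sd = 0.012,
                             noise_sd = 0.005, noise_corr_nm = 3,
                             grid = 350:2500,
                             planted = NULL, planted_r2 = 0.8,
                             seed = 1L) {
  if (!(lwc_min > 0 && lwc_min < lwc_max && lwc_max < 100)) {
    stop_lwc("need 0 < lwc_min < lwc_max < 100")
  }
  if (lwc_mean < lwc_min || lwc_mean > lwc_max) {
    stop_lwc("lwc_mean %.2f outside [lwc_min, lwc_max]", lwc_mean)
  }
  if (noise_sd < 0) stop_lwc("noise_sd must be >= 0")
  if (any(centers_nm < 350 | centers_nm > 2500)) stop_lwc("absorption centers must lie in 350-2500 nm")
  stopifnot(length(widths_nm) == length(centers_nm), length(depths) == length(centers_nm))
  if (!is.null(planted)) {
    for (p in planted) {
      if (!all(p$wavelengths %in% grid)) {
        stop_lwc("planted wavelengths off-grid: %s", paste(setdiff(p$wavelengths, grid), collapse = ", "))
      }
    }
    if (planted_r2 <= 0 || planted_r2 >= 1) stop_lwc("planted_r2 must be in (0, 1)")
  }
  structure(
    list(
      n = as.integer(n), lwc_mean = lwc_mean, lwc_cv = lwc_cv,
      lwc_min = lwc_min, lwc_max = lwc_max,
      centers_nm = centers_nm, widths_nm = widths_nm,
      depths = depths, depth_slopes = depth_slopes,
      amp = amp, amp_slope = amp_slope, gain_sd = gain_sd,
      gain_corr_nm = gain_corr_nm, depth_jitter_sd = depth_jitter_sd,
      pigment_depths = pigment_depths, pigment_sd = pigment_sd,
      baseline_offset_sd = baseline_offset_sd,
      baseline_slope_sd = baseline_slope_sd,
      noise_sd = noise_sd, noise_corr_nm = noise_corr_nm,
      grid = as.integer(grid),
      planted = planted, planted_r2 = planted_r2,
      seed = as.integer(seed)
    ),
    class = "lwc_synth_config"
  )
}

lwc_sd <- function(cfg) cfg$lwc_cv / 100 * cfg$lwc_mean

#' Draw LWC values from the configured truncated normal
#'
#' Inverse-CDF sampling of a normal with the configured mean and CV,
#' truncated to `[lwc_min, lwc_max]`; seeded by `cfg$seed` so the draw is
#' reproducible bit-for-bit.
#'
#' @param cfg a [synthetic_config()].
#' @return trait tibble `sample_id, lwc_percent`.
#' @export
sample_lwc <- function(cfg) {
  sdv <- lwc_sd(cfg)
  lo <- stats::pnorm(cfg$lwc_min, cfg$lwc_mean, sdv)
  hi <- stats::pnorm(cfg$lwc_max, cfg$lwc_mean, sdv)
  vals <- with_local_seed(cfg$seed, {
    stats::qnorm(stats::runif(cfg$n, lo, hi), cfg$lwc_mean, sdv)
  })
  vals <- pmin(pmax(vals, cfg$lwc_min), cfg$lwc_max)
  tibble::tibble(sample_id = sprintf("S%03d", seq_len(cfg$n)), lwc_percent = vals)
}

# noiseless reflectance curve at one LWC; gain/baseline/pigment arguments
# are per-sample nuisances (defaults give the pure closed-form curve)
clean_spectrum <- function(lwc, cfg, gain = 1, offset = 0, slope = 0,
                           depth_gain = 1,
                           pig_blue = cfg$pigment_depths[1],
                           pig_red = cfg$pigment_depths[2]) {
  wl <- cfg$grid
  vis <- 0.055 + 0.05 * exp(-0.5 * ((wl - 554) / 28)^2) -
    pig_blue * exp(-0.5 * ((wl - 460) / 40)^2) -
    pig_red * exp(-0.5 * ((wl - 668) / 28)^2)
  red_edge <- 1 / (1 + exp(-(wl - 718) / 16))
  swir <- 0.25 + 0.75 / (1 + exp((wl - 1650) / 220))
  shape <- vis + cfg$amp * red_edge * swir
  depth <- pmax(depth_gain * (cfg$depths + cfg$depth_slopes * (lwc - cfg$lwc_mean)), 0)
  water <- 1 - colSums(depth * t(vapply(
    seq_along(cfg$centers_nm),
    function(i) exp(-0.5 * ((wl - cfg$centers_nm[i]) / cfg$widths_nm[i])^2),
    numeric(length(wl))
  ))) # safe: vapply returns bands x features
  scale_lwc <- 1 - cfg$amp_slope * (lwc - cfg$lwc_mean)
  core <- gain * scale_lwc * shape * water
  # depth-driven negativity is a configuration error; additive-drift
  # excursions are rare nuisance draws and are clipped by the caller
  if (mean(core <= 0) > 0.05) {
    stop_lwc("unphysical config: reflectance <= 0 over %.1f%% of bands", 100 * mean(core <= 0))
  }
  core + offset + slope * (wl - 1425) / 1000
}

#' Simulate one canopy spectrum at a given LWC
#'
#' Evaluates the generator's closed-form curve (baseline times water
#' absorption term, amplitude declining with LWC) and adds seeded Gaussian
#' band noise. Reflectance is clipped to (0, 1).
#'
#' @param lwc leaf water content in percent, within the config bounds.
#' @param cfg a [synthetic_config()].
#' @param noise_seed seed for the band noise; `NULL` with `noise_sd = 0`
#'   gives the deterministic noiseless curve.
#' @param gain,offset,slope per-sample nuisance parameters (defaults off).
#' @return tibble `wavelength_nm, reflectance`.
#' @export
simulate_spectrum <- function(lwc, cfg, noise_seed = NULL,
                              gain = 1, offset = 0, slope = 0) {
  if (lwc < cfg$lwc_min || lwc > cfg$lwc_max) {
    stop_lwc("lwc %.2f outside config bounds [%.2f, %.2f]", lwc, cfg$lwc_min, cfg$lwc_max)
  }
  curve <- clean_spectrum(lwc, cfg, gain, offset, slope)
  if (cfg$noise_sd > 0) {
    if (is.null(noise_seed)) stop_lwc("noise_seed required when noise_sd > 0")
    e <- with_local_seed(noise_seed, stats::rnorm(length(curve)))
    curve <- curve + cfg$noise_sd * correlate_noise(rbind(e), cfg$noise_corr_nm)[1, ]
  }
  tibble::tibble(
    wavelength_nm = cfg$grid,
    reflectance = pmin(pmax(curve, 1e-6), 1 - 1e-6)
  )
}

#' Generate a complete synthetic dataset
#'
#' Draws LWC values, simulates one spectrum per sample on the configured
#' grid (with per-sample gain, baseline drift and band noise), and returns
#' aligned spectra and trait tables. With planted index signals the trait is
#' re-generated as a linear function of the named index values plus noise
#' scaled to the target R-squared, and the ground truth is recorded. The
#' whole dataset is a pure function of the configuration (seed included).
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `"lwc_synth"`: list with `spectra` (wide tibble),
#'   `traits`, and `ground_truth` (config plus planted-signal record).
#' @export
make_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "lwc_synth_config"))
  traits <- sample_lwc(cfg)
  n <- cfg$n
  nuis <- with_local_seed(cfg$seed + 1L, list(
    gain = gain_field(n, cfg$grid, cfg$gain_corr_nm, cfg$gain_sd),
    depth_gain = stats::rnorm(n, 1, cfg$depth_jitter_sd),
    offset = stats::rnorm(n, 0, cfg$baseline_offset_sd),
    slope = stats::rnorm(n, 0, cfg$baseline_slope_sd),
    pig_blue = pmin(pmax(stats::rnorm(
      n, cfg$pigment_depths[1], cfg$pigment_sd * cfg$pigment_depths[1]
    ), 0), 0.03),
    pig_red = pmin(pmax(stats::rnorm(
      n, cfg$pigment_depths[2], cfg$pigment_sd * cfg$pigment_depths[2]
    ), 0), 0.03)
  ))
  nb <- length(cfg$grid)
  noise <- if (cfg$noise_sd > 0) {
    e <- with_local_seed(cfg$seed + 2L, matrix(stats::rnorm(n * nb), nrow = n))
    cfg$noise_sd * correlate_noise(e, cfg$noise_corr_nm)
  } else {
    matrix(0, n, nb)
  }
  clean <- matrix(0, n, nb, dimnames = list(traits$sample_id, cfg$grid))
  for (i in seq_len(n)) {
    clean[i, ] <- clean_spectrum(
      traits$lwc_percent[i], cfg,
      gain = nuis$gain[i, ], offset = nuis$offset[i], slope = nuis$slope[i],
      depth_gain = nuis$depth_gain[i],
      pig_blue = nuis$pig_blue[i], pig_red = nuis$pig_red[i]
    )
  }
  vals <- pmin(pmax(clean + noise, 1e-6), 1 - 1e-6)
  spectra <- as_spectra(vals, wavelengths = cfg$grid, sample_ids = traits$sample_id)
  ground_truth <- list(config = cfg, planted = NULL)
  if (!is.null(cfg$planted)) {
    z <- vapply(cfg$planted, function(p) {
      w <- (p$weight %||% 1)
      vals_p <- planted_index_values(spectra, p)
      w * as.numeric(scale(vals_p))
    }, numeric(n))
    zc <- as.numeric(scale(rowSums(z)))
    e <- with_local_seed(cfg$seed + 3L, stats::rnorm(n))
    y <- sqrt(cfg$planted_r2) * zc + sqrt(1 - cfg$planted_r2) * as.numeric(scale(e))
    traits$lwc_percent <- pmin(
      pmax(cfg$lwc_mean + lwc_sd(cfg) * y, cfg$lwc_min), cfg$lwc_max
    )
    ground_truth$planted <- cfg$planted
    ground_truth$target_r2 <- cfg$planted_r2
  }
  structure(
    list(spectra = spectra, traits = traits, ground_truth = ground_truth),
    class = "lwc_synth"
  )
}

# per-sample multiplicative gain curves: cubic splines through independent
# N(1, sd) knots spaced corr_nm / 2 apart, evaluated on the band grid
gain_field <- function(n, grid, corr_nm, sd) {
  knots <- seq(min(grid) - corr_nm, max(grid) + corr_nm, by = corr_nm / 2)
  A <- matrix(stats::rnorm(n * length(knots), 1, sd), nrow = n)
  t(apply(A, 1, function(a) stats::spline(knots, a, xout = grid)$y))
}

# smooth iid standard-normal rows with a Gaussian kernel along the band
# axis, normalized so the marginal variance stays 1 (truncated-kernel edges
# renormalized per position)
correlate_noise <- function(E, sd_nm) {
  if (sd_nm <= 0) return(E)
  half <- as.integer(ceiling(3 * sd_nm))
  k <- stats::dnorm(-half:half, 0, sd_nm)
  k <- k / sqrt(sum(k^2))
  nb <- ncol(E)
  out <- t(apply(E, 1, function(e) {
    f <- as.numeric(stats::filter(e, k, sides = 2))
    for (i in which(is.na(f))) {
      lo <- max(1L, i - half)
      hi <- min(nb, i + half)
      kk <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
      f[i] <- sum(e[lo:hi] * kk) / sqrt(sum(kk^2))
    }
    f
  }))
  dimnames(out) <- dimnames(E)
  out
}

planted_index_values <- function(spectra, p) {
  wl <- p$wavelengths
  tbl <- if (length(wl) == 2L) {
    two_band_index(spectra, p$form, wl[1], wl[2])
  } else if (length(wl) == 3L) {
    three_band_index(spectra, p$form, wl[1], wl[2], wl[3])
  } else {
    stop_lwc("planted signal needs 2 or 3 wavelengths")
  }
  if (any(!tbl$valid)) stop_lwc("planted index degenerate for %d sample(s)", sum(!tbl$valid))
  tbl$value
}

#' @export
print.lwc_synth <- function(x, ...) {
  cat(sprintf(
    "synthetic LWC dataset: %d samples x %d bands, LWC %.2f-%.2f%% (CV %.2f%%)%s\n",
    length(spectra_ids(x$spectra)), nrow(x$spectra),
    min(x$traits$lwc_percent), max(x$traits$lwc_percent),
    100 * stats::sd(x$traits$lwc_percent) / mean(x$traits$lwc_percent),
    if (is.null(x$ground_truth$planted)) "" else " [planted signal]"
  ))
  invisible(x)
}
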