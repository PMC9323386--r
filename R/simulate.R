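#' Configuration for the synthetic FT-NIR spectra generator
#'
#' Describes a labelled population of diffuse-reflectance absorbance spectra
#' with the structure typical of refrigerated-storage studies: a smooth
#' quadratic baseline, Gaussian absorption peaks (defaults near 5200 and
#' 6900 cm^-1, the water-related combination and first-overtone bands), a
#' small progressive class-dependent shift in peak amplitude (the storage-day
#' effect), per-sample multiplicative/additive scatter distortion (the
#' artefact MSC removes), and additive channel noise elevated inside the
#' low-wavenumber water band.
#'
#' @param n_classes number of storage classes (default 6).
#' @param samples_per_class spectra per class (default 67; 6 x 67 = 402).
#' @param wavenumber_start,wavenumber_end grid end points in cm^-1, strictly
#'   decreasing from start to end (defaults 10000 and 4000).
#' @param n_points channels on the grid (default 1557, ~4 cm^-1 spacing).
#' @param baseline_coefs length-3 numeric: quadratic baseline coefficients
#'   `b0 + b1*t + b2*t^2` in absorbance units, where `t` runs 0..1 from the
#'   high- to the low-wavenumber end.
#' @param peak_centers Gaussian peak centres, cm^-1.
#' @param peak_widths Gaussian peak standard deviations, cm^-1.
#' @param peak_amplitudes class-1 peak heights, absorbance units.
#' @param class_amplitude_step per-class amplitude increment for each peak,
#'   absorbance units: class `c` has height
#'   `peak_amplitudes + (c-1)*class_amplitude_step`.
#' @param scatter_slope_sd standard deviation of the per-sample multiplicative
#'   scatter slope around 1 (dimensionless).
#' @param scatter_offset_sd standard deviation of the per-sample additive
#'   offset (absorbance units).
#' @param noise_sd standard deviation of the i.i.d. channel noise
#'   (absorbance units).
#' @param water_band cm^-1 interval (low, high) with elevated noise.
#' @param water_noise_multiplier factor applied to `noise_sd` inside
#'   `water_band` (>= 1 models the residual water-band noise).
#' @param seed optional integer seed stored in the config and used by
#'   [simulate_spectra()] by default.
#' @return An object of class `spectra_config` (a validated list).
#' @seealso [well_separated_config()] for a high-contrast preset,
#'   [class_template()], [simulate_spectra()].
#' @export
spectra_config <- function(n_classes = 6,
                           samples_per_class = 67,
                           wavenumber_start = 10000,
                           wavenumber_end = 4000,
                           n_points = 1557,
                           baseline_coefs = c(0.25, 0.15, 0.08),
                           peak_centers = c(5200, 6900),
                           peak_widths = c(120, 220),
                           peak_amplitudes = c(0.75, 0.55),
                           class_amplitude_step = c(0.0175, 0.0125),
                           scatter_slope_sd = 0.05,
                           scatter_offset_sd = 0.02,
                           noise_sd = 0.01,
                           water_band = c(4000, 4350),
                           water_noise_multiplier = 3,
                           seed = NULL) {
  np <- length(peak_centers)
  peak_widths <- rep_len(peak_widths, np)
  peak_amplitudes <- rep_len(peak_amplitudes, np)
  class_amplitude_step <- rep_len(class_amplitude_step, np)
  cfg <- list(n_classes = as.integer(n_classes),
              samples_per_class = as.integer(samples_per_class),
              wavenumber_start = wavenumber_start,
              wavenumber_end = wavenumber_end,
              n_points = as.integer(n_points),
              baseline_coefs = baseline_coefs,
              peak_centers = peak_centers,
              peak_widths = peak_widths,
              peak_amplitudes = peak_amplitudes,
              class_amplitude_step = class_amplitude_step,
              scatter_slope_sd = scatter_slope_sd,
              scatter_offset_sd = scatter_offset_sd,
              noise_sd = noise_sd,
              water_band = sort(water_band),
              water_noise_multiplier = water_noise_multiplier,
              seed = if (!is.null(seed)) as.integer(seed))
  validate_spectra_config(cfg)
  class(cfg) <- "spectra_config"
  cfg
}

validate_spectra_config <- function(cfg) {
  stopifnot(cfg$n_points >= 2,
            cfg$wavenumber_start > cfg$wavenumber_end,
            cfg$n_classes >= 1, cfg$samples_per_class >= 1,
            length(cfg$baseline_coefs) == 3,
            all(cfg$peak_widths > 0),
            cfg$scatter_slope_sd >= 0, cfg$scatter_offset_sd >= 0,
            cfg$noise_sd >= 0, cfg$water_noise_multiplier >= 0,
            length(cfg$water_band) == 2)
  invisible(cfg)
}

#' High-contrast synthetic preset
#'
#' The same generative model as [spectra_config()] but with a larger
#' class-amplitude step and lower channel noise, so that all classes form
#' well-separated clusters after dimension reduction (label recovery is
#' essentially perfect). Intended for label-recovery and
#' initialization-robustness checks, where the generating partition must be
#' unambiguous. The noise level is kept moderate on purpose: the class means
#' of this generative model are collinear (amplitudes grow linearly with
#' class), and vanishingly tight clusters on a line make the clustering
#' objectives needlessly multimodal, which is a numerical artefact rather
#' than a property of real spectra.
#'
#' @param ... overrides passed on to [spectra_config()].
#' @return A `spectra_config`.
#' @export
well_separated_config <- function(...) {
  spectra_config(class_amplitude_step = c(0.02, 0.015),
                 noise_sd = 0.008, ...)
}

#' Wavenumber grid of a configuration
#' @param config a [spectra_config()].
#' @return Numeric vector of `n_points` wavenumbers, strictly decreasing.
#' @export
config_wavenumbers <- function(config) {
  seq(config$wavenumber_start, config$wavenumber_end,
      length.out = config$n_points)
}

#' Noiseless class template spectrum
#'
#' The deterministic part of the generative model for one class: quadratic
#' baseline plus Gaussian peaks whose heights grow linearly with the class
#' index. Adjacent classes therefore overlap more than distant ones, and the
#' template is independent of the seed (randomness enters only through
#' scatter and noise in [simulate_spectra()]).
#'
#' @param class_index class in `1:n_classes`.
#' @param config a [spectra_config()].
#' @return Numeric vector of `n_points` absorbances.
#' @export
class_template <- function(class_index, config) {
  validate_spectra_config(config)
  if (length(class_index) != 1 || class_index < 1 ||
      class_index > config$n_classes) {
    stop(sprintf("'class_index' must be in 1..%d", config$n_classes))
  }
  w <- config_wavenumbers(config)
  t01 <- (config$wavenumber_start - w) /
    (config$wavenumber_start - config$wavenumber_end)
  b <- config$baseline_coefs
  y <- b[1] + b[2] * t01 + b[3] * t01^2
  for (p in seq_along(config$peak_centers)) {
    amp <- config$peak_amplitudes[p] +
      (class_index - 1) * config$class_amplitude_step[p]
    y <- y + amp * exp(-(w - config$peak_centers[p])^2 /
                         (2 * config$peak_widths[p]^2))
  }
  y
}

#' Simulate a labelled synthetic spectra set
#'
#' Each sample is `slope * template(class) + offset + noise` with
#' `slope ~ 1 + N(0, scatter_slope_sd)`, `offset ~ N(0, scatter_offset_sd)`
#' and i.i.d. channel noise `N(0, noise_sd)`, the noise standard deviation
#' multiplied by `water_noise_multiplier` inside the water band. Samples are
#' generated class-major (all of class 1, then class 2, ...); for a fixed
#' seed the draw order is: all slopes, then all offsets, then the noise
#' matrix row by row, so output is bitwise reproducible.
#'
#' @param config a [spectra_config()].
#' @param seed integer seed; defaults to `config$seed`. When `NULL`, draws
#'   from the current RNG stream.
#' @return A [spectra_set()] with `n_classes * samples_per_class` rows,
#'   labels `1..n_classes`, and sample ids `d<class>_<replicate>`.
#' @export
simulate_spectra <- function(config, seed = config$seed) {
  validate_spectra_config(config)
  if (!is.null(seed)) set.seed(seed)
  k <- config$n_classes
  spc <- config$samples_per_class
  n <- k * spc
  p <- config$n_points
  w <- config_wavenumbers(config)

  slopes <- 1 + stats::rnorm(n, 0, config$scatter_slope_sd)
  offsets <- stats::rnorm(n, 0, config$scatter_offset_sd)
  noise <- matrix(stats::rnorm(n * p), nrow = n, byrow = TRUE)
  sd_vec <- rep(config$noise_sd, p)
  in_band <- w >= config$water_band[1] & w <= config$water_band[2]
  sd_vec[in_band] <- sd_vec[in_band] * config$water_noise_multiplier
  noise <- sweep(noise, 2, sd_vec, "*")

  templates <- vapply(seq_len(k), class_template, numeric(p), config = config)
  labels <- rep(seq_len(k), each = spc)
  absorbance <- slopes * t(templates)[labels, , drop = FALSE] +
    offsets + noise
  ids <- sprintf("d%d_%02d", labels, rep(seq_len(spc), times = k))
  spectra_set(absorbance, w, labels = labels, sample_ids = ids)
}
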