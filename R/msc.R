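#' Fit an MSC reference (standard) spectrum
#'
#' The reference for multiplicative scatter correction is the arithmetic
#' mean spectrum of the supplied set, the usual stand-in for the unobservable
#' ideal spectrum.
#'
#' @param x a [spectra_set()] or numeric matrix (samples x wavenumbers),
#'   at least two spectra.
#' @return An object of class `msc_reference`: list with `reference` (mean
#'   spectrum), `wavenumbers` (or `NULL` for bare matrices) and
#'   `n_source_samples`.
#' @export
msc_reference <- function(x) {
  m <- as_spectra_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 spectra to fit an MSC reference")
  ref <- colMeans(m)
  if (stats::var(ref) <= 0) {
    stop("reference spectrum is constant; MSC is undefined")
  }
  structure(
    list(reference = ref,
         wavenumbers = if (inherits(x, "spectra_set")) x$wavenumbers,
         n_source_samples = nrow(m)),
    class = "msc_reference"
  )
}

#' @export
print.msc_reference <- function(x, ...) {
  cat(sprintf("<msc_reference> mean of %d spectra, %d points\n",
              x$n_source_samples, length(x$reference)))
  invisible(x)
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x_i` is regressed by ordinary least squares on the
#' reference spectrum over all channels, `x_i ~ intercept + slope * ref`,
#' and corrected to `(x_i - intercept) / slope`. This removes the per-sample
#' additive offset and multiplicative slope that light scatter imposes on
#' diffuse-reflectance spectra. A fitted slope smaller than `slope_tol` in
#' magnitude is degenerate: that sample is returned uncorrected with a
#' warning and flagged in the fit table.
#'
#' @param x a [spectra_set()] or numeric matrix to correct.
#' @param reference an [msc_reference()]; fitted from `x` itself when `NULL`.
#'   Fit the reference on training data only and reuse it for test data to
#'   avoid leakage.
#' @param slope_tol magnitude below which a fitted slope is treated as
#'   degenerate (default 1e-8).
#' @return An object of class `msc`: list with `spectra` (the corrected set,
#'   same shape and grid as the input), `reference`, and the per-sample fit
#'   `slope`, `intercept`, `degenerate`.
#' @examples
#' cfg <- spectra_config(n_classes = 2, samples_per_class = 5, n_points = 80,
#'                       seed = 1)
#' s <- simulate_spectra(cfg)
#' corr <- msc(s)
#' range(corr$slope)
#' @export
msc <- function(x, reference = NULL, slope_tol = 1e-8) {
  m <- as_spectra_matrix(x)
  if (is.null(reference)) reference <- msc_reference(x)
  stopifnot(inherits(reference, "msc_reference"))
  ref <- reference$reference
  if (length(ref) != ncol(m)) {
    stop("spectra and reference are on different wavenumber grids")
  }
  rc <- ref - mean(ref)
  ss <- sum(rc^2)
  if (ss <= 0) stop("reference spectrum is constant; MSC is undefined")
  slope <- unname(drop(m %*% rc) / ss)
  intercept <- unname(rowMeans(m)) - slope * mean(ref)
  degenerate <- abs(slope) < slope_tol
  if (any(degenerate)) {
    warning(sprintf("%d sample(s) with degenerate MSC slope left uncorrected",
                    sum(degenerate)))
  }
  safe_slope <- ifelse(degenerate, 1, slope)
  safe_int <- ifelse(degenerate, 0, intercept)
  corrected <- (m - safe_int) / safe_slope
  out <- if (inherits(x, "spectra_set")) {
    spectra_set(corrected, x$wavenumbers, labels = x$labels,
                sample_ids = x$sample_ids)
  } else {
    spectra_set(corrected, seq_len(ncol(m)))
  }
  structure(
    list(spectra = out, reference = reference, slope = slope,
         intercept = intercept, degenerate = degenerate),
    class = "msc"
  )
}

#' @export
print.msc <- function(x, ...) {
  cat(sprintf("<msc> %d spectra corrected; slope range [%.4f, %.4f]\n",
              nrow(x$spectra$absorbance), min(x$slope), max(x$slope)))
  if (any(x$degenerate)) {
    cat("  degenerate (uncorrected):", sum(x$degenerate), "sample(s)\n")
  }
  invisible(x)
}

#' @export
coef.msc <- function(object, ...) {
  cbind(slope = object$slope, intercept = object$intercept)
}
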