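#' Construct a spectra set
#'
#' A `spectra_set` holds a sample-by-wavenumber absorbance matrix together
#' with its wavenumber grid (cm^-1, conventionally decreasing for FT-NIR
#' diffuse reflectance data), optional integer class labels (e.g. storage
#' day), and sample identifiers.
#'
#' @param absorbance numeric matrix, rows are samples, columns are
#'   wavenumber channels. All values must be finite.
#' @param wavenumbers numeric vector of length `ncol(absorbance)`, in cm^-1.
#' @param labels optional integer vector of class indices (>= 1), one per
#'   sample.
#' @param sample_ids optional character vector of sample identifiers;
#'   generated as `s0001, s0002, ...` when omitted.
#' @return An object of class `spectra_set`: a list with components
#'   `absorbance`, `wavenumbers`, `labels`, `sample_ids`.
#' @examples
#' x <- spectra_set(matrix(runif(20), 4, 5), seq(9000, 5000, length.out = 5),
#'                  labels = c(1, 1, 2, 2))
#' x
#' @export
spectra_set <- function(absorbance, wavenumbers, labels = NULL,
                        sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (!all(is.finite(absorbance))) {
    stop("'absorbance' must be a finite numeric matrix")
  }
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(absorbance)) {
    stop("length(wavenumbers) must equal ncol(absorbance)")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(absorbance)) {
      stop("'labels' must have one entry per sample")
    }
    if (anyNA(labels) || any(labels < 1L)) {
      stop("'labels' must be integers >= 1")
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%04d", seq_len(nrow(absorbance)))
  } else {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != nrow(absorbance)) {
      stop("'sample_ids' must have one entry per sample")
    }
  }
  structure(
    list(absorbance = absorbance, wavenumbers = wavenumbers,
         labels = labels, sample_ids = sample_ids),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d wavenumbers (%.0f to %.0f cm^-1)\n",
              nrow(x$absorbance), ncol(x$absorbance),
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a spectra set by sample
#'
#' @param x a [spectra_set()].
#' @param i sample index (integer or logical).
#' @param ... unused.
#' @return A `spectra_set` containing the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$absorbance[i, , drop = FALSE], x$wavenumbers,
              labels = if (!is.null(x$labels)) x$labels[i],
              sample_ids = x$sample_ids[i])
}

#' Number of samples in a spectra set
#' @param x a [spectra_set()].
#' @return Integer sample count.
#' @export
n_spectra <- function(x) nrow(as_spectra_matrix(x))

#' Coerce spectra input to a plain matrix
#'
#' Accepts a `spectra_set` or a bare numeric matrix; always returns the
#' absorbance matrix.
#' @param x a [spectra_set()] or numeric matrix.
#' @return Numeric matrix of absorbances (samples x wavenumbers).
#' @export
as_spectra_matrix <- function(x) {
  if (inherits(x, "spectra_set")) x$absorbance else as.matrix(x)
}

#' Plot spectra
#'
#' Draws all spectra against the wavenumber grid with the conventional
#' reversed (decreasing) x axis, coloured by class label when present.
#'
#' @param x a [spectra_set()].
#' @param max_lines maximum number of spectra drawn (thinned evenly beyond).
#' @param ... further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.spectra_set <- function(x, max_lines = 60, ...) {
  n <- nrow(x$absorbance)
  idx <- if (n > max_lines) round(seq(1, n, length.out = max_lines)) else seq_len(n)
  cols <- if (!is.null(x$labels)) x$labels[idx] else 1L
  graphics::matplot(x$wavenumbers, t(x$absorbance[idx, , drop = FALSE]),
                    type = "l", lty = 1, col = cols,
                    xlim = rev(range(x$wavenumbers)),
                    xlab = expression(Wavenumber ~ (cm^-1)),
                    ylab = "Absorbance", ...)
  invisible(x)
}

#' Write a spectra set to CSV
#'
#' Long layout: first column `sample_id`, second column `label` (omitted when
#' `wide = TRUE` or when the set is unlabelled), remaining columns the
#' absorbances with the wavenumber values as headers.
#'
#' @param x a [spectra_set()].
#' @param path output file path.
#' @param wide if `TRUE`, write only the absorbance matrix with wavenumber
#'   headers (no id or label columns).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, wide = FALSE) {
  stopifnot(inherits(x, "spectra_set"))
  a <- as.data.frame(x$absorbance)
  names(a) <- format(x$wavenumbers, trim = TRUE, scientific = FALSE)
  if (wide) {
    utils::write.csv(a, path, row.names = FALSE)
  } else {
    d <- cbind(data.frame(sample_id = x$sample_ids), a)
    if (!is.null(x$labels)) d <- cbind(d[1], label = x$labels, d[-1])
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a spectra set from CSV
#'
#' Inverse of [write_spectra()]: expects wavenumber-valued column headers,
#' with optional leading `sample_id` and `label` columns.
#'
#' @param path CSV file path.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  ids <- NULL
  labels <- NULL
  if ("sample_id" %in% names(d)) {
    ids <- as.character(d$sample_id)
    d$sample_id <- NULL
  }
  if ("label" %in% names(d)) {
    labels <- as.integer(d$label)
    d$label <- NULL
  }
  w <- suppressWarnings(as.numeric(names(d)))
  if (anyNA(w)) stop("column headers must be wavenumber values")
  spectra_set(as.matrix(d), w, labels = labels, sample_ids = ids)
}
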