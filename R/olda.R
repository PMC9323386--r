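#' Between-, within- and total-scatter matrices
#'
#' Direct evaluation of the three scatter matrices of discriminant analysis:
#' `Sb = sum_c n_c (mu_c - mu)(mu_c - mu)'`,
#' `Sw = sum_c sum_{i in c} (x_i - mu_c)(x_i - mu_c)'`,
#' `St = sum_i (x_i - mu)(x_i - mu)'`, with `St = Sb + Sw`.
#' Forms d x d matrices explicitly, so intended for moderate dimension;
#' [olda()] itself works on factored forms and never builds these.
#'
#' @param x numeric matrix, samples x features.
#' @param labels class vector (integer/factor), at least two non-empty
#'   classes.
#' @return An object of class `scatter_matrices`: list with `Sb`, `Sw`,
#'   `St`, `class_means` (k x d), `global_mean`, `counts`.
#' @export
scatter_matrices <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(as.factor(labels))
  if (nrow(x) != length(labels)) stop("'labels' must match rows of 'x'")
  k <- max(labels)
  if (k < 2) stop("need at least two classes")
  counts <- tabulate(labels, k)
  if (any(counts == 0)) stop("every class must be non-empty")
  if (nrow(x) < k) stop("need at least as many samples as classes")
  mu <- colMeans(x)
  cm <- matrix(0, k, ncol(x))
  Sw <- matrix(0, ncol(x), ncol(x))
  for (c in seq_len(k)) {
    xc <- x[labels == c, , drop = FALSE]
    cm[c, ] <- colMeans(xc)
    d <- sweep(xc, 2, cm[c, ])
    Sw <- Sw + crossprod(d)
  }
  dm <- sweep(cm, 2, mu)
  Sb <- crossprod(dm * sqrt(counts))
  dt <- sweep(x, 2, mu)
  St <- crossprod(dt)
  structure(list(Sb = Sb, Sw = Sw, St = St, class_means = cm,
                 global_mean = mu, counts = counts),
            class = "scatter_matrices")
}

#' Orthogonal linear discriminant analysis
#'
#' Supervised dimension reduction maximizing the pseudo-inverse Fisher
#' criterion `trace((G' St G)^+ (G' Sb G))`, valid in the small-sample-size
#' regime where the feature dimension exceeds the sample count and the
#' scatter matrices are singular. The solution is computed from reduced
#' decompositions of the centered data (never forming d x d scatter
#' matrices): a thin SVD of the centered data gives the total-scatter range,
#' the class-mean structure is whitened there, a second SVD extracts the
#' discriminant directions, and a final QR factorization orthonormalizes the
#' transformation. Columns are ordered by decreasing criterion contribution
#' and sign-fixed so each column's largest-magnitude entry is positive.
#'
#' @param x numeric training matrix, samples x features (d may exceed n).
#' @param labels class vector, k >= 2 non-empty classes.
#' @param n_components number of discriminant directions, at most `k - 1`
#'   (the rank bound of the between-class scatter); defaults to `k - 1`.
#'   Reduced with a warning if the between-class rank is lower.
#' @param sv_tol relative singular-value threshold used for the
#'   pseudo-inverse; defaults to `max(dim) * .Machine$double.eps`.
#' @return An object of class `olda`: list with orthonormal projection `G`
#'   (d x q), `mean` (training global mean used for centering),
#'   `n_components`, `criterion_value` (the maximized trace),
#'   `component_values` and `component_shares` (per-component contribution,
#'   summing to 1 over retained components), `n_classes`, `class_levels`.
#' @examples
#' x <- matrix(rnorm(60 * 3), 60, 3)
#' x[21:40, 1] <- x[21:40, 1] + 4; x[41:60, 2] <- x[41:60, 2] + 4
#' fit <- olda(x, rep(1:3, each = 20))
#' crossprod(fit$G)      # identity
#' head(predict(fit, x))
#' @export
olda <- function(x, labels, n_components = NULL, sv_tol = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  f <- as.factor(labels)
  labels <- as.integer(f)
  if (nrow(x) != length(labels)) stop("'labels' must match rows of 'x'")
  k <- max(labels)
  if (k < 2) stop("need at least two classes")
  counts <- tabulate(labels, k)
  if (any(counts == 0)) stop("every class must be non-empty")
  if (is.null(n_components)) n_components <- k - 1L
  if (n_components > k - 1) {
    stop(sprintf("'n_components' cannot exceed k - 1 = %d", k - 1))
  }
  n <- nrow(x); d <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)

  # thin SVD of the centered data: St = V diag(s^2) V'
  sv <- svd(xc, nu = 0)
  if (is.null(sv_tol)) sv_tol <- max(n, d) * .Machine$double.eps
  keep <- sv$d > sv_tol * max(sv$d)
  if (!any(keep)) stop("all samples identical; no total scatter")
  s <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]

  # class-mean factor Hb: columns sqrt(n_c) (mu_c - mu), so Sb = Hb Hb'
  cm <- rowsum(x, labels) / counts
  Hb <- t(sweep(cm, 2, mu) * sqrt(counts))       # d x k

  # whiten within the total-scatter range and extract discriminant dirs
  B <- (crossprod(V, Hb)) / s                    # t x k
  sb <- svd(B, nv = 0)
  rank_b <- sum(sb$d > max(dim(B)) * .Machine$double.eps * max(sb$d, 0))
  q <- min(n_components, rank_b)
  if (q < n_components) {
    warning(sprintf(
      "between-class rank %d < requested %d components; returning %d",
      rank_b, n_components, q))
  }
  if (q < 1) stop("between-class scatter has rank 0")
  W <- V %*% (sb$u[, seq_len(q), drop = FALSE] / s)   # ULDA transform

  qr_w <- qr(W)
  G <- qr.Q(qr_w)[, seq_len(q), drop = FALSE]
  flip <- apply(G, 2, function(g) sign(g[which.max(abs(g))]))
  G <- sweep(G, 2, flip, "*")

  comp <- sb$d[seq_len(q)]^2
  structure(
    list(G = G, mean = mu, n_components = q,
         criterion_value = sum(comp),
         component_values = comp,
         component_shares = comp / sum(comp),
         n_classes = k, class_levels = levels(f)),
    class = "olda"
  )
}

#' @export
print.olda <- function(x, ...) {
  cat(sprintf("<olda> %d classes, %d components (d = %d)\n",
              x$n_classes, x$n_components, nrow(x$G)))
  cat(sprintf("  criterion trace((St^L)+ Sb^L) = %.6g\n", x$criterion_value))
  cat("  component shares:",
      paste(sprintf("%.3f", x$component_shares), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.olda <- function(object, ...) {
  d <- data.frame(component = seq_len(object$n_components),
                  criterion = object$component_values,
                  share = object$component_shares,
                  cumulative = cumsum(object$component_shares))
  cat(sprintf("Orthogonal LDA: %d classes, input dimension %d\n",
              object$n_classes, nrow(object$G)))
  print(d, row.names = FALSE, digits = 4)
  invisible(d)
}

#' @export
coef.olda <- function(object, ...) object$G

#' Project spectra onto the OLDA discriminant subspace
#'
#' Centers new observations by the training global mean and projects onto
#' the orthonormal discriminant directions.
#'
#' @param object an [olda()] model.
#' @param newdata numeric matrix (samples x features) or [spectra_set()]
#'   with the model's input dimension.
#' @param ... unused.
#' @return Score matrix, samples x `n_components`, columns `OLDA1, OLDA2, ...`
#' @export
predict.olda <- function(object, newdata, ...) {
  m <- as_spectra_matrix(newdata)
  if (ncol(m) != nrow(object$G)) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(m), nrow(object$G)))
  }
  scores <- sweep(m, 2, object$mean) %*% object$G
  colnames(scores) <- paste0("OLDA", seq_len(ncol(scores)))
  scores
}

#' Pairwise score plot of OLDA components
#'
#' @param x an [olda()] model.
#' @param newdata matrix or [spectra_set()] to project and plot.
#' @param labels optional class labels used for colour; taken from
#'   `newdata$labels` when it is a labelled `spectra_set`.
#' @param components which components to plot (default first 3 available).
#' @param ... passed to [graphics::pairs()] / [graphics::plot()].
#' @return The score matrix, invisibly.
#' @export
plot.olda <- function(x, newdata, labels = NULL,
                      components = seq_len(min(3, x$n_components)), ...) {
  scores <- predict(x, newdata)
  if (is.null(labels) && inherits(newdata, "spectra_set")) {
    labels <- newdata$labels
  }
  col <- if (is.null(labels)) 1L else as.integer(as.factor(labels))
  s <- scores[, components, drop = FALSE]
  if (ncol(s) >= 3) {
    graphics::pairs(s, col = col, pch = 16, ...)
  } else {
    graphics::plot(s[, 1], if (ncol(s) > 1) s[, 2] else seq_len(nrow(s)),
                   col = col, pch = 16,
                   xlab = colnames(s)[1],
                   ylab = if (ncol(s) > 1) colnames(s)[2] else "index", ...)
  }
  invisible(scores)
}
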