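#' Parameters shared by the fuzzy clustering estimators
#'
#' @param n_clusters number of clusters `c` (default 6, one per storage day).
#' @param m fuzzifier (> 1, default 2): exponent controlling membership
#'   softness in FCM and GK.
#' @param p K-harmonic-means distance power (> 0, default 2).
#' @param max_iter maximum number of full update sweeps (default 100).
#' @param tol convergence threshold on the maximum absolute change of the
#'   cluster centers between sweeps (default 1e-5). With
#'   `conv = "memberships"` the threshold applies to the membership matrix
#'   instead.
#' @param conv convergence criterion: `"centers"` (default) or
#'   `"memberships"`.
#' @param dist_floor floor applied to squared distances (default 1e-12);
#'   distances at or below the floor trigger the coincidence rule (membership
#'   split uniformly over coincident centers).
#' @param gk_volume cluster volume `rho_i` of the Gustafson-Kessel norm
#'   constraint, recycled over clusters (default 1).
#' @param gk_reg Gustafson-Kessel covariance regularization in `[0, 1]`:
#'   blend weight toward the determinant-scaled identity (default 1e-6).
#'   `gk_reg = 1` forces an identity-shaped norm, making GK coincide with
#'   FCM.
#' @param gk_cond_max maximum condition number allowed for a fuzzy
#'   covariance matrix; smaller eigenvalues are floored (default 1e10).
#' @return A list of class `fuzzy_params`.
#' @export
fuzzy_params <- function(n_clusters = 6, m = 2, p = 2, max_iter = 100,
                         tol = 1e-5, conv = c("centers", "memberships"),
                         dist_floor = 1e-12, gk_volume = 1, gk_reg = 1e-6,
                         gk_cond_max = 1e10) {
  conv <- match.arg(conv)
  stopifnot(n_clusters >= 2, m > 1, p > 0, max_iter >= 1, tol > 0,
            dist_floor >= 0, all(gk_volume > 0),
            gk_reg >= 0, gk_reg <= 1, gk_cond_max >= 1)
  structure(list(n_clusters = as.integer(n_clusters), m = m, p = p,
                 max_iter = as.integer(max_iter), tol = tol, conv = conv,
                 dist_floor = dist_floor, gk_volume = gk_volume,
                 gk_reg = gk_reg, gk_cond_max = gk_cond_max),
            class = "fuzzy_params")
}

# squared Euclidean distances, samples x centers
sq_dist <- function(x, v) {
  d2 <- outer(rowSums(x^2), rowSums(v^2), "+") - 2 * tcrossprod(x, v)
  pmax(d2, 0)
}

# memberships (samples x centers) from a squared-distance matrix.
# 'expo' is the exponent applied to the squared-distance ratio:
#   FCM/GK: 1/(m-1);  KHM: (p+2)/2.
# Samples coinciding with one or more centers (d2 <= floor) get membership
# split uniformly over the coincident centers.
memberships_from_d2 <- function(d2, expo, floor) {
  w <- pmax(d2, max(floor, .Machine$double.xmin))^(-expo)
  u <- w / rowSums(w)
  coin <- d2 <= floor
  hit <- which(rowSums(coin) > 0)
  if (length(hit)) {
    ch <- coin[hit, , drop = FALSE]
    u[hit, ] <- ch / rowSums(ch)
  }
  u
}

#' Fuzzy C-means memberships at fixed centers
#'
#' The classical FCM update
#' `u_ik = [ sum_j (d2_ik / d2_jk)^(1/(m-1)) ]^-1` with `d2` the squared
#' Euclidean distance, floored at `dist_floor`; a sample coinciding with one
#' or more centers has its membership split uniformly over the coincident
#' centers. Every membership column sums to 1.
#'
#' @param x data matrix, samples x features.
#' @param centers center matrix, clusters x features.
#' @param m fuzzifier (> 1).
#' @param dist_floor squared-distance floor.
#' @return Membership matrix U, clusters x samples.
#' @examples
#' fcm_membership(matrix(0.25), matrix(c(0, 1)), m = 2)  # 0.9, 0.1
#' @export
fcm_membership <- function(x, centers, m = 2, dist_floor = 1e-12) {
  x <- as.matrix(x); centers <- as.matrix(centers)
  stopifnot(m > 1, nrow(centers) >= 2, ncol(x) == ncol(centers))
  if (!all(is.finite(x)) || !all(is.finite(centers))) {
    stop("inputs must be finite")
  }
  t(memberships_from_d2(sq_dist(x, centers), 1 / (m - 1), dist_floor))
}

#' K-harmonic-means memberships at fixed centers
#'
#' `m(c_j | x_i) = ||x_i - c_j||^(-p-2) / sum_l ||x_i - c_l||^(-p-2)`,
#' distances floored and the coincidence rule applied as in
#' [fcm_membership()].
#'
#' @inheritParams fcm_membership
#' @param p distance power (> 0).
#' @return Membership matrix U, clusters x samples.
#' @examples
#' fcm <- khm_membership(matrix(0), matrix(c(1, 2)), p = 2)  # 16/17, 1/17
#' @export
khm_membership <- function(x, centers, p = 2, dist_floor = 1e-12) {
  x <- as.matrix(x); centers <- as.matrix(centers)
  stopifnot(p > 0, nrow(centers) >= 2, ncol(x) == ncol(centers))
  if (!all(is.finite(x)) || !all(is.finite(centers))) {
    stop("inputs must be finite")
  }
  t(memberships_from_d2(sq_dist(x, centers), (p + 2) / 2, dist_floor))
}

#' Gustafson-Kessel fuzzy covariance matrices
#'
#' `F_i = sum_k u_ik^m (x_k - v_i)(x_k - v_i)' / sum_k u_ik^m`, followed by
#' the regularization used throughout the GK estimator: a `gk_reg` blend
#' toward the determinant-scaled identity and an eigenvalue floor keeping
#' the condition number at or below `gk_cond_max`.
#'
#' @param x data matrix, samples x features.
#' @param U membership matrix, clusters x samples.
#' @param V center matrix, clusters x features.
#' @param m fuzzifier.
#' @param gk_reg blend weight toward the determinant-scaled identity.
#' @param gk_cond_max maximum condition number.
#' @return List of symmetric positive-definite covariance matrices, one per
#'   cluster.
#' @export
gk_covariance <- function(x, U, V, m = 2, gk_reg = 1e-6, gk_cond_max = 1e10) {
  x <- as.matrix(x); U <- as.matrix(U); V <- as.matrix(V)
  nc <- nrow(V); q <- ncol(x)
  stopifnot(nrow(U) == nc, ncol(U) == nrow(x), ncol(V) == q)
  lapply(seq_len(nc), function(i) {
    um <- U[i, ]^m
    tot <- sum(um)
    if (tot <= .Machine$double.eps * ncol(U)) {
      stop(sprintf("cluster collapse: cluster %d has (near-)zero total membership", i))
    }
    diff <- sweep(x, 2, V[i, ])
    F_i <- crossprod(diff * um, diff) / tot
    regularize_cov(F_i, gk_reg, gk_cond_max)
  })
}

# blend toward det-scaled identity, then floor eigenvalues
regularize_cov <- function(F_i, gk_reg, gk_cond_max) {
  q <- ncol(F_i)
  F_i <- (F_i + t(F_i)) / 2
  detF <- det(F_i)
  s <- if (is.finite(detF) && detF > 0) detF^(1 / q) else mean(diag(F_i))
  if (!is.finite(s) || s <= 0) s <- 1
  F_i <- (1 - gk_reg) * F_i + gk_reg * s * diag(q)
  e <- eigen(F_i, symmetric = TRUE)
  lmax <- max(e$values)
  if (lmax <= 0) stop("cluster collapse: fuzzy covariance is not positive")
  vals <- pmax(e$values, lmax / gk_cond_max)
  F_i <- e$vectors %*% (vals * t(e$vectors))
  (F_i + t(F_i)) / 2
}

# GK adaptive norms A_i = (rho_i det(F_i))^(1/q) F_i^-1 and the induced
# squared distances (samples x clusters)
gk_norms <- function(Fs, rho) {
  q <- ncol(Fs[[1]])
  rho <- rep_len(rho, length(Fs))
  lapply(seq_along(Fs), function(i) {
    e <- eigen(Fs[[i]], symmetric = TRUE)
    detF <- prod(e$values)
    A <- e$vectors %*% ((1 / e$values) * t(e$vectors))
    (rho[i] * detF)^(1 / q) * A
  })
}

gk_sq_dist <- function(x, V, As) {
  n <- nrow(x)
  d2 <- matrix(0, n, nrow(V))
  for (i in seq_len(nrow(V))) {
    diff <- sweep(x, 2, V[i, ])
    d2[, i] <- pmax(rowSums((diff %*% As[[i]]) * diff), 0)
  }
  d2
}

#' Fit a fuzzy partition by FCM, K-harmonic means or Gustafson-Kessel
#'
#' All three estimators alternate a membership update and a center update
#' from user-supplied initial centers, stopping when the maximum absolute
#' center change falls below `params$tol` or after `params$max_iter` sweeps.
#' One iteration is one full sweep; convergence is checked after the sweep,
#' so a fit initialized at a fixed point reports `n_iter = 1`.
#'
#' * `"fcm"`: memberships per [fcm_membership()]; centers are the
#'   `u^m`-weighted means; objective `J = sum u^m d2` (non-increasing).
#' * `"khm"`: memberships per [khm_membership()]; centers use the harmonic
#'   boosting weights `w_i = sum_l d_il^(-p-2) / (sum_l d_il^(-p))^2`;
#'   objective `sum_i c / sum_j d_ij^(-p)` (the harmonic-mean loss).
#' * `"gk"`: centers as FCM; per-cluster fuzzy covariances
#'   ([gk_covariance()]) define adaptive Mahalanobis norms
#'   `A_i = (rho_i det F_i)^(1/q) F_i^-1` under the fixed-volume constraint;
#'   memberships use the induced distances; objective `sum u^m d2_A`. The
#'   first sweep uses Euclidean distances (identity norm) since no
#'   memberships exist yet.
#'
#' @param x data matrix (samples x features), e.g. OLDA scores.
#' @param centers initial center matrix, `n_clusters` x features.
#' @param method `"fcm"`, `"khm"` or `"gk"`.
#' @param params a [fuzzy_params()]; `params$n_clusters` must match
#'   `nrow(centers)`.
#' @param keep_history if `TRUE`, store the membership matrix of every sweep
#'   in `$u_history` (for diagnostics).
#' @return An object of class `fuzzy_partition`: list with membership matrix
#'   `U` (clusters x samples, columns summing to 1, evaluated at the returned
#'   centers), centers `V`, `method`,
#'   `n_iter`, `objective` (per-sweep trace), `converged`, `params`, and for
#'   GK the covariances `covariances` and norms `norms`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 5), 20))
#' fit <- fuzzy_cluster(x, x[c(1, 21), ], method = "fcm",
#'                      params = fuzzy_params(n_clusters = 2))
#' table(fitted(fit), rep(1:2, each = 20))
#' @export
fuzzy_cluster <- function(x, centers, method = c("fcm", "khm", "gk"),
                          params = fuzzy_params(), keep_history = FALSE) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  V <- as.matrix(centers)
  storage.mode(V) <- "double"
  if (!all(is.finite(x)) || !all(is.finite(V))) stop("inputs must be finite")
  nc <- nrow(V)
  if (nc < 2) stop("need at least 2 clusters")
  if (nc != params$n_clusters) {
    stop("nrow(centers) must equal params$n_clusters")
  }
  if (ncol(V) != ncol(x)) stop("centers and data dimension mismatch")
  n <- nrow(x)
  if (method == "gk" && n <= nc) {
    stop("Gustafson-Kessel needs more samples than clusters")
  }

  m <- params$m; p <- params$p; floor_ <- params$dist_floor
  expo <- if (method == "khm") (p + 2) / 2 else 1 / (m - 1)
  As <- NULL            # GK norms; identity on the first sweep
  Fs <- NULL
  U <- NULL
  objective <- numeric(0)
  converged <- FALSE
  u_history <- if (keep_history) list()
  n_iter <- 0L

  for (it in seq_len(params$max_iter)) {
    d2 <- if (method == "gk" && !is.null(As)) gk_sq_dist(x, V, As)
          else sq_dist(x, V)
    U_new <- memberships_from_d2(d2, expo, floor_)      # samples x clusters

    if (method == "khm") {
      d2f <- pmax(d2, max(floor_, .Machine$double.xmin))
      inv_p <- rowSums(d2f^(-p / 2))                    # sum_l d^-p
      w <- rowSums(d2f^(-(p + 2) / 2)) / inv_p^2        # boosting weights
      uw <- U_new * w
      V_new <- crossprod(uw, x) / colSums(uw)
    } else {
      um <- U_new^m
      tot <- colSums(um)
      if (any(tot <= .Machine$double.eps * n)) {
        stop(sprintf("cluster collapse: cluster %d has (near-)zero total membership",
                     which.min(tot)))
      }
      V_new <- crossprod(um, x) / tot
    }

    if (method == "gk") {
      Fs <- gk_covariance(x, t(U_new), V_new, m = m, gk_reg = params$gk_reg,
                          gk_cond_max = params$gk_cond_max)
      As <- gk_norms(Fs, params$gk_volume)
      d2_obj <- gk_sq_dist(x, V_new, As)
      objective <- c(objective, sum(U_new^m * d2_obj))
    } else if (method == "khm") {
      d2_new <- pmax(sq_dist(x, V_new), max(floor_, .Machine$double.xmin))
      objective <- c(objective, sum(nc / rowSums(d2_new^(-p / 2))))
    } else {
      d2_obj <- sq_dist(x, V_new)
      objective <- c(objective, sum(U_new^m * pmax(d2_obj, floor_)))
    }

    if (keep_history) u_history[[it]] <- t(U_new)
    n_iter <- it
    delta <- if (params$conv == "centers" || is.null(U)) {
      max(abs(V_new - V))
    } else {
      max(abs(U_new - U))
    }
    if (params$conv == "memberships" && is.null(U)) delta <- Inf
    U <- U_new
    V <- V_new
    if (delta < params$tol) { converged <- TRUE; break }
  }

  # re-evaluate memberships at the returned centers (and norms), so that U
  # and V are mutually consistent and predict() reproduces U exactly
  d2_fin <- if (method == "gk" && !is.null(As)) gk_sq_dist(x, V, As)
            else sq_dist(x, V)
  U <- memberships_from_d2(d2_fin, expo, floor_)

  structure(
    list(U = t(U), V = V, method = method, n_iter = n_iter,
         objective = objective, converged = converged, params = params,
         covariances = Fs, norms = As, n = n,
         u_history = u_history),
    class = "fuzzy_partition"
  )
}

#' Hard labels from a fuzzy partition
#'
#' Assigns each sample to the cluster with the largest membership; ties are
#' broken by the lowest cluster index.
#'
#' @param U membership matrix (clusters x samples) or a `fuzzy_partition`.
#' @return Integer vector of cluster assignments, one per sample.
#' @export
assign_labels <- function(U) {
  if (inherits(U, "fuzzy_partition")) U <- U$U
  U <- as.matrix(U)
  apply(U, 2, which.max)
}

#' @export
fitted.fuzzy_partition <- function(object, ...) assign_labels(object)

#' Memberships of new samples under a fitted partition
#'
#' Evaluates the partition's membership formula at the stored centers (and,
#' for Gustafson-Kessel, the stored adaptive norms) without iterating.
#'
#' @param object a [fuzzy_cluster()] fit.
#' @param newdata matrix of samples in the clustered feature space.
#' @param ... unused.
#' @return Membership matrix, clusters x new samples.
#' @export
predict.fuzzy_partition <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != ncol(object$V)) stop("feature dimension mismatch")
  p <- object$params
  d2 <- if (object$method == "gk" && !is.null(object$norms)) {
    gk_sq_dist(x, object$V, object$norms)
  } else {
    sq_dist(x, object$V)
  }
  expo <- if (object$method == "khm") (p$p + 2) / 2 else 1 / (p$m - 1)
  t(memberships_from_d2(d2, expo, p$dist_floor))
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> %s: %d clusters, %d samples\n",
              toupper(x$method), nrow(x$U), ncol(x$U)))
  cat(sprintf("  %d iteration(s), %s (final objective %.6g)\n", x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$objective[length(x$objective)]))
  invisible(x)
}

#' @export
summary.fuzzy_partition <- function(object, ...) {
  lab <- assign_labels(object)
  cat(sprintf("%s partition of %d samples into %d clusters\n",
              toupper(object$method), ncol(object$U), nrow(object$U)))
  cat(sprintf("  iterations: %d (%s)\n", object$n_iter,
              if (object$converged) "converged" else "not converged"))
  cat("  cluster sizes (hard):",
      paste(tabulate(lab, nrow(object$U)), collapse = ", "), "\n")
  cat("  mean max-membership:", sprintf("%.3f", mean(apply(object$U, 2, max))),
      "\n")
  invisible(object)
}

#' Membership-profile plot
#'
#' One panel per cluster, plotting that cluster's membership value against
#' the sample index (the standard fuzzy-membership diagnostic figure).
#'
#' @param x a [fuzzy_cluster()] fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fuzzy_partition <- function(x, ...) {
  nc <- nrow(x$U)
  op <- graphics::par(mfrow = c(nc, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nc)) {
    graphics::plot(x$U[i, ], type = "h", ylim = c(0, 1),
                   ylab = sprintf("u[%d,]", i), xlab = "", ...)
  }
  invisible(x)
}
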