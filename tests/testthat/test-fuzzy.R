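test_that("FCM memberships match hand-evaluated values", {
  # 1-D, centers {0, 1}, x = 0.25, m = 2: d2 = (0.0625, 0.5625) -> (0.9, 0.1)
  u <- fcm_membership(matrix(0.25), matrix(c(0, 1)), m = 2)
  expect_equal(drop(u), c(0.9, 0.1), tolerance = 1e-12)

  # equidistant sample splits evenly
  u2 <- fcm_membership(matrix(0.5), matrix(c(0, 1)), m = 2)
  expect_equal(drop(u2), c(0.5, 0.5), tolerance = 1e-12)

  # coincidence rule: a sample at a center gets crisp membership
  u3 <- fcm_membership(matrix(c(0, 0), 1), rbind(c(0, 0), c(1, 0), c(0, 2)),
                       m = 2)
  expect_equal(drop(u3), c(1, 0, 0))
})

test_that("KHM memberships match the negative-power formula", {
  # distances (1, 2), p = 2: 1 / (1 + 2^-4) = 16/17
  u <- khm_membership(matrix(0), matrix(c(1, 2)), p = 2)
  expect_equal(drop(u), c(16 / 17, 1 / 17), tolerance = 1e-12)

  u2 <- khm_membership(matrix(0), matrix(c(-3, 3)), p = 2)
  expect_equal(drop(u2), c(0.5, 0.5), tolerance = 1e-12)

  # large p: membership of the nearest center tends to 1
  u3 <- khm_membership(matrix(0), matrix(c(1, 2)), p = 50)
  expect_gt(u3[1, 1], 1 - 1e-7)
})

test_that("memberships at fixed centers match direct formula evaluation", {
  set.seed(10)
  for (rep in 1:5) {
    x <- matrix(rnorm(24), 12, 2)
    v <- matrix(rnorm(4), 2, 2)
    d2 <- as.matrix(dist(rbind(x, v)))[1:12, 13:14]^2
    m <- 2; p <- 2
    u_fcm_direct <- t(1 / (d2 * rowSums(1 / d2)))
    expect_equal(fcm_membership(x, v, m = m), u_fcm_direct,
                 tolerance = 1e-12, ignore_attr = TRUE)
    w <- d2^(-(p + 2) / 2)
    expect_equal(khm_membership(x, v, p = p), t(w / rowSums(w)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("FCM recovers separated blobs and detects fixed points", {
  blobs <- make_blobs(20, rbind(c(0, 0), c(6, 6)), sd = 0.3, seed = 11)
  params <- fuzzy_params(n_clusters = 2)
  fit <- fuzzy_cluster(blobs$x, blobs$x[c(1, 21), ], "fcm", params = params)
  expect_true(fit$converged)
  true_means <- rbind(colMeans(blobs$x[1:20, ]), colMeans(blobs$x[21:40, ]))
  expect_equal(fit$V, true_means, tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(matched_accuracy(assign_labels(fit), blobs$labels), 100)

  # restarting at the converged solution terminates after one sweep
  refit <- fuzzy_cluster(blobs$x, fit$V, "fcm", params = params)
  expect_equal(refit$n_iter, 1)
  expect_true(refit$converged)

  expect_error(fuzzy_params(n_clusters = 1))
})

test_that("the FCM objective is non-increasing", {
  set.seed(12)
  for (rep in 1:5) {
    x <- matrix(rnorm(60 * 3), 60, 3)
    init <- x[sample(60, 3), ]
    fit <- fuzzy_cluster(x, init, "fcm",
                         params = fuzzy_params(n_clusters = 3, tol = 1e-8))
    expect_true(all(diff(fit$objective) <= 1e-10))
  }
})

test_that("KHM fits blobs, detects fixed points and survives degeneracy", {
  blobs <- make_blobs(20, rbind(c(0, 0), c(6, 6)), sd = 0.3, seed = 13)
  params <- fuzzy_params(n_clusters = 2)
  fit <- fuzzy_cluster(blobs$x, blobs$x[c(1, 21), ], "khm", params = params)
  true_means <- rbind(colMeans(blobs$x[1:20, ]), colMeans(blobs$x[21:40, ]))
  expect_equal(fit$V, true_means, tolerance = 0.05, ignore_attr = TRUE)

  refit <- fuzzy_cluster(blobs$x, fit$V, "khm", params = params)
  expect_equal(refit$n_iter, 1)

  # one point duplicated: both centers collapse onto it
  x0 <- matrix(rep(c(2, -1), each = 10), 10)
  fit0 <- fuzzy_cluster(x0, rbind(c(0, 0), c(5, 5)), "khm", params = params)
  expect_equal(fit0$V[1, ], c(2, -1), tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(fit0$V[2, ], c(2, -1), tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("GK covariances reduce to weighted scatter and spot isotropy", {
  # two points, equal unit memberships: F = mean outer product of deviations
  x <- rbind(c(1, 0), c(3, 2))
  U <- matrix(1, 1, 2)
  V <- matrix(colMeans(x), 1)
  Fs <- gk_covariance(x, U, V, m = 2, gk_reg = 0)
  hand <- (outer(c(-1, -1), c(-1, -1)) + outer(c(1, 1), c(1, 1))) / 2
  # the singular hand matrix gets its smallest eigenvalue floored at
  # lambda_max / cond_max, a ~1e-10 perturbation
  expect_equal(Fs[[1]], hand, tolerance = 1e-9)

  # crisp memberships: each F is its cluster's scatter matrix / n
  blobs <- make_blobs(30, rbind(c(0, 0), c(8, 0)), sd = 0.5, seed = 14)
  U2 <- rbind(as.numeric(blobs$labels == 1), as.numeric(blobs$labels == 2))
  V2 <- rbind(colMeans(blobs$x[1:30, ]), colMeans(blobs$x[31:60, ]))
  Fs2 <- gk_covariance(blobs$x, U2, V2, m = 2, gk_reg = 0)
  d1 <- sweep(blobs$x[1:30, ], 2, V2[1, ])
  expect_equal(Fs2[[1]], crossprod(d1) / 30, tolerance = 1e-10)

  # isotropic data: F close to a scalar multiple of the identity
  iso <- make_blobs(400, matrix(c(0, 0), 1), sd = 1, seed = 15)
  U3 <- matrix(1, 1, 400)
  F3 <- gk_covariance(iso$x, U3, matrix(colMeans(iso$x), 1), m = 2)[[1]]
  expect_lt(abs(F3[1, 2]) / mean(diag(F3)), 0.15)
  expect_lt(abs(F3[1, 1] - F3[2, 2]) / mean(diag(F3)), 0.2)

  # a cluster with no membership mass is a collapse
  expect_error(gk_covariance(blobs$x, U2 * c(0, 1), V2, m = 2), "collapse")
})

test_that("GK recovers elongated clusters that defeat FCM", {
  set.seed(16)
  n <- 150
  a <- cbind(rnorm(n, 0, 6), rnorm(n, 0, 0.3))
  b <- cbind(rnorm(n, 0, 6), rnorm(n, 3, 0.3))
  x <- rbind(a, b)
  lab <- rep(1:2, each = n)
  init <- rbind(c(-5, 1.5), c(5, 1.5))  # split along the long axis
  params <- fuzzy_params(n_clusters = 2)
  acc_fcm <- matched_accuracy(assign_labels(
    fuzzy_cluster(x, init, "fcm", params = params)), lab)
  acc_gk <- matched_accuracy(assign_labels(
    fuzzy_cluster(x, init, "gk", params = params)), lab)
  expect_lt(acc_fcm, 90)
  expect_gte(acc_gk, 99)
})

test_that("GK with an identity norm reproduces FCM exactly", {
  blobs <- make_blobs(25, rbind(c(0, 0), c(3, 0), c(0, 3)), sd = 0.6,
                      seed = 17)
  init <- blobs$x[c(1, 26, 51), ]
  p_fcm <- fuzzy_params(n_clusters = 3)
  p_id <- fuzzy_params(n_clusters = 3, gk_reg = 1)  # full blend to identity
  f1 <- fuzzy_cluster(blobs$x, init, "fcm", params = p_fcm)
  f2 <- fuzzy_cluster(blobs$x, init, "gk", params = p_id)
  expect_equal(f1$n_iter, f2$n_iter)
  expect_lt(max(abs(f1$U - f2$U)), 1e-8)
  expect_equal(f1$V, f2$V, tolerance = 1e-8)
})

test_that("membership columns always sum to one, at every sweep", {
  set.seed(18)
  for (method in c("fcm", "khm", "gk")) {
    x <- matrix(rnorm(80 * 3), 80, 3)
    fit <- fuzzy_cluster(x, x[1:4, ], method,
                         params = fuzzy_params(n_clusters = 4),
                         keep_history = TRUE)
    for (U in fit$u_history) {
      expect_equal(colSums(U), rep(1, 80), tolerance = 1e-8)
      expect_true(all(U >= 0 & U <= 1))
    }
  }
})

test_that("hard assignment follows maximum membership with low-index ties", {
  expect_equal(assign_labels(matrix(c(0.9, 0.1), 2)), 1)
  expect_equal(assign_labels(matrix(c(0.5, 0.5), 2)), 1)
  U <- rbind(c(1, 0, 0.2), c(0, 1, 0.8))
  expect_equal(assign_labels(U), c(1, 2, 2))
})

test_that("predict reproduces the final training memberships", {
  blobs <- make_blobs(15, rbind(c(0, 0), c(5, 5)), sd = 0.4, seed = 19)
  for (method in c("fcm", "khm", "gk")) {
    fit <- fuzzy_cluster(blobs$x, blobs$x[c(1, 16), ], method,
                         params = fuzzy_params(n_clusters = 2))
    expect_equal(predict(fit, blobs$x), fit$U, tolerance = 1e-12)
  }
})
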