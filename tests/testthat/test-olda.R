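test_that("scatter matrices match the hand-evaluated sums", {
  x <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  sm <- scatter_matrices(x, c(1, 1, 2, 2))
  expect_equal(sm$global_mean, c(1, 1))
  expect_equal(sm$Sb, rbind(c(0, 0), c(0, 4)))
  expect_equal(sm$Sw, rbind(c(4, 0), c(0, 0)))
  expect_equal(sm$St, sm$Sb + sm$Sw)
})

test_that("degenerate scatter configurations behave as defined", {
  # each class a single point: no within-class spread
  x <- rbind(c(0, 1), c(3, 5), c(-2, 2))
  sm <- scatter_matrices(x, 1:3)
  expect_equal(sm$Sw, matrix(0, 2, 2))
  # all samples identical: every scatter matrix vanishes
  sm0 <- scatter_matrices(matrix(1, 6, 2), rep(1:2, 3))
  expect_equal(sm0$Sb, matrix(0, 2, 2))
  expect_equal(sm0$St, matrix(0, 2, 2))
  # error cases
  expect_error(scatter_matrices(matrix(1:4, 2), c(1, 1)), "two classes")
})

test_that("scatter matrices are PSD and satisfy St = Sb + Sw on random data", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(20:60, 1); d <- sample(2:6, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * d), n, d)
    lab <- sample(rep(seq_len(k), length.out = n))
    sm <- scatter_matrices(x, lab)
    expect_equal(sm$St, sm$Sb + sm$Sw, tolerance = 1e-8)
    expect_gte(min(eigen(sm$Sb, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_gte(min(eigen(sm$Sw, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_lte(qr(sm$Sb)$rank, k - 1)
  }
})

test_that("projection columns are orthonormal and capped at k - 1", {
  set.seed(4)
  x <- matrix(rnorm(90 * 8), 90, 8)
  lab <- rep(1:3, each = 30)
  x[lab == 2, 1] <- x[lab == 2, 1] + 3
  x[lab == 3, 2] <- x[lab == 3, 2] + 3
  fit <- olda(x, lab)
  expect_equal(fit$n_components, 2)
  expect_equal(crossprod(fit$G), diag(2), tolerance = 1e-8)
  expect_equal(sum(fit$component_shares), 1, tolerance = 1e-12)
  expect_error(olda(x, lab, n_components = 3), "k - 1")

  # two classes: a single direction regardless of dimension
  fit2 <- olda(x, as.integer(lab == 1) + 1L)
  expect_equal(fit2$n_components, 1)
})

test_that("OLDA agrees with a classical LDA eigen-solve when Sw is regular", {
  set.seed(5)
  x <- matrix(rnorm(60 * 3), 60, 3)
  lab <- rep(1:3, each = 20)
  x[lab == 2, 1] <- x[lab == 2, 1] + 4
  x[lab == 3, 2] <- x[lab == 3, 2] + 4
  fit <- olda(x, lab)

  sm <- scatter_matrices(x, lab)
  W <- Re(eigen(solve(sm$Sw) %*% sm$Sb)$vectors[, 1:2])
  Qw <- qr.Q(qr(W))
  # principal angles between the two 2-D subspaces are ~0
  cosines <- svd(crossprod(Qw, fit$G))$d
  expect_equal(cosines, c(1, 1), tolerance = 1e-6)

  # and the pseudo-inverse criterion matches the classical trace
  SbL <- t(W) %*% sm$Sb %*% W
  StL <- t(W) %*% sm$St %*% W
  expect_equal(fit$criterion_value, sum(diag(solve(StL) %*% SbL)),
               tolerance = 1e-8)
})

test_that("scores are centered and reproduce the criterion", {
  set.seed(6)
  x <- matrix(rnorm(80 * 6), 80, 6)
  lab <- rep(1:4, each = 20)
  for (c in 2:4) x[lab == c, c - 1] <- x[lab == c, c - 1] + 3
  fit <- olda(x, lab)
  # the training global mean projects to the origin
  expect_equal(drop(predict(fit, matrix(fit$mean, 1))), rep(0, 3),
               tolerance = 1e-10, ignore_attr = TRUE)
  # recomputing the trace criterion on the projected scores recovers it
  sc <- predict(fit, x)
  smL <- scatter_matrices(sc, lab)
  expect_equal(sum(diag(solve(smL$St) %*% smL$Sb)), fit$criterion_value,
               tolerance = 1e-8)
  expect_error(predict(fit, x[, 1:3]), "expects")
})

test_that("a separable two-class problem is split by the score sign", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40, -4, 0.5), 20), matrix(rnorm(40, 4, 0.5), 20))
  lab <- rep(1:2, each = 20)
  fit <- olda(x, lab, n_components = 1)
  sc <- drop(predict(fit, x))
  expect_true(all(tapply(sign(sc), lab, function(s) length(unique(s))) == 1))
  expect_equal(sum(sign(sc[lab == 1])[1] == sign(sc)), 20)
})

test_that("scores are invariant under feature permutation up to sign", {
  set.seed(8)
  x <- matrix(rnorm(60 * 5), 60, 5)
  lab <- rep(1:3, each = 20)
  x[lab == 2, 1] <- x[lab == 2, 1] + 2
  x[lab == 3, 3] <- x[lab == 3, 3] + 2
  perm <- c(4, 2, 5, 1, 3)
  f1 <- olda(x, lab)
  f2 <- olda(x[, perm], lab)
  s1 <- predict(f1, x)
  s2 <- predict(f2, x[, perm])
  for (j in 1:2) {
    expect_true(max(abs(s1[, j] - s2[, j])) < 1e-8 ||
                  max(abs(s1[, j] + s2[, j])) < 1e-8)
  }
})

test_that("rank-deficient between-class scatter reduces the component count", {
  # class means exactly collinear by construction: rank(Sb) = 1, k - 1 = 2
  pat <- rbind(c(0.1, 0), c(-0.1, 0), c(0, 0.1), c(0, -0.1))
  base <- rbind(pat, sweep(pat, 2, c(5, 0), "+"), sweep(pat, 2, c(10, 0), "+"))
  lab <- rep(1:3, each = 4)
  expect_warning(fit <- olda(base, lab, n_components = 2), "rank")
  expect_equal(fit$n_components, 1)
})
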