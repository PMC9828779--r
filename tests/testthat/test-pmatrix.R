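test_that("estimate_pmatrix is the n-1 sample covariance with guards", {
  P <- estimate_pmatrix(rbind(c(0, 0), c(2, 2), c(1, 1)))
  expect_equal(unname(P$cov), matrix(1, 2, 2))
  # the spec's two-point hand example (n-1 = 1)
  X2 <- rbind(c(0, 0), c(2, 2))
  expect_equal(unname(cov(X2)), matrix(2, 2, 2))
  expect_error(estimate_pmatrix(X2), "at least 3")
  set.seed(1)
  X <- matrix(rnorm(50), 10, 5)
  P2 <- estimate_pmatrix(X)
  expect_equal(P2$cov, t(P2$cov))
  expect_true(all(diag(P2$cov) >= 0))
  expect_error(estimate_pmatrix(rbind(c(1, NA), c(1, 2), c(0, 1))), "missing")
})

test_that("sample covariance is consistent for a known MVN", {
  set.seed(3)
  Sigma <- matrix(c(4, 1.5, 0.5, 1.5, 2, -0.3, 0.5, -0.3, 1), 3, 3)
  X <- MASS::mvrnorm(1e5, rep(0, 3), Sigma)
  P <- estimate_pmatrix(X)
  expect_lt(max(abs(P$cov - Sigma)), 0.05 * max(abs(Sigma)))
})

test_that("leading_eigenvector satisfies the eigen identity and conventions", {
  le <- leading_eigenvector(diag(c(3, 1)))
  expect_equal(le$vector, c(1, 0))
  expect_equal(le$value, 3)
  expect_warning(leading_eigenvector(diag(2)), "unstable")
  set.seed(4)
  A <- crossprod(matrix(rnorm(100), 10, 10)) + diag(10)
  le2 <- leading_eigenvector(A)
  expect_lt(max(abs(A %*% le2$vector - le2$value * le2$vector)), 1e-9)
  expect_equal(sum(le2$vector^2), 1, tolerance = 1e-12)
  expect_gt(le2$vector[which.max(abs(le2$vector))], 0)
})

test_that("theta_angle reproduces closed-form cases and is sign-invariant", {
  expect_equal(theta_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(theta_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(theta_angle(c(1, 0), c(-1, 0)), 0)
  expect_equal(theta_angle(c(1, 0), c(1, 1) / sqrt(2)), 45)
  expect_error(theta_angle(c(0, 0), c(1, 0)), "zero vector")
  expect_error(theta_angle(c(1, 0), c(1, 0, 0)), "equal dimension")
  # non-unit vectors: product normalization handles lengths
  expect_equal(theta_angle(c(3, 0), c(0, 0.5)), 90)
  # literal sum-of-norms variant differs (sensitivity flag only)
  expect_gt(theta_angle(c(1, 0), c(1, 0), literal_sum = TRUE), 0)
})

test_that("riemannian distance matches a Cholesky-whitening oracle", {
  expect_equal(pmatrix_distance(diag(2), diag(c(exp(2), 1))), 2)
  set.seed(6)
  for (i in 1:5) {
    A <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
    B <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
    expect_equal(pmatrix_distance(A, A), 0, tolerance = 1e-7)
    # oracle via Cholesky whitening (independent route)
    L <- chol(A)
    M <- solve(t(L)) %*% B %*% solve(L)
    oracle <- sqrt(sum(log(eigen(M, symmetric = TRUE,
                                 only.values = TRUE)$values)^2))
    expect_equal(pmatrix_distance(A, B), oracle, tolerance = 1e-8)
    # symmetry and invariance under a common invertible transform
    expect_equal(pmatrix_distance(A, B), pmatrix_distance(B, A),
                 tolerance = 1e-8)
    T <- matrix(rnorm(36), 6, 6) + diag(6)
    expect_equal(pmatrix_distance(T %*% A %*% t(T), T %*% B %*% t(T)),
                 pmatrix_distance(A, B), tolerance = 1e-7)
  }
  expect_error(pmatrix_distance(diag(2), diag(3)), "same dimension")
})

test_that("mean Mahalanobis distance option uses the pooled covariance", {
  P1 <- estimate_pmatrix(MASS::mvrnorm(50, rep(0, 3), diag(3)))
  P2 <- estimate_pmatrix(MASS::mvrnorm(50, rep(0, 3), diag(3)))
  mu1 <- c(1, 0, 0); mu2 <- c(0, 0, 0)
  d <- pmatrix_distance(P1, P2, "mean_mahalanobis", mu1 = mu1, mu2 = mu2)
  Sp <- (49 * P1$cov + 49 * P2$cov) / 98
  expect_equal(d, sqrt(drop(t(mu1 - mu2) %*% solve(Sp) %*% (mu1 - mu2))),
               tolerance = 1e-10)
  expect_error(pmatrix_distance(P1, P2, "mean_mahalanobis"), "requires")
})

test_that("bootstrap_compare is reproducible and null on identical samples", {
  set.seed(10)
  X <- MASS::mvrnorm(80, rep(0, 4), diag(c(5, 2, 1, 0.5)))
  r1 <- bootstrap_compare(X, X, "theta", n_boot = 300, seed = 99)
  expect_equal(r1$observed, 0)
  expect_false(r1$significant)
  expect_equal(r1$p_value, 1)          # every null angle >= 0 = observed
  r2 <- bootstrap_compare(X, X, "theta", n_boot = 300, seed = 99)
  expect_identical(r1, r2)             # bit-reproducible given seed
  expect_error(bootstrap_compare(X, X, "theta", n_boot = 300), "seed")
  expect_warning(bootstrap_compare(X, X, "theta", n_boot = 50, seed = 1),
                 "unstable")
})

test_that("strongly divergent eigenstructure is detected by the bootstrap", {
  sim <- simulate_two_populations(200, 90, eigen_spectrum = c(10, 1, 0.5),
                                  seed = 12)
  r <- bootstrap_compare(sim$XA, sim$XB, "theta", n_boot = 500, seed = 12)
  expect_true(r$significant)
  expect_lt(r$p_value, 0.05)
  rd <- bootstrap_compare(sim$XA, sim$XB, "distance", n_boot = 500, seed = 12)
  expect_gt(rd$observed, 0)
})
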