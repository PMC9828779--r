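test_that("reflect_config mirrors x, toggles the flag, and is an involution", {
  s <- landmark_set("a", rbind(c(1, 2), c(-3, 4)))
  r <- reflect_config(s)
  expect_equal(r$coords, rbind(c(-1, 2), c(3, 4)))
  expect_true(r$flipped)
  expect_equal(reflect_config(r)$coords, s$coords)
  expect_false(reflect_config(r)$flipped)
  # reflection is an isometry: wing length unchanged
  expect_equal(wing_length(r, 1, 2), wing_length(s, 1, 2))
})

test_that("reflected mirror images align to originals under GPA", {
  set.seed(11)
  base <- random_landmark_sets(4, k = 23)
  mirrored <- lapply(base, function(s) {
    m <- s
    m$coords[, 1] <- -m$coords[, 1]           # digitized from the other side
    m$specimen_id <- paste0(s$specimen_id, "_m")
    m
  })
  fixed <- lapply(mirrored, reflect_config)
  g <- generalized_procrustes(c(base, fixed))
  n <- length(base)
  for (i in seq_len(n))
    expect_lt(sum((g$aligned[i, ] - g$aligned[n + i, ])^2), 1e-16)
})

test_that("GPA removes similarity transforms and finds exact alignment", {
  set.seed(5)
  a <- matrix(rnorm(46), 23, 2)
  cfgs <- list(landmark_set("orig", a),
               landmark_set("copy", a),
               landmark_set("moved", similarity_transform(a)))
  g <- generalized_procrustes(cfgs)
  expect_true(g$converged)
  expect_lt(sum((g$aligned[1, ] - g$aligned[2, ])^2), 1e-18)
  expect_lt(sum((g$aligned[1, ] - g$aligned[3, ])^2), 1e-16)
  # aligned configurations are centered with unit centroid size
  for (i in 1:3) {
    m <- matrix(g$aligned[i, ], 23, 2, byrow = TRUE)
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sum(m^2), 1, tolerance = 1e-9)
  }
  expect_error(generalized_procrustes(list(cfgs[[1]])), "at least 2")
  expect_error(generalized_procrustes(
    list(cfgs[[1]], landmark_set("bad", matrix(0, 23, 2)))), "degenerate")
  expect_error(generalized_procrustes(
    list(cfgs[[1]], landmark_set("short", matrix(rnorm(10), 5, 2)))),
    "same number of landmarks")
})

test_that("GPA matches an alternating-minimization oracle built on vegan", {
  skip_if_not_installed("vegan")
  set.seed(21)
  consensus0 <- matrix(rnorm(46), 23, 2)
  cfgs <- lapply(1:5, function(i) {
    landmark_set(paste0("s", i),
                 similarity_transform(consensus0 + matrix(rnorm(46, sd = 0.1), 23, 2)))
  })
  g <- generalized_procrustes(cfgs, tol = 1e-12)
  ours <- sum(vapply(seq_len(5), function(i) {
    m <- matrix(g$aligned[i, ], 23, 2, byrow = TRUE)
    sum((m - g$consensus)^2)
  }, numeric(1)))

  # oracle: same objective, rotations from vegan's pairwise Procrustes
  mats <- lapply(cfgs, function(s) {
    co <- sweep(s$coords, 2, colMeans(s$coords))
    co / sqrt(sum(co^2))
  })
  cons <- mats[[1]]
  for (it in 1:200) {
    mats <- lapply(mats, function(m)
      m %*% vegan::procrustes(cons, m, scale = FALSE)$rotation)
    new_cons <- Reduce(`+`, mats) / length(mats)
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    if (sum((new_cons - cons)^2) < 1e-24) { cons <- new_cons; break }
    cons <- new_cons
  }
  oracle <- sum(vapply(mats, function(m) sum((m - cons)^2), numeric(1)))
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("GPA output is invariant to random pre-transformations", {
  set.seed(31)
  cfgs <- random_landmark_sets(6, k = 11)
  g1 <- generalized_procrustes(cfgs, tol = 1e-12)
  moved <- lapply(cfgs, function(s)
    landmark_set(s$specimen_id, similarity_transform(s$coords)))
  g2 <- generalized_procrustes(moved, tol = 1e-12)
  # shapes identical up to one global rotation: align consensus to consensus
  d1 <- as.dist(as.matrix(dist(g1$aligned)))
  d2 <- as.dist(as.matrix(dist(g2$aligned)))
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-6)
})

test_that("wing_length is the Euclidean distance between two raw landmarks", {
  co <- matrix(0, 5, 2); co[4, ] <- c(3, 4)
  s <- landmark_set("w", co)
  expect_equal(wing_length(s), 5)
  expect_equal(wing_length(s, 1, 2), 0)      # coincident landmarks
  expect_error(wing_length(s, 1, 9), "out of range")
})

test_that("size_correct returns OLS residuals with the stated properties", {
  size <- c(1, 2, 3, 4)
  # trait exactly proportional to size -> zero residuals
  expect_true(all(abs(size_correct(cbind(2 * size), size)) < 1e-12))
  # trait independent of size -> centered trait
  tr <- cbind(c(5, 5, 5, 5))
  expect_true(all(abs(size_correct(tr, size)) < 1e-12))
  # hand-computed OLS on a 4-specimen table: y = c(1,3,2,5) on x = size
  y <- c(1, 3, 2, 5)
  b <- sum((size - mean(size)) * (y - mean(y))) / sum((size - mean(size))^2)
  a <- mean(y) - b * mean(size)
  expect_equal(as.vector(size_correct(cbind(y), size)), y - (a + b * size),
               tolerance = 1e-12)
  # residuals have zero mean and zero covariance with size
  set.seed(2)
  R <- size_correct(matrix(rnorm(40), 10, 4), rnorm(10, 10))
  expect_true(all(abs(colMeans(R)) < 1e-10))
  expect_error(size_correct(matrix(1, 3, 2), c(2, 2, 2)), "constant")
})

test_that("pca has correct variance fractions, reconstruction and conventions", {
  # points on a line in 2-D
  x <- seq(-1, 1, length.out = 20)
  p <- pca(cbind(x, 2 * x))
  expect_equal(p$var_fraction, c(1, 0), tolerance = 1e-12)
  # isotropic Gaussian: both axes carry half the variance
  set.seed(8)
  p2 <- pca(matrix(rnorm(2e4), 1e4, 2))
  expect_lt(max(abs(p2$var_fraction - 0.5)), 0.02)
  # reconstruction identity with all components kept
  X <- matrix(rnorm(60), 12, 5)
  p3 <- pca(X)
  Xhat <- sweep(p3$scores %*% p3$loadings, 2, -p3$center)
  expect_lt(max(abs(X - Xhat)), 1e-9)
  # loadings rows unit length; var_fraction non-increasing
  expect_equal(unname(rowSums(p3$loadings^2)), rep(1, 5), tolerance = 1e-9)
  expect_true(all(diff(p3$var_fraction) <= 1e-12))
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(p3$loadings, 1, function(l) l[which.max(abs(l))] > 0)))
  # permutation invariance of variance fractions
  p4 <- pca(X[sample(12), ])
  expect_equal(p4$var_fraction, p3$var_fraction, tolerance = 1e-10)
  expect_error(pca(matrix(0, 5, 3)), "rank 0")
})
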