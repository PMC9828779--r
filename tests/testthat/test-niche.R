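# exhaustive-search oracle: largest variable subset (earliest in column
# order among ties) satisfying both the VIF and the pairwise-correlation
# constraints
oracle_select <- function(E, r_max, vif_max = 10) {
  vars <- colnames(E)
  best <- NULL
  for (k in rev(seq_along(vars))) {
    for (idx in utils::combn(length(vars), k, simplify = FALSE)) {
      X <- E[, idx, drop = FALSE]
      cr <- abs(cor(X)); diag(cr) <- 0
      if (max(cr) > r_max) next
      ok <- all(vapply(seq_len(ncol(X)), function(j) {
        if (ncol(X) == 1) return(TRUE)
        r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
        1 / (1 - r2) <= vif_max
      }, logical(1)))
      if (ok) { best <- vars[idx]; break }
    }
    if (!is.null(best)) break
  }
  best
}

test_that("select_variables keeps orthogonal sets and prunes duplicates", {
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(400), 40, 10)))    # orthogonal columns, r = 0
  colnames(Q) <- paste0("v", 1:10)
  expect_equal(select_variables(Q, r_max = 0.7), colnames(Q))
  # an exact duplicate column: exactly one of the pair is dropped
  E <- cbind(Q[, 1:4], dup = Q[, 2])
  colnames(E) <- c(paste0("v", 1:4), "dup")
  kept <- select_variables(E, r_max = 0.7)
  expect_length(kept, 4)
  expect_equal(sum(c("v2", "dup") %in% kept), 1)
  expect_error(select_variables(Q[1:5, ], r_max = 0.7), "at least 10")
})

test_that("select_variables matches the exhaustive-subset oracle on a toy", {
  # a "bridge" variable correlated > r_max with two variables that are
  # themselves below r_max: the unique optimum drops only the bridge
  set.seed(22)
  n <- 200
  Q <- qr.Q(qr(matrix(rnorm(n * 10), n, 10)))  # orthonormal columns
  v1 <- Q[, 1]
  v9 <- 0.6 * Q[, 1] + 0.8 * Q[, 2]            # cor(v1, v9) = 0.6
  # noisy bisector: cor ~ 0.82 with each of v1, v9 but finite VIF (< 10)
  bridge <- v1 + v9 + 0.779 * Q[, 10]
  bridge <- bridge / sqrt(sum(bridge^2))
  E <- cbind(v1, Q[, 3:8], bridge, v9, Q[, 9])
  colnames(E) <- paste0("v", 1:10)
  cr <- abs(cor(E)); diag(cr) <- 0
  stopifnot(sum(cr > 0.8) == 4)                # only the two bridge pairs
  kept <- select_variables(E, r_max = 0.8, vif_max = 10)
  orc <- oracle_select(E, r_max = 0.8, vif_max = 10)
  expect_equal(length(kept), length(orc))
  expect_setequal(kept, orc)
  expect_false("v8" %in% kept)                 # the bridge is the one dropped
})

test_that("density_grid normalizes, masks, and is uniform when occ == background", {
  set.seed(23)
  pts <- matrix(rnorm(2e4), 1e4, 2)
  g <- density_grid(pts, pts, R = 60)
  expect_equal(sum(g$z), 1, tolerance = 1e-9)
  expect_true(all(g$z[!g$mask] == 0))
  on_mask <- g$z[g$mask]
  expect_lt(max(on_mask) / min(on_mask[on_mask > 0]), 1.5)
  # concentrated occurrences on a flat background: mass stays near the point
  bg <- cbind(runif(4000, -1, 1), runif(4000, -1, 1))
  occ <- matrix(rnorm(40, 0, 1e-3), 20, 2)
  g2 <- density_grid(occ, bg, R = 80)
  r2 <- outer(g2$x^2, g2$y^2, `+`)
  within <- sqrt(r2) <= 3 * max(g2$h)
  expect_gte(sum(g2$z[within]), 0.99)
  expect_error(density_grid(occ[1:2, , drop = FALSE], bg), "at least 5")
  expect_error(density_grid(occ, cbind(rep(1, 10), rep(2, 10))),
               "degenerate")
})

test_that("overlap indices give 1 on identical, 0 on disjoint, 0.5 on half-support", {
  mk <- function(z) structure(list(z = z / sum(z), x = 1:nrow(z), y = 1:ncol(z),
                                   mask = z >= 0, h = c(1, 1),
                                   lims = c(0, 1, 0, 1)),
                              class = "niche_grid")
  R <- 10
  u <- mk(matrix(1, R, R))
  expect_equal(unname(overlap_indices(u, u)), c(1, 1))
  a <- matrix(0, R, R); a[1:5, ] <- 1
  b <- matrix(0, R, R); b[6:10, ] <- 1
  expect_equal(unname(overlap_indices(mk(a), mk(b))), c(0, 0))
  # half-support uniform vs full uniform: D = 0.5 by hand summation
  expect_equal(unname(overlap_indices(mk(a), u))[1], 0.5)
  # symmetry and joint-permutation invariance
  set.seed(24)
  z1 <- matrix(runif(R * R), R, R); z2 <- matrix(runif(R * R), R, R)
  expect_equal(overlap_indices(mk(z1), mk(z2)), overlap_indices(mk(z2), mk(z1)))
  perm <- sample(R * R)
  pz <- function(z) matrix(z[perm], R, R)
  expect_equal(overlap_indices(mk(pz(z1)), mk(pz(z2))),
               overlap_indices(mk(z1), mk(z2)), tolerance = 1e-12)
  bad <- mk(matrix(1, R, R)); bad$lims <- c(0, 2, 0, 1)
  expect_error(overlap_indices(u, bad), "same grid")
})

test_that("similarity_test is seed-reproducible with sane p-values", {
  set.seed(25)
  bg <- cbind(runif(1500, -3, 3), runif(1500, -3, 3))
  occ1 <- MASS::mvrnorm(150, c(-1, 0), diag(2) * 0.3)
  occ2 <- MASS::mvrnorm(150, c(1, 0), diag(2) * 0.3)
  r1 <- similarity_test(occ1, occ2, bg, bg, n_rep = 199, seed = 31, R = 60)
  r2 <- similarity_test(occ1, occ2, bg, bg, n_rep = 199, seed = 31, R = 60)
  expect_identical(r1[c("D", "I", "p_D", "p_I")], r2[c("D", "I", "p_D", "p_I")])
  expect_true(r1$p_D > 0 && r1$p_D <= 1)
  expect_true(r1$D >= 0 && r1$D <= 1 && r1$I >= 0 && r1$I <= 1)
  # identical occurrence sets: maximal overlap beats translated nulls
  r3 <- similarity_test(occ1, occ1, bg, bg, n_rep = 499, seed = 32, R = 60,
                        alternative = "greater")
  expect_equal(r3$D, 1, tolerance = 1e-9)
  expect_lte(r3$p_similarity, 0.05)
  expect_error(similarity_test(occ1, occ2, bg, bg, n_rep = 199), "seed")
})
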