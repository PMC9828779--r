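test_that("make_windows follows the 30/10 overlapping rule", {
  ids <- paste0("i", 1:50)
  w <- make_windows(ids, size = 30, step = 10)
  expect_length(w, 3)
  expect_equal(w[[1]], ids[1:30])
  expect_equal(w[[2]], ids[11:40])
  expect_equal(w[[3]], ids[21:50])
  expect_length(make_windows(paste0("i", 1:30)), 1)
  # n = 70: enumerate by the rule independently
  ids70 <- paste0("i", 1:70)
  w70 <- make_windows(ids70)
  starts <- seq(1, 70 - 30 + 1, by = 10)
  expect_length(w70, length(starts))
  for (k in seq_along(starts))
    expect_equal(w70[[k]], ids70[starts[k]:(starts[k] + 29)])
  expect_equal(w70[[5]], ids70[41:70])
  expect_error(make_windows(paste0("i", 1:20)), "window size")
  expect_error(make_windows(ids, size = 5, step = 10), "size >= step")
})

test_that("local_outlier_filter retains the chi-square fraction", {
  set.seed(5)
  X <- MASS::mvrnorm(1e4, rep(0, 5), diag(c(4, 3, 2, 1, 0.5)))
  keep <- local_outlier_filter(X, level = 0.95)
  expect_equal(mean(keep), 0.95, tolerance = 0.01)
  # near-idempotence: a second pass removes few additional points
  X2 <- X[keep, ]
  keep2 <- local_outlier_filter(X2, level = 0.95)
  expect_lte(mean(!keep2), 0.06)
  # a gross outlier is removed
  Y <- rbind(MASS::mvrnorm(200, rep(0, 4), diag(4)), rep(50, 4))
  expect_false(local_outlier_filter(Y)[201])
})

make_scan_data <- function(n_per_sp = 120, d = 4, rotate_near_contact = 0,
                           seed = 1) {
  set.seed(seed)
  spec <- c(8, 2, 1, 0.5)[1:d]
  out <- list(X = list(), pos = list())
  for (sp in c("A", "B")) {
    pos <- if (sp == "A") runif(n_per_sp, 0, 9) else runif(n_per_sp, 9, 14.58)
    X <- matrix(rnorm(n_per_sp * d), n_per_sp, d) %*% diag(sqrt(spec))
    if (rotate_near_contact > 0 && sp == "A") {
      near <- order(abs(pos - 9))[1:30]
      a <- rotate_near_contact * pi / 180
      G <- diag(d); G[1:2, 1:2] <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
      X[near, ] <- X[near, ] %*% t(G)
    }
    rownames(X) <- paste0(sp, seq_len(n_per_sp))
    out$X[[sp]] <- X; out$pos[[sp]] <- pos
  }
  out
}

test_that("window_scan orders windows outward and is seed-reproducible", {
  sd <- make_scan_data(seed = 2)
  s1 <- window_scan(sd$X, sd$pos, contact_km = 9, size = 30, step = 10,
                    n_boot = 200, seed = 7)
  s2 <- window_scan(sd$X, sd$pos, contact_km = 9, size = 30, step = 10,
                    n_boot = 200, seed = 7)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  for (sp in c("A", "B")) {
    md <- s1$mean_distance_km[s1$species == sp]
    expect_true(all(diff(md) > 0))   # strictly increasing away from contact
  }
  # window membership is disjoint from the reference (furthest) individuals
  members <- attr(s1, "members")
  far_A <- rownames(sd$X$A)[order(abs(sd$pos$A - 9))][91:120]
  expect_length(intersect(unlist(members[s1$species == "A"]), far_A), 0)
  # permuting storage order leaves window statistics unchanged
  perm <- sample(nrow(sd$X$A))
  sdp <- sd; sdp$X$A <- sd$X$A[perm, ]; sdp$pos$A <- sd$pos$A[perm]
  s3 <- window_scan(sdp$X, sdp$pos, contact_km = 9, size = 30, step = 10,
                    n_boot = 200, seed = 7)
  expect_equal(s3$theta_deg, s1$theta_deg, tolerance = 1e-12)
  expect_error(window_scan(lapply(sd$X, function(x) x[1:40, ]),
                           lapply(sd$pos, `[`, 1:40), 9), "2\\*size")
})

test_that("a covariance rotation near the contact shows up in nearby windows", {
  sd <- make_scan_data(n_per_sp = 150, rotate_near_contact = 60, seed = 3)
  s <- window_scan(sd$X, sd$pos, contact_km = 9, size = 30, step = 10,
                   n_boot = 500, seed = 11)
  a <- s[s$species == "A", ]
  expect_gt(a$theta_deg[1], a$theta_deg[nrow(a)])
  expect_true(a$significant_theta[1])
  expect_false(a$significant_theta[nrow(a)])
})

fake_scan <- function(theta_by_species, distances = seq(0.5, 4, length.out = 8)) {
  do.call(rbind, lapply(names(theta_by_species), function(sp)
    data.frame(species = sp, window_index = seq_along(distances),
               mean_distance_km = distances, mean_position_km = distances,
               theta_deg = theta_by_species[[sp]], theta_p = 0.5,
               significant_theta = FALSE, matrix_distance = 1,
               distance_p = 0.5, significant_distance = FALSE)))
}

test_that("trend_test finds interactions and scales linearly", {
  set.seed(8)
  flat <- fake_scan(list(A = rnorm(8, 10, 2), B = rnorm(8, 10, 2)))
  t1 <- trend_test(flat, "theta")
  expect_gt(t1$interaction_p, 0.05)
  rising <- fake_scan(list(A = seq(0, 30, length.out = 8) + rnorm(8, 0, 2),
                           B = rnorm(8, 5, 2)))
  t2 <- trend_test(rising, "theta")
  expect_lt(t2$interaction_p, 0.01)
  # doubling all distances halves the slope estimates exactly
  doubled <- rising; doubled$mean_distance_km <- 2 * rising$mean_distance_km
  t3 <- trend_test(doubled, "theta")
  expect_equal(t3$slopes, t2$slopes / 2, tolerance = 1e-10)
  expect_error(trend_test(rising[rising$species == "A", ]), "both species")
})
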