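test_that("filter_variants matches the brute-force per-rule oracle exactly", {
  G <- six_site_fixture()
  res <- filter_variants(G)
  orc <- oracle_filter(G)
  expect_equal(res$G$site_ids, G$site_ids[orc$alive])
  expect_equal(res$losses, orc$losses)
  expect_equal(res$G$site_ids, "pass")            # exactly one survivor
  expect_equal(sum(res$losses), 5L)               # losses sum to in - out
})

test_that("vacuous thresholds pass everything; monomorphic sites fail MAF", {
  G <- six_site_fixture()
  res <- filter_variants(G, maf_min = 0, max_missing = 1, gq_min = 0,
                         dp_min = 0, dp_max = Inf, biallelic_only = FALSE)
  expect_equal(res$G$site_ids, G$site_ids)
  expect_equal(unname(res$G$dosages), unname(G$dosages))
  # monomorphic site removed by the MAF rule alone
  res2 <- filter_variants(G, maf_min = 0.04, max_missing = 1, gq_min = 0,
                          dp_min = 0, dp_max = Inf, biallelic_only = FALSE)
  expect_false("monomorphic" %in% res2$G$site_ids)
  expect_gte(res2$losses[["maf"]], 1L)
  # all-removed case warns and returns an empty matrix
  expect_warning(filter_variants(G, maf_min = 0.6), "all sites removed")
})

test_that("filter losses always sum to sites_in - sites_out", {
  set.seed(12)
  for (r in 1:5) {
    n <- 20; m <- 40
    dos <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                         prob = c(0.3, 0.2, 0.3, 0.2)), n, m)
    G <- genotype_matrix(dos,
                         depth = matrix(rpois(n * m, 12), n, m),
                         qual = runif(m, 10, 60),
                         n_alleles = sample(2:3, m, TRUE, prob = c(0.8, 0.2)))
    res <- suppressWarnings(filter_variants(G))
    expect_equal(sum(res$losses), m - ncol(res$G$dosages))
    orc <- oracle_filter(G)
    expect_equal(res$losses, orc$losses)
    expect_equal(res$G$site_ids, G$site_ids[orc$alive])
  }
})

test_that("genotype_pca separates fixed clusters and places F1s between", {
  dos <- rbind(matrix(0L, 10, 20), matrix(2L, 10, 20))
  G <- genotype_matrix(dos, sample_ids = paste0("s", 1:20))
  p <- genotype_pca(G)
  expect_gt(p$var_fraction[1], 0.99)
  expect_gt(abs(mean(p$scores[1:10, 1]) - mean(p$scores[11:20, 1])), 1)
  # an all-heterozygous row scores between the cluster means
  G2 <- genotype_matrix(rbind(dos, rep(1L, 20)),
                        sample_ids = paste0("s", 1:21))
  p2 <- genotype_pca(G2)
  mid <- p2$scores[21, 1]
  expect_gt(mid, min(mean(p2$scores[1:10, 1]), mean(p2$scores[11:20, 1])))
  expect_lt(mid, max(mean(p2$scores[1:10, 1]), mean(p2$scores[11:20, 1])))
})

test_that("genotype_pca equals a direct eigendecomposition oracle", {
  set.seed(14)
  n <- 40
  diag_dos <- cbind(matrix(rep(c(0L, 2L), each = n / 2), n, 10))
  bg <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  dos <- cbind(diag_dos, bg)
  dos[sample(length(dos), 40)] <- NA
  G <- genotype_matrix(dos)
  p <- genotype_pca(G)
  # oracle: mean-impute, center, eigendecompose the covariance directly
  m <- apply(dos, 2, function(col) { col[is.na(col)] <- mean(col, na.rm = TRUE); col })
  ev <- eigen(cov(m), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(p$var_fraction[1]), ev[1] / sum(ev), tolerance = 1e-9)
  # mirrored dosages give mirrored PC1 scores
  pm <- genotype_pca(genotype_matrix(2L - dos))
  expect_equal(abs(cor(p$scores[, 1], pm$scores[, 1])), 1, tolerance = 1e-9)
})

test_that("hybrid_index calls pure, F1 and backcross genotypes correctly", {
  nd <- 30
  A <- matrix(0L, 8, nd); B <- matrix(2L, 8, nd)
  f1 <- rep(1L, nd)
  pureA <- rep(0L, nd)
  dos <- rbind(A, B, f1 = f1, pureA = pureA)
  ids <- c(paste0("A", 1:8), paste0("B", 1:8), "f1", "pureA")
  G <- genotype_matrix(dos, sample_ids = ids)
  hrep <- hybrid_index(G, paste0("A", 1:8), paste0("B", 1:8))
  f1row <- hrep[hrep$sample_id == "f1", ]
  expect_equal(f1row$hybrid_index, 0.5)
  expect_equal(f1row$interspecific_het, 1)
  expect_equal(f1row$call, "F1_candidate")
  parow <- hrep[hrep$sample_id == "pureA", ]
  expect_equal(parow$hybrid_index, 0)
  expect_equal(parow$call, "pure_A")
  # invariance to permuting site order
  perm <- sample(nd)
  Gp <- genotype_matrix(dos[, perm], sample_ids = ids)
  repp <- hybrid_index(Gp, paste0("A", 1:8), paste0("B", 1:8))
  expect_equal(repp$hybrid_index, hrep$hybrid_index)
  expect_error(hybrid_index(G, paste0("A", 1:8), paste0("B", 1:8),
                            diagnostic_delta = 1.5), "diagnostic")
  expect_error(hybrid_index(G, paste0("A", 1:4), paste0("B", 1:8)),
               "at least 5")
})

test_that("simulated backcrosses fall in the other class", {
  set.seed(15)
  nd <- 40
  dosA <- matrix(0L, 10, nd); dosB <- matrix(2L, 10, nd)
  calls <- replicate(50, {
    # gamete from an F1 (Bernoulli half per site) plus a pure-A gamete
    bc <- rbinom(nd, 1, 0.5)
    G <- genotype_matrix(rbind(dosA, dosB, bc = as.integer(bc)),
                         sample_ids = c(paste0("A", 1:10), paste0("B", 1:10),
                                        "bc"))
    hybrid_index(G, paste0("A", 1:10), paste0("B", 1:10))$call
  })
  expect_gte(mean(calls == "other"), 0.95)
})
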