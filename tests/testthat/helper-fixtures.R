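# Shared fixture builders (all data generated in code).

random_landmark_sets <- function(n, k = 5L, with_scale = FALSE) {
  lapply(seq_len(n), function(i) {
    landmark_set(sprintf("s%02d", i),
                 matrix(round(stats::rnorm(2 * k), 6), k, 2),
                 scale = if (with_scale) round(stats::runif(1, 0.1, 2), 6)
                         else NA_real_)
  })
}

# apply a random similarity transform (rotation + translation + scale)
similarity_transform <- function(coords) {
  a <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  s <- stats::runif(1, 0.2, 5)
  t(t(s * coords %*% R) + stats::rnorm(2, sd = 10))
}

# five-site toy VCF with GT:DP:GQ used by genotype-parsing tests
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ind1", "ind2", "ind3", sep = "\t"),
    paste("chr1", 10, "s1", "A", "T", ".", "PASS", ".", "GT:DP:GQ",
          "0/0:12:50", "0/1:15:44", "1/1:9:38", sep = "\t"),
    paste("chr1", 20, "s2", "G", "C", ".", "PASS", ".", "GT:DP:GQ",
          "./.:3:10", "0/0:20:60", "0/1:18:55", sep = "\t"),
    paste("chr1", 30, "s3", "T", "A", ".", "PASS", ".", "GT:DP:GQ",
          "1/1:25:33", "1/1:22:41", "0/0:11:29", sep = "\t"),
    paste("chr1", 40, "s4", "C", "G", ".", "PASS", ".", "GT:DP:GQ",
          "0/1:14:47", "./.:2:5", "0/1:16:52", sep = "\t"),
    paste("chr1", 50, "s5", "A", "G", ".", "PASS", ".", "GT:DP:GQ",
          "0/0:13:39", "0/1:17:46", "./.:4:12", sep = "\t"))
  writeLines(lines, path)
  path
}

# hand-constructed expected dosages for the toy VCF (individuals x sites)
toy_vcf_expected <- function() {
  matrix(c(0L, 1L, 2L,      # s1
           NA, 0L, 1L,      # s2
           2L, 2L, 0L,      # s3
           1L, NA, 1L,      # s4
           0L, 1L, NA),     # s5
         nrow = 3, ncol = 5,
         dimnames = list(c("ind1", "ind2", "ind3"),
                         paste0("chr1:", c(10, 20, 30, 40, 50))))
}

# six-site genotype fixture: one site fails each filter rule, one passes all
six_site_fixture <- function() {
  n <- 10L
  good <- c(rep(0L, 5), rep(1L, 2), rep(2L, 3))       # MAF 0.4, passes all
  mono <- rep(0L, n)                                  # fails MAF
  multi <- good                                       # fails biallelic
  lowq <- good                                        # fails quality (GQ 15)
  baddp <- good                                       # fails depth (all DP 2)
  missy <- c(good[1:3], rep(NA_integer_, 7))          # 70% missing
  dos <- cbind(pass = good, nonbi = multi, lowgq = lowq, baddepth = baddp,
               missing = missy, monomorphic = mono)
  depth <- matrix(12L, n, 6)
  depth[, 4] <- 2L
  qual <- c(45, 50, 15, 48, 52, 47)
  genotype_matrix(dos, sample_ids = sprintf("i%02d", 1:n),
                  depth = depth, qual = qual,
                  n_alleles = c(2L, 3L, 2L, 2L, 2L, 2L))
}

# Independent brute-force application of the filter rules, used as the
# oracle for filter_variants on small fixtures.
oracle_filter <- function(G, maf_min = 0.04, max_missing = 0.60, gq_min = 20,
                          dp_min = 5, dp_max = 30) {
  dos <- G$dosages
  losses <- c(biallelic = 0L, quality = 0L, depth = 0L, missingness = 0L,
              maf = 0L)
  alive <- rep(TRUE, ncol(dos))
  for (j in seq_len(ncol(dos))) {
    if (G$n_alleles[j] != 2) { losses["biallelic"] <- losses["biallelic"] + 1L
                               alive[j] <- FALSE; next }
    if (G$qual[j] <= gq_min) { losses["quality"] <- losses["quality"] + 1L
                               alive[j] <- FALSE; next }
    col <- dos[, j]
    miss_before <- mean(is.na(col))
    col[G$depth[, j] < dp_min | G$depth[, j] > dp_max] <- NA
    if (mean(is.na(col)) > max_missing) {
      rule <- if (miss_before <= max_missing) "depth" else "missingness"
      losses[rule] <- losses[rule] + 1L; alive[j] <- FALSE; next
    }
    p <- mean(col, na.rm = TRUE) / 2
    if (min(p, 1 - p) < maf_min) { losses["maf"] <- losses["maf"] + 1L
                                   alive[j] <- FALSE }
  }
  list(alive = alive, losses = losses)
}
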