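#' Filter variants by quality, depth, missingness and allele frequency
#'
#' Applies the site filters in a fixed order: (1) non-biallelic sites removed;
#' (2) sites with genotype-quality summary `<= gq_min` removed; (3) depth
#' rule — when per-entry depths are present, entries with depth outside
#' `[dp_min, dp_max]` are set missing; when absent, sites whose mean depth is
#' outside the range are removed; (4) sites with more than `max_missing`
#' missing entries removed; (5) sites with minor allele frequency below
#' `maf_min` removed. In the loss report, a site removed at the missingness
#' step is attributed to the depth rule when it would have passed without the
#' depth masking, so per-rule losses sum to `sites_in - sites_out`.
#'
#' @param G A [genotype_matrix].
#' @param maf_min Minimum minor allele frequency (sites with MAF `< maf_min`
#'   removed; default 0.04).
#' @param max_missing Maximum tolerated missing fraction per site (default
#'   0.60, i.e. sites with more than 60% missing data are removed).
#' @param gq_min Sites with quality summary `<= gq_min` are removed (default
#'   20).
#' @param dp_min,dp_max Allowed depth range (defaults 5 and 30).
#' @param biallelic_only Remove non-biallelic sites (default `TRUE`).
#' @return List with `G` (filtered [genotype_matrix]), `losses` (named
#'   per-rule site losses in application order), and `masked_entries`
#'   (entries set missing by the depth rule).
#' @export
filter_variants <- function(G, maf_min = 0.04, max_missing = 0.60,
                            gq_min = 20L, dp_min = 5, dp_max = 30,
                            biallelic_only = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosages
  keep <- rep(TRUE, ncol(dos))
  losses <- c(biallelic = 0L, quality = 0L, depth = 0L,
              missingness = 0L, maf = 0L)
  if (biallelic_only) {
    bad <- G$n_alleles != 2L
    losses["biallelic"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (!is.null(G$qual)) {
    bad <- !is.na(G$qual) & G$qual <= gq_min
    losses["quality"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  masked <- 0L
  miss_pre <- colMeans(is.na(dos))
  if (!is.null(G$depth)) {
    bad_entry <- !is.na(G$depth) & (G$depth < dp_min | G$depth > dp_max)
    masked <- sum(bad_entry[, keep, drop = FALSE] & !is.na(dos[, keep, drop = FALSE]))
    dos[bad_entry] <- NA_integer_
  } else if (any(keep)) {
    # no per-entry depth: nothing to mask; mean-depth rule has no data either
  }
  miss_post <- colMeans(is.na(dos))
  bad_miss <- miss_post > max_missing
  # attribute to depth when masking alone pushed the site over the threshold
  depth_blame <- bad_miss & (miss_pre <= max_missing)
  losses["depth"] <- sum(depth_blame & keep)
  losses["missingness"] <- sum(bad_miss & !depth_blame & keep)
  keep <- keep & !bad_miss
  p <- colMeans(dos, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  bad_maf <- is.na(maf) | maf < maf_min
  losses["maf"] <- sum(bad_maf & keep)
  keep <- keep & !bad_maf
  if (!any(keep)) warning("all sites removed by filtering")
  out <- genotype_matrix(dos[, keep, drop = FALSE],
                         sample_ids = G$sample_ids,
                         site_ids = G$site_ids[keep],
                         depth = if (is.null(G$depth)) NULL else G$depth[, keep, drop = FALSE],
                         qual = if (is.null(G$qual)) NULL else G$qual[keep],
                         n_alleles = G$n_alleles[keep])
  list(G = out, losses = losses, masked_entries = masked)
}

#' Principal components of a genotype matrix
#'
#' Missing dosages are mean-imputed per site (all-missing sites are dropped
#' with a warning), the matrix is centered, and the PCA of
#' [pca()] is applied. Optionally the first axis is oriented so that a named
#' reference group (e.g. the western species) has a negative mean score,
#' giving a reproducible west-to-east axis for the genomic cline.
#'
#' @param G A [genotype_matrix].
#' @param orient_negative_ids Optional sample ids whose mean PC1 score is
#'   forced negative by flipping the axis.
#' @return A `shape_scores` object (scores, loadings, var_fraction).
#' @export
genotype_pca <- function(G, orient_negative_ids = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosages
  if (nrow(dos) < 2L || ncol(dos) < 2L)
    stop("need at least 2 individuals and 2 sites")
  all_missing <- colSums(!is.na(dos)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing site(s) dropped before PCA")
    dos <- dos[, !all_missing, drop = FALSE]
  }
  m <- apply(dos, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- mu
    col
  })
  rownames(m) <- G$sample_ids
  res <- pca(m)
  if (!is.null(orient_negative_ids)) {
    idx <- match(orient_negative_ids, G$sample_ids)
    idx <- idx[!is.na(idx)]
    if (length(idx) && mean(res$scores[idx, 1]) > 0) {
      res$scores[, 1] <- -res$scores[, 1]
      res$loadings[1, ] <- -res$loadings[1, ]
    }
  }
  res
}

#' Hybrid index and F1 detection at diagnostic sites
#'
#' Diagnostic sites are those whose allele-frequency difference between two
#' reference groups is at least `diagnostic_delta`. For each query sample the
#' hybrid index is the mean proportion of B-type alleles over its non-missing
#' diagnostic sites (0 = pure A, 1 = pure B) and the interspecific
#' heterozygosity is the fraction of heterozygous diagnostic genotypes. A
#' first-generation (F1) hybrid is heterozygous at essentially all diagnostic
#' sites with an index near 0.5, whereas backcrosses shift the index toward a
#' parent while halving heterozygosity, so they fall in the `other` class.
#'
#' @param G A [genotype_matrix].
#' @param groupA_ids,groupB_ids Non-overlapping reference sample ids, at
#'   least 5 each.
#' @param diagnostic_delta Minimum between-group allele-frequency difference
#'   for a diagnostic site (default 0.9).
#' @param samples Samples to score; defaults to all samples outside the two
#'   reference groups.
#' @param f1_index_range,f1_het_min Call thresholds for `F1_candidate`
#'   (index within the range and heterozygosity at least the minimum).
#' @param pure_max Index at most `pure_max` (or at least `1 - pure_max`) is
#'   called pure (default 0.1).
#' @return Data.frame with `sample_id`, `hybrid_index`, `interspecific_het`,
#'   `n_diagnostic`, `call` in {pure_A, pure_B, F1_candidate, other}.
#' @export
hybrid_index <- function(G, groupA_ids, groupB_ids, diagnostic_delta = 0.9,
                         samples = NULL, f1_index_range = c(0.4, 0.6),
                         f1_het_min = 0.85, pure_max = 0.1) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (length(intersect(groupA_ids, groupB_ids)))
    stop("reference groups must not overlap")
  if (length(groupA_ids) < 5L || length(groupB_ids) < 5L)
    stop("each reference group needs at least 5 individuals")
  dos <- G$dosages
  iA <- match(groupA_ids, G$sample_ids); iB <- match(groupB_ids, G$sample_ids)
  if (anyNA(iA) || anyNA(iB)) stop("unknown sample ids in reference groups")
  fA <- colMeans(dos[iA, , drop = FALSE], na.rm = TRUE) / 2
  fB <- colMeans(dos[iB, , drop = FALSE], na.rm = TRUE) / 2
  diag_sites <- which(!is.na(fA) & !is.na(fB) & abs(fA - fB) >= diagnostic_delta)
  if (!length(diag_sites))
    stop("no diagnostic sites at delta = ", diagnostic_delta,
         "; consider lowering diagnostic_delta")
  if (is.null(samples)) samples <- setdiff(G$sample_ids, c(groupA_ids, groupB_ids))
  iq <- match(samples, G$sample_ids)
  if (anyNA(iq)) stop("unknown sample ids in samples")
  D <- dos[iq, diag_sites, drop = FALSE]
  # dosage of the B-type allele: flip sites where A carries more ALT copies
  flip <- fA[diag_sites] > fB[diag_sites]
  D[, flip] <- 2L - D[, flip]
  hi <- rowMeans(D, na.rm = TRUE) / 2
  het <- rowMeans(dos[iq, diag_sites, drop = FALSE] == 1L, na.rm = TRUE)
  call <- rep("other", length(iq))
  call[hi >= f1_index_range[1] & hi <= f1_index_range[2] & het >= f1_het_min] <-
    "F1_candidate"
  call[hi <= pure_max & call == "other"] <- "pure_A"
  call[hi >= 1 - pure_max & call == "other"] <- "pure_B"
  data.frame(sample_id = samples, hybrid_index = unname(hi),
             interspecific_het = unname(het),
             n_diagnostic = rowSums(!is.na(D)), call = call,
             stringsAsFactors = FALSE)
}
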