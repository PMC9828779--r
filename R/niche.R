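#' Select least-correlated environmental variables
#'
#' Two-stage pruning of a variable set before niche analysis: first,
#' variables are dropped one at a time (highest variance inflation factor
#' first) until all VIF are at most `vif_max`; then, while any pair has
#' absolute Pearson correlation above `r_max`, the member of the worst pair
#' with the higher mean absolute correlation to the remaining variables is
#' dropped. Ties are broken deterministically by column order (the
#' later column is dropped).
#'
#' @param E Numeric matrix or data.frame, samples x variables.
#' @param r_max Maximum tolerated pairwise |Pearson r|.
#' @param vif_max Maximum tolerated VIF (default 10).
#' @return Character vector of retained variable names, in input order.
#' @export
select_variables <- function(E, r_max, vif_max = 10) {
  E <- as.matrix(E)
  if (ncol(E) < 2L) stop("need at least 2 variables")
  if (nrow(E) < 10L) stop("need at least 10 samples")
  vars <- colnames(E) %||% paste0("V", seq_len(ncol(E)))
  colnames(E) <- vars
  keep <- vars
  vif_of <- function(cols) {
    X <- E[, cols, drop = FALSE]
    vapply(seq_along(cols), function(j) {
      # suppress the "perfect fit" note lm emits for exact duplicates
      r2 <- suppressWarnings(
        summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  while (length(keep) > 1L) {
    v <- vif_of(keep)
    if (max(v) <= vif_max) break
    worst <- which(v == max(v))
    keep <- keep[-worst[length(worst)]]   # tie: drop the later column
  }
  repeat {
    if (length(keep) < 2L) break
    cr <- abs(stats::cor(E[, keep, drop = FALSE]))
    diag(cr) <- 0
    if (max(cr) <= r_max) break
    ij <- which(cr == max(cr), arr.ind = TRUE)[1, ]
    mean_r <- rowMeans(cr)
    drop_j <- if (mean_r[ij[1]] > mean_r[ij[2]]) ij[1]
              else if (mean_r[ij[2]] > mean_r[ij[1]]) ij[2]
              else max(ij)
    keep <- keep[-drop_j]
  }
  if (!length(keep)) stop("all variables dropped; relax r_max or vif_max")
  vars[vars %in% keep]
}

#' Occurrence-density surface over an environmental ordination
#'
#' Gaussian kernel densities of the occurrences and of the available
#' background are evaluated on a shared R x R grid spanning the background
#' (kernel bandwidth by Silverman's rule on the background, shared by both
#' densities). The occurrence density is divided by the background density on
#' occupied cells — correcting for the availability of environments — and
#' renormalized to sum to one; cells with negligible background density are
#' masked out.
#'
#' @param scores Occurrences, n x 2 matrix of ordination coordinates.
#' @param background Available environment points, m x 2 matrix covering the
#'   occurrences' bounding box.
#' @param R Grid resolution per axis (default 100).
#' @param bandwidth Optional length-2 kernel bandwidth (as in
#'   [MASS::kde2d()]); default Silverman's rule on the background.
#' @param lims Optional grid limits `c(xmin, xmax, ymin, ymax)`; default the
#'   background range padded by half a bandwidth.
#' @return A list of class `niche_grid`: `z` (R x R, sums to 1), `x`, `y`
#'   (cell-center coordinates), `mask` (background-occupied cells), `h`,
#'   `lims`.
#' @export
density_grid <- function(scores, background, R = 100L, bandwidth = NULL,
                         lims = NULL) {
  scores <- as.matrix(scores); background <- as.matrix(background)
  if (nrow(scores) < 5L) stop("need at least 5 occurrences")
  if (nrow(background) < 5L) stop("background is empty or degenerate")
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(background[, 1]),
                   MASS::bandwidth.nrd(background[, 2]))
    if (any(bandwidth <= 0)) stop("degenerate background (zero bandwidth)")
  }
  if (is.null(lims)) {
    lims <- c(range(background[, 1]) + c(-1, 1) * bandwidth[1] / 2,
              range(background[, 2]) + c(-1, 1) * bandwidth[2] / 2)
  }
  kb <- MASS::kde2d(background[, 1], background[, 2], h = bandwidth,
                    n = R, lims = lims)
  ko <- MASS::kde2d(scores[, 1], scores[, 2], h = bandwidth, n = R,
                    lims = lims)
  mask <- kb$z > 1e-12 * max(kb$z)
  z <- matrix(0, R, R)
  z[mask] <- ko$z[mask] / kb$z[mask]
  if (sum(z) <= 0) stop("occurrence density vanishes on the background mask")
  z <- z / sum(z)
  structure(list(z = z, x = kb$x, y = kb$y, mask = mask, h = bandwidth,
                 lims = lims), class = "niche_grid")
}

#' Niche overlap indices on density grids
#'
#' Schoener's `D = 1 - sum(|z1 - z2|) / 2` and Warren's
#' `I = 1 - sum((sqrt(z1) - sqrt(z2))^2) / 2` (one minus half the squared
#' Hellinger distance), both in \[0, 1\]: 1 for identical surfaces, 0 for
#' disjoint supports.
#'
#' @param z1,z2 `niche_grid` objects on identical grids.
#' @return Named numeric vector `c(D = , I = )`.
#' @export
overlap_indices <- function(z1, z2) {
  stopifnot(inherits(z1, "niche_grid"), inherits(z2, "niche_grid"))
  if (!all(dim(z1$z) == dim(z2$z)) || !isTRUE(all.equal(z1$lims, z2$lims)))
    stop("niche grids must share the same grid")
  D <- 1 - sum(abs(z1$z - z2$z)) / 2
  I <- 1 - sum((sqrt(z1$z) - sqrt(z2$z))^2) / 2
  c(D = D, I = I)
}

shift_grid <- function(z, di, dj) {
  R <- nrow(z); C <- ncol(z)
  out <- matrix(0, R, C)
  src_i <- seq_len(R) - di; src_j <- seq_len(C) - dj
  ok_i <- src_i >= 1 & src_i <= R; ok_j <- src_j >= 1 & src_j <= C
  out[ok_i, ok_j] <- z[src_i[ok_i], src_j[ok_j]]
  out
}

#' Niche similarity randomization test
#'
#' Tests whether the observed overlap between two groups' niches differs from
#' overlap expected by chance given their available backgrounds: the second
#' group's occurrence density is relocated `n_rep` times by translating its
#' centroid to a random cell of its own background (truncated to the grid and
#' renormalized), and the overlap with the first group's observed density is
#' recomputed each time. With `alternative = "lower"`, small p-values indicate
#' niches more diverged (lower overlap) than the null; with `"greater"`, more
#' similar. The p-value uses the add-one estimator
#' `(1 + k) / (n_rep + 1)`.
#'
#' @param occ1,occ2 Occurrence coordinate matrices (n x 2) for the two groups.
#' @param background1,background2 Background coordinate matrices.
#' @param n_rep Number of randomizations (default 1000).
#' @param seed Integer seed (required).
#' @param alternative Direction of the test on overlap.
#' @param R Grid resolution.
#' @return A list of class `overlap_result`: `D`, `I`, `p_similarity` (for D
#'   in the stated direction), `p_D`, `p_I`, `alternative`, `n_rep`, `seed`.
#' @export
similarity_test <- function(occ1, occ2, background1, background2,
                            n_rep = 1000L, seed,
                            alternative = c("greater", "lower"), R = 100L) {
  alternative <- match.arg(alternative)
  if (n_rep < 100L) warning("n_rep < 100 gives coarse p-values")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  bg_all <- rbind(as.matrix(background1), as.matrix(background2))
  h <- c(MASS::bandwidth.nrd(bg_all[, 1]), MASS::bandwidth.nrd(bg_all[, 2]))
  if (any(h <= 0)) stop("degenerate background (zero bandwidth)")
  lims <- c(range(bg_all[, 1]) + c(-1, 1) * h[1] / 2,
            range(bg_all[, 2]) + c(-1, 1) * h[2] / 2)
  z1 <- density_grid(occ1, background1, R = R, bandwidth = h, lims = lims)
  z2 <- density_grid(occ2, background2, R = R, bandwidth = h, lims = lims)
  obs <- overlap_indices(z1, z2)
  # centroid of z2 in cell units
  wi <- rowSums(z2$z); wj <- colSums(z2$z)
  ci <- sum(seq_len(R) * wi); cj <- sum(seq_len(R) * wj)
  cells <- which(z2$mask, arr.ind = TRUE)
  null_D <- numeric(n_rep); null_I <- numeric(n_rep)
  for (b in seq_len(n_rep)) {
    tgt <- cells[sample.int(nrow(cells), 1L), ]
    zs <- shift_grid(z2$z, round(tgt[1] - ci), round(tgt[2] - cj))
    s <- sum(zs)
    if (s <= 0) { null_D[b] <- 0; null_I[b] <- 0; next }
    zs <- zs / s
    null_D[b] <- 1 - sum(abs(z1$z - zs)) / 2
    null_I[b] <- 1 - sum((sqrt(z1$z) - sqrt(zs))^2) / 2
  }
  pfun <- function(null, o) {
    if (alternative == "greater") (1 + sum(null >= o)) / (n_rep + 1)
    else (1 + sum(null <= o)) / (n_rep + 1)
  }
  structure(list(D = unname(obs["D"]), I = unname(obs["I"]),
                 p_D = pfun(null_D, obs["D"]), p_I = pfun(null_I, obs["I"]),
                 p_similarity = pfun(null_D, obs["D"]),
                 alternative = alternative, n_rep = as.integer(n_rep),
                 seed = as.integer(seed)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> D = %.3f, I = %.3f; p(%s) = %.4f (D), %.4f (I); %d reps\n",
              x$D, x$I, x$alternative, x$p_D, x$p_I, x$n_rep))
  invisible(x)
}
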