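#' Build overlapping sliding windows over an ordering
#'
#' Windows of `size` individuals stepping by `step` along an ordering (here,
#' individuals sorted by distance from the point of contact): windows
#' `[1..size]`, `[1+step..size+step]`, ... as long as a full window fits; a
#' final partial window is dropped.
#'
#' @param ids_sorted_from_contact Ids ordered from the point of contact
#'   outward.
#' @param size Window size (default 30 individuals).
#' @param step Step size (default 10 individuals).
#' @return List of id vectors, each of length `size`.
#' @export
make_windows <- function(ids_sorted_from_contact, size = 30L, step = 10L) {
  n <- length(ids_sorted_from_contact)
  if (step < 1L || size < step) stop("need size >= step >= 1")
  if (n < size)
    stop("only ", n, " individuals but window size is ", size)
  starts <- seq.int(1L, n - size + 1L, by = step)
  lapply(starts, function(s) ids_sorted_from_contact[s:(s + size - 1L)])
}

#' Remove local multivariate outliers by PCA confidence region
#'
#' For one species' trait matrix: PCA, keep the leading components that
#' together explain at least `var_explained` of the variance, and retain
#' individuals whose squared Mahalanobis distance on those components (sum of
#' squared standardized scores) is within the chi-square `level` quantile.
#' Applied before windowed P-matrix estimation because statistically assigned
#' (non-genotyped) individuals can include misassignments that would distort
#' local covariance structure.
#'
#' @param X Numeric trait matrix for one species.
#' @param level Chi-square confidence level (default 0.95).
#' @param var_explained Minimum cumulative variance fraction of the retained
#'   components (default 0.95).
#' @return Logical vector, `TRUE` for retained rows (named by rownames).
#' @export
local_outlier_filter <- function(X, level = 0.95, var_explained = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 specimens")
  p <- pca(X)
  k <- which(cumsum(p$var_fraction) >= var_explained)[1]
  if (is.na(k)) k <- length(p$var_fraction)
  sc <- p$scores[, seq_len(k), drop = FALSE]
  ev <- pmax(p$eigenvalues[seq_len(k)], .Machine$double.eps)
  md2 <- colSums(t(sc^2) / ev)
  keep <- md2 <= stats::qchisq(level, df = k)
  names(keep) <- rownames(X)
  keep
}

#' Sliding-window P-matrix scan along a contact zone
#'
#' For each species, individuals are ordered by their distance from the point
#' of contact; the `size` individuals furthest from contact on the species'
#' own side form a fixed reference set (the "utmost" end of the transect),
#' and overlapping windows of `size` individuals stepping by `step` move
#' outward from the contact through the remaining individuals. Each window's
#' P matrix is compared to the reference P matrix by the angle between
#' leading eigenvectors and by the riemannian matrix distance, each with
#' bootstrap significance via [bootstrap_compare()].
#'
#' @param X_by_species Named list (one element per species) of specimens x
#'   traits matrices.
#' @param positions Named list of transect positions (km), parallel to the
#'   rows of each trait matrix.
#' @param contact_km Position of the point of contact (e.g. a fitted genomic
#'   cline center).
#' @param size,step Window size and step (defaults 30 and 10 individuals).
#' @param n_boot Bootstrap replicates per comparison.
#' @param seed Integer seed; window b of species s uses a seed derived from
#'   it, so the full scan is reproducible.
#' @return A data.frame of class `window_scan` with one row per window:
#'   `species`, `window_index`, `mean_distance_km` (mean distance from
#'   contact), `mean_position_km`, `theta_deg`, `theta_p`,
#'   `significant_theta`, `matrix_distance`, `distance_p`,
#'   `significant_distance`; window memberships in `attr(,"members")`.
#' @export
window_scan <- function(X_by_species, positions, contact_km, size = 30L,
                        step = 10L, n_boot = 1000L, seed = 1L) {
  stopifnot(is.list(X_by_species), is.list(positions),
            identical(names(X_by_species), names(positions)))
  rows <- list(); members <- list()
  for (sp in names(X_by_species)) {
    X <- as.matrix(X_by_species[[sp]])
    pos <- positions[[sp]]
    if (length(pos) != nrow(X)) stop("positions do not match traits for ", sp)
    if (nrow(X) < 2L * size)
      stop("species ", sp, " has ", nrow(X),
           " individuals; need at least 2*size = ", 2L * size,
           " for disjoint reference and scan sets")
    ord <- order(abs(pos - contact_km))
    ref_idx <- utils::tail(ord, size)          # furthest from contact
    pool <- setdiff(ord, ref_idx)              # ordered, nearest first
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
    wins <- make_windows(pool, size = size, step = step)
    Xref <- X[ref_idx, , drop = FALSE]
    for (wi in seq_along(wins)) {
      idx <- wins[[wi]]
      Xw <- X[idx, , drop = FALSE]
      sd_seed <- (as.integer(seed) + 7919L * wi +
                    31L * match(sp, names(X_by_species))) %% .Machine$integer.max
      bt <- bootstrap_compare(Xw, Xref, "theta", n_boot = n_boot, seed = sd_seed)
      bd <- bootstrap_compare(Xw, Xref, "distance", n_boot = n_boot, seed = sd_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, window_index = wi,
        mean_distance_km = mean(abs(pos[idx] - contact_km)),
        mean_position_km = mean(pos[idx]),
        theta_deg = bt$observed, theta_p = bt$p_value,
        significant_theta = bt$significant,
        matrix_distance = bd$observed, distance_p = bd$p_value,
        significant_distance = bd$significant,
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- ids[idx]
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "members") <- members
  attr(out, "contact_km") <- contact_km
  class(out) <- c("window_scan", class(out))
  out
}

#' Test for a trend in windowed P-matrix divergence
#'
#' Ordinary least squares of the window statistic (theta or the matrix
#' distance) on mean distance from contact, species, and their interaction,
#' with the bootstrap significance state included as an additive covariate
#' (dropped automatically when constant across windows). Reports per-species
#' slopes and the Wald p-value of the species-by-distance interaction.
#'
#' @param results A `window_scan` data.frame covering both species.
#' @param statistic `"theta"` or `"distance"`.
#' @return List with `coefficients` (summary table), `slopes` (named
#'   per-species slope estimates), `interaction_p`, and the fitted `model`.
#' @export
trend_test <- function(results, statistic = c("theta", "distance")) {
  statistic <- match.arg(statistic)
  df <- as.data.frame(results)
  df$stat <- if (statistic == "theta") df$theta_deg else df$matrix_distance
  df$sig <- as.numeric(if (statistic == "theta") df$significant_theta
                       else df$significant_distance)
  if (length(unique(df$species)) < 2L)
    stop("trend test needs windows from both species")
  if (any(table(df$species) < 3L))
    stop("need at least 3 windows per species")
  df$species <- factor(df$species)
  form <- if (stats::var(df$sig) > 0)
    stat ~ mean_distance_km * species + sig else stat ~ mean_distance_km * species
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)$coefficients
  qr_ok <- !is.na(stats::coef(fit))
  if (!all(qr_ok)) stop("collinear design in trend test")
  lv <- levels(df$species)
  b <- stats::coef(fit)
  slope_base <- b[["mean_distance_km"]]
  int_name <- grep("^mean_distance_km:species", names(b), value = TRUE)
  slopes <- c(slope_base, slope_base + b[[int_name]])
  names(slopes) <- lv
  list(coefficients = sm, slopes = slopes,
       interaction_p = sm[int_name, "Pr(>|t|)"], model = fit)
}
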