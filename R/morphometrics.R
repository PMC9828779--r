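#' Reflect a landmark configuration
#'
#' Mirrors a configuration about the vertical axis (x negated), toggling its
#' `flipped` flag. Used to bring left-side structures into the orientation of
#' right-side ones before superimposition, mimicking the horizontal flip of a
#' scanned image.
#'
#' @param cfg A [landmark_set].
#' @return The reflected [landmark_set].
#' @export
reflect_config <- function(cfg) {
  stopifnot(inherits(cfg, "landmark_set"))
  coords <- cfg$coords
  coords[, 1] <- -coords[, 1]
  landmark_set(cfg$specimen_id, coords, flipped = !cfg$flipped, scale = cfg$scale)
}

centroid_size <- function(coords) {
  cen <- colMeans(coords)
  sqrt(sum(sweep(coords, 2, cen)^2))
}

# Optimal 2-D rotation (no reflection) aligning X onto Y, both centered.
opt_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes analysis
#'
#' Iteratively removes translation, scale and rotation from a set of 2-D
#' landmark configurations: each configuration is centered at the origin,
#' scaled to unit centroid size, and rotated to minimize its summed squared
#' distance to the current consensus; the consensus is the mean of the aligned
#' configurations, itself rescaled to unit centroid size. Iteration stops when
#' the consensus changes by less than `tol` (root summed squared coordinate
#' change). Reflections are never applied during alignment — mirrored
#' configurations must be handled beforehand with [reflect_config()].
#'
#' @param configs List of [landmark_set] objects with equal landmark counts.
#' @param tol Convergence tolerance on the consensus update.
#' @param max_iter Maximum number of consensus updates.
#'
#' @return A list of class `procrustes_result` with elements `aligned`
#'   (specimens x 2k matrix of Procrustes coordinates, columns
#'   `x1,y1,...,xk,yk`), `consensus` (k x 2 mean shape, unit centroid size),
#'   `centroid_sizes`, `specimen_ids`, `n_iter` and `converged`.
#' @export
generalized_procrustes <- function(configs, tol = 1e-8, max_iter = 100L) {
  if (length(configs) < 2L) stop("need at least 2 configurations")
  k <- vapply(configs, function(c) c$n_landmarks, integer(1))
  if (length(unique(k)) != 1L)
    stop("all configurations must have the same number of landmarks (found ",
         paste(unique(k), collapse = ", "), ")")
  k <- k[1]
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  sizes <- numeric(length(configs))
  mats <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    co <- configs[[i]]$coords
    co <- sweep(co, 2, colMeans(co))
    cs <- sqrt(sum(co^2))
    if (cs < .Machine$double.eps * k)
      stop("degenerate configuration (all landmarks coincide): ", ids[i])
    sizes[i] <- cs
    mats[[i]] <- co / cs
  }
  consensus <- mats[[1]]
  n_iter <- 0L
  converged <- FALSE
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    for (i in seq_along(mats))
      mats[[i]] <- mats[[i]] %*% opt_rotation(mats[[i]], consensus)
    new_cons <- Reduce(`+`, mats) / length(mats)
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    # align the new consensus to the old one to remove rotational drift
    new_cons <- new_cons %*% opt_rotation(new_cons, consensus)
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  aligned <- t(vapply(mats, function(m) as.vector(t(m)), numeric(2 * k)))
  colnames(aligned) <- as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k)))
  rownames(aligned) <- ids
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = sizes, specimen_ids = ids,
                 n_iter = n_iter, converged = converged),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> %d specimens, %d landmarks, %d iterations (%s)\n",
              nrow(x$aligned), ncol(x$aligned) / 2, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Wing length from a raw configuration
#'
#' Euclidean distance between two landmarks in the original digitized units
#' (before any Procrustes alignment). The default pair (1, 4) is the
#' conventional base-to-apex wing-length measure.
#'
#' @param cfg A [landmark_set].
#' @param i,j 1-based landmark indices.
#' @return Nonnegative numeric distance.
#' @export
wing_length <- function(cfg, i = 1L, j = 4L) {
  stopifnot(inherits(cfg, "landmark_set"))
  if (i < 1L || j < 1L || i > cfg$n_landmarks || j > cfg$n_landmarks)
    stop("landmark index out of range (configuration has ",
         cfg$n_landmarks, " landmarks)")
  sqrt(sum((cfg$coords[i, ] - cfg$coords[j, ])^2))
}

#' Size-correct traits by regression on a body-size measure
#'
#' Returns, for each trait column, the residuals of an ordinary
#' least-squares regression of the untransformed trait on `size` (here,
#' measured wing length). Residuals have zero mean and zero sample covariance
#' with `size`.
#'
#' @param traits Numeric matrix, specimens x variables.
#' @param size Numeric vector of per-specimen sizes.
#' @return Residual matrix with the same dimensions and dimnames as `traits`.
#' @export
size_correct <- function(traits, size) {
  traits <- as.matrix(traits)
  if (nrow(traits) < 3L) stop("need at least 3 specimens for size correction")
  if (length(size) != nrow(traits)) stop("size length must match specimen count")
  if (anyNA(size)) stop("missing size values are not allowed")
  if (stats::sd(size) == 0) stop("size is constant; regression undefined")
  res <- stats::lm.fit(cbind(1, size), traits)$residuals
  res <- as.matrix(res)
  dimnames(res) <- dimnames(traits)
  res
}

#' Principal component analysis of trait matrices
#'
#' PCA on the sample covariance (n-1 denominator), without variable scaling:
#' Procrustes coordinates share units, so correlation-based scaling would
#' distort shape variation. Scores are the centered data projected on the
#' eigenvectors ordered by decreasing eigenvalue. Each loading vector is
#' oriented so its largest-magnitude entry is positive, making score signs
#' reproducible across runs and platforms.
#'
#' @param X Numeric matrix, specimens x variables.
#' @param center Center columns first (default `TRUE`).
#' @return A list of class `shape_scores`: `scores` (specimens x components),
#'   `loadings` (components x variables, rows unit length), `var_fraction`,
#'   `eigenvalues`, and `center` (column means used).
#' @export
pca <- function(X, center = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 specimens")
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc)
  ev <- s$d^2 / (nrow(X) - 1)
  if (sum(ev) <= 0) stop("matrix has rank 0; PCA undefined")
  rot <- s$v
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(ncol(rot))) {
    big <- which.max(abs(rot[, j]))
    if (rot[big, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- Xc %*% rot
  ncomp <- min(nrow(X) - 1L, ncol(X))
  scores <- scores[, seq_len(ncomp), drop = FALSE]
  rot <- rot[, seq_len(ncomp), drop = FALSE]
  ev <- ev[seq_len(ncomp)]
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  rownames(scores) <- rownames(X)
  loadings <- t(rot)
  rownames(loadings) <- colnames(scores)
  colnames(loadings) <- colnames(X)
  structure(list(scores = scores, loadings = loadings,
                 var_fraction = ev / sum(ev), eigenvalues = ev, center = mu),
            class = "shape_scores")
}

#' @export
print.shape_scores <- function(x, ...) {
  vf <- x$var_fraction[seq_len(min(5, length(x$var_fraction)))]
  cat(sprintf("<shape_scores> %d specimens, %d components; leading var fractions: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", vf), collapse = " ")))
  invisible(x)
}
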