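ridge_solve <- function(S, b, ridge = TRUE) {
  d <- ncol(S)
  out <- tryCatch(solve(S, b), error = function(e) NULL)
  if (!is.null(out) && rcond(S) > 1e-10) return(out)
  if (!ridge)
    stop("pooled covariance is singular; re-run with ridge = TRUE")
  lambda <- 1e-8 * sum(diag(S)) / d
  solve(S + diag(lambda, d), b)
}

#' Fit a two-class linear discriminant
#'
#' Fisher's linear discriminant under equal-covariance Gaussian
#' class-conditionals: the weight vector is the pooled-covariance inverse
#' applied to the difference of class means, and the decision threshold is the
#' midpoint between projected class means shifted by the log prior ratio.
#' Because Procrustes coordinate blocks are rank-deficient (2k coordinates
#' lose 4 dimensions to the superimposition), a small ridge
#' (1e-8 * trace/dim) is added to the pooled covariance when it is
#' near-singular.
#'
#' @param X Numeric matrix, specimens x variables (training set).
#' @param labels Two-level factor or character vector of class labels.
#' @param equal_priors Use equal priors instead of training class frequencies.
#' @param ridge Allow the ridge fallback for near-singular pooled covariance.
#' @return A list of class `discriminant_model`: `weights`, `threshold`,
#'   `class_means`, `pooled_cov`, `priors`, `classes`, `variables`, and
#'   `confusion` (training-set confusion counts).
#' @export
fit_lda <- function(X, labels, equal_priors = FALSE, ridge = TRUE) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("exactly two classes required, got: ",
                              paste(cls, collapse = ", "))
  n <- nrow(X); d <- ncol(X)
  if (n < d + 1L) stop("need at least variables+1 training specimens")
  iA <- labels == cls[1]; iB <- labels == cls[2]
  nA <- sum(iA); nB <- sum(iB)
  if (nA < 2L || nB < 2L) stop("each class needs at least 2 specimens")
  muA <- colMeans(X[iA, , drop = FALSE])
  muB <- colMeans(X[iB, , drop = FALSE])
  Sp <- ((nA - 1) * stats::cov(X[iA, , drop = FALSE]) +
         (nB - 1) * stats::cov(X[iB, , drop = FALSE])) / (n - 2)
  w <- drop(ridge_solve(Sp, muA - muB, ridge = ridge))
  priors <- if (equal_priors) c(0.5, 0.5) else c(nA, nB) / n
  names(priors) <- cls
  threshold <- sum(w * (muA + muB)) / 2 - log(priors[1] / priors[2])
  model <- structure(
    list(weights = w, threshold = unname(threshold),
         class_means = rbind(muA, muB), pooled_cov = Sp, priors = priors,
         classes = cls, variables = colnames(X)),
    class = "discriminant_model")
  pred <- assign_species(model, X)
  model$confusion <- table(truth = factor(labels, cls),
                           predicted = factor(pred$label, cls))
  model
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> classes %s vs %s, %d variables, priors %.2f/%.2f\n",
              x$classes[1], x$classes[2], length(x$weights),
              x$priors[1], x$priors[2]))
  if (!is.null(x$confusion)) {
    acc <- sum(diag(x$confusion)) / sum(x$confusion)
    cat(sprintf("  training accuracy: %.3f\n", acc))
  }
  invisible(x)
}

#' Assign specimens to species with a fitted discriminant
#'
#' Labels each row of `X` by the maximum-posterior class under
#' equal-covariance Gaussian class-conditionals with the training priors.
#' The returned `score` is the linear discriminant value `w'x`; the posterior
#' for the first class is `plogis(score - threshold)`.
#'
#' @param model A `discriminant_model` from [fit_lda()].
#' @param X Numeric matrix with the training variables (matched by name when
#'   column names are present).
#' @return A data.frame with columns `label`, `score`, `posterior_A` (posterior
#'   probability of the model's first class) and `posterior` (posterior of the
#'   assigned class).
#' @export
assign_species <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$variables) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$variables)) {
    if (anyDuplicated(model$variables) || anyDuplicated(colnames(X)))
      stop("duplicate column names make variable matching ambiguous; ",
           "supply columns in the training order with unique names")
    if (!all(model$variables %in% colnames(X)))
      stop("query columns do not match training variables")
    X <- X[, model$variables, drop = FALSE]
  } else if (ncol(X) != length(model$weights)) {
    stop("query has ", ncol(X), " columns; model expects ",
         length(model$weights))
  }
  score <- drop(X %*% model$weights)
  pA <- stats::plogis(score - model$threshold)
  label <- ifelse(pA >= 0.5, model$classes[1], model$classes[2])
  data.frame(label = label, score = score, posterior_A = pA,
             posterior = pmax(pA, 1 - pA),
             row.names = rownames(X), stringsAsFactors = FALSE)
}

#' Filter low-confidence assignments
#'
#' Retains specimens whose squared Mahalanobis distance to their assigned
#' class centroid lies within the chi-square quantile at `level` with as many
#' degrees of freedom as trait variables — a per-class multivariate
#' confidence region. This reduces false-positive assignments near the
#' class boundary and removes phenotypic outliers.
#'
#' @param X Numeric matrix of the traits used for assignment.
#' @param labels Assigned class label per row of `X`.
#' @param level Confidence level in (0, 1); default 0.97.
#' @param joint If `TRUE`, use a single centroid and covariance over all
#'   specimens instead of per-class regions.
#' @param ridge Allow ridge fallback for near-singular class covariances.
#' @return Logical vector, `TRUE` for retained specimens (named by rownames
#'   of `X` when present).
#' @export
confidence_filter <- function(X, labels, level = 0.97, joint = FALSE,
                              ridge = TRUE) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  X <- as.matrix(X)
  labels <- as.character(labels)
  d <- ncol(X)
  cutoff <- stats::qchisq(level, df = d)
  keep <- rep(NA, nrow(X))
  groups <- if (joint) list(all = seq_len(nrow(X))) else split(seq_len(nrow(X)), labels)
  for (idx in groups) {
    Xi <- X[idx, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- stats::cov(Xi)
    dev <- sweep(Xi, 2, mu)
    md2 <- rowSums(dev * t(ridge_solve(S, t(dev), ridge = ridge)))
    keep[idx] <- md2 <= cutoff
  }
  names(keep) <- rownames(X)
  keep
}
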