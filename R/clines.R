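#' Rescale a score vector to [0, 1]
#'
#' `(y - min) / (max - min)`. Cline fits are performed on rescaled scores so
#' that centers and widths are comparable across trait sets; the operation is
#' idempotent.
#'
#' @param y Numeric vector with `min(y) < max(y)`.
#' @return Numeric vector in \[0, 1\].
#' @export
rescale01 <- function(y) {
  r <- range(y, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] >= r[2])
    stop("cannot rescale a constant (or empty) vector")
  (y - r[1]) / (r[2] - r[1])
}

#' Sigmoid cline mean function
#'
#' `y_left + (y_right - y_left) / (1 + exp(-4 (x - c) / w))`. The factor 4
#' makes `w` the conventional cline width: the maximum slope, attained at the
#' center `c`, is `(y_right - y_left) / w`, so for a 0-to-1 cline `w` is the
#' inverse of the maximum slope.
#'
#' @param x Position(s) along the transect (km).
#' @param c Cline center (km).
#' @param w Cline width (km), strictly positive.
#' @param y_left,y_right Asymptotic values at the two transect ends.
#' @return Numeric vector of cline means.
#' @export
sigmoid_mean <- function(x, c, w, y_left, y_right) {
  if (w <= 0) stop("cline width must be positive")
  y_left + (y_right - y_left) / (1 + exp(-4 * (x - c) / w))
}

# Profile log-likelihood at fixed (c, w): the sigmoid mean is linear in
# (y_left, y_right - y_left), so those and sigma have closed-form MLEs.
cline_profile_logl <- function(x, y, c, w) {
  s <- 1 / (1 + exp(-4 * (x - c) / w))
  fit <- stats::lm.fit(cbind(1, s), y)
  n <- length(y)
  sigma2 <- max(sum(fit$residuals^2) / n, 1e-24)
  list(logL = -n / 2 * (log(2 * pi * sigma2) + 1),
       y_left = unname(fit$coefficients[1]),
       y_right = unname(fit$coefficients[1] + fit$coefficients[2]),
       sigma = sqrt(sigma2))
}

#' Fit an individual-based sigmoid cline by maximum likelihood
#'
#' Fits `y_i ~ Normal(sigmoid_mean(x_i; c, w, y_left, y_right), sigma)` over
#' all individuals, together with a constant model `y_i ~ Normal(mu, sigma)`,
#' and returns the AIC-preferred model. The likelihood is profiled: for fixed
#' (center, width) the end values and residual SD have closed-form maximum
#' likelihood estimates, so the numerical search is 2-dimensional and is run
#' from multiple starting points (centers on deciles of `x` with seeded
#' jitter, widths log-uniform) because the likelihood surface is multi-modal
#' in the center. The center is bounded to the observed `x` range and the
#' width to `(width_floor, range(x))`; a fit at the width floor is flagged
#' (`width_boundary`), which matters for near-step clines.
#'
#' @param x Individual positions (km).
#' @param y Individual scores, typically [rescale01()]d.
#' @param n_starts Number of optimizer starts (default 20).
#' @param seed Integer seed for start-point jitter.
#' @param width_floor Lower bound on the width (km); default 0.001 (1 m),
#'   keeping the likelihood finite for step-like data.
#' @return A list of class `cline_fit` with `center_km`, `width_km`,
#'   `y_left`, `y_right`, `sigma`, `logL`, `aic`, `model` ("sigmoid" or
#'   "constant"), `width_boundary`, `center_ci` (NA until [profile_ci()] is
#'   called), the constant-model `logL_constant`/`aic_constant`, `n`, and the
#'   bounds used.
#' @export
fit_cline <- function(x, y, n_starts = 20L, seed = 1L, width_floor = 0.001) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (n < 10L) stop("need at least 10 individuals to fit a cline")
  xr <- range(x)
  span <- diff(xr)
  if (span <= 0) stop("x must span a positive range")
  # constant model (MLE sigma uses 1/n)
  mu <- mean(y)
  sigma2c <- max(mean((y - mu)^2), 1e-24)
  logL_const <- -n / 2 * (log(2 * pi * sigma2c) + 1)
  aic_const <- 2 * 2 - 2 * logL_const

  lw_lo <- log(width_floor); lw_hi <- log(span)
  nll <- function(par) -cline_profile_logl(x, y, par[1], exp(par[2]))$logL
  set.seed(as.integer(seed))
  dec <- stats::quantile(x, probs = seq(0.05, 0.95, length.out = n_starts),
                         names = FALSE)
  starts <- cbind(
    c = pmin(xr[2], pmax(xr[1], dec + stats::runif(n_starts, -0.02, 0.02) * span)),
    lw = stats::runif(n_starts, lw_lo, lw_hi))
  best <- NULL
  for (s in seq_len(n_starts)) {
    o <- tryCatch(
      stats::optim(starts[s, ], nll, method = "L-BFGS-B",
                   lower = c(xr[1], lw_lo), upper = c(xr[2], lw_hi),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop("cline optimizer failed to converge from any start (n = ", n,
         ", x range ", xr[1], "-", xr[2], ")")
  c_hat <- unname(best$par[1]); w_hat <- unname(exp(best$par[2]))
  prof <- cline_profile_logl(x, y, c_hat, w_hat)
  logL_sig <- prof$logL
  aic_sig <- 2 * 5 - 2 * logL_sig
  use_sigmoid <- aic_sig <= aic_const
  structure(list(
    model = if (use_sigmoid) "sigmoid" else "constant",
    center_km = if (use_sigmoid) c_hat else NA_real_,
    width_km = if (use_sigmoid) w_hat else NA_real_,
    y_left = if (use_sigmoid) prof$y_left else mu,
    y_right = if (use_sigmoid) prof$y_right else mu,
    sigma = if (use_sigmoid) prof$sigma else sqrt(sigma2c),
    logL = if (use_sigmoid) logL_sig else logL_const,
    aic = if (use_sigmoid) aic_sig else aic_const,
    logL_sigmoid = logL_sig, aic_sigmoid = aic_sig,
    logL_constant = logL_const, aic_constant = aic_const,
    width_boundary = use_sigmoid && (w_hat <= width_floor * (1 + 1e-6)),
    center_ci = c(NA_real_, NA_real_),
    n = n, x_range = xr, width_floor = width_floor),
    class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  if (x$model == "constant") {
    cat(sprintf("<cline_fit> constant model preferred (AIC %.1f vs sigmoid %.1f), mean = %.3f\n",
                x$aic_constant, x$aic_sigmoid, x$y_left))
  } else {
    w <- x$width_km
    wtxt <- if (w < 1) sprintf("%.0f m", w * 1000) else sprintf("%.3f km", w)
    cat(sprintf("<cline_fit> center = %.3f km%s, width = %s%s, ends %.3f -> %.3f, AIC %.1f\n",
                x$center_km,
                if (!anyNA(x$center_ci)) sprintf(" [%.3f, %.3f]", x$center_ci[1], x$center_ci[2]) else "",
                wtxt, if (x$width_boundary) " (at floor)" else "",
                x$y_left, x$y_right, x$aic))
  }
  invisible(x)
}

#' Profile-likelihood confidence interval for a cline parameter
#'
#' The interval is the set of fixed values of the parameter whose profile
#' log-likelihood (all other parameters re-optimized) lies within
#' `qchisq(level, 1) / 2` of the maximum (1.9207 at level 0.95). Endpoints
#' are located by bisection to 1e-4 km between the estimate and the fitting
#' bounds; if the profile never drops below the cutoff before a bound, that
#' side is returned at the bound and flagged (`attr(ci, "boundary")`).
#'
#' @param fit A `cline_fit` with `model = "sigmoid"`.
#' @param x,y The data the cline was fitted to.
#' @param param `"center_km"` or `"width_km"`.
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric `(low, high)` with a logical `boundary`
#'   attribute per side.
#' @export
profile_ci <- function(fit, x, y, param = c("center_km", "width_km"),
                       level = 0.95) {
  param <- match.arg(param)
  if (fit$model != "sigmoid")
    stop("profile CI requires a sigmoid fit (constant model selected)")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  xr <- fit$x_range
  lw_lo <- log(fit$width_floor); lw_hi <- log(diff(xr))
  cutoff <- fit$logL_sigmoid - stats::qchisq(level, df = 1) / 2
  # the nuisance-parameter search can miss narrow likelihood spikes (the
  # surface is nearly flat in the center when the width is tiny), so the
  # profile is floored at the value with the nuisance held at its joint MLE
  if (param == "center_km") {
    prof <- function(v) {
      o <- stats::optimize(function(lw) cline_profile_logl(x, y, v, exp(lw))$logL,
                           interval = c(lw_lo, lw_hi), maximum = TRUE,
                           tol = 1e-9)
      max(o$objective, cline_profile_logl(x, y, v, fit$width_km)$logL)
    }
    mle <- fit$center_km; lo_bound <- xr[1]; hi_bound <- xr[2]
  } else {
    prof <- function(v) {
      o <- stats::optimize(function(cc) cline_profile_logl(x, y, cc, v)$logL,
                           interval = xr, maximum = TRUE, tol = 1e-9)
      max(o$objective, cline_profile_logl(x, y, fit$center_km, v)$logL)
    }
    mle <- fit$width_km; lo_bound <- fit$width_floor; hi_bound <- diff(xr)
  }
  find_side <- function(bound) {
    if (prof(bound) >= cutoff) return(list(v = bound, boundary = TRUE))
    lo <- min(bound, mle); hi <- max(bound, mle)
    # invariant: prof >= cutoff at the MLE side, < cutoff at the bound side
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      inside <- prof(mid) >= cutoff
      if (bound < mle) { if (inside) hi <- mid else lo <- mid }
      else             { if (inside) lo <- mid else hi <- mid }
      if (hi - lo < 1e-4) break
    }
    list(v = (lo + hi) / 2, boundary = FALSE)
  }
  left <- find_side(lo_bound)
  right <- find_side(hi_bound)
  ci <- c(left$v, right$v)
  attr(ci, "boundary") <- c(low = left$boundary, high = right$boundary)
  attr(ci, "level") <- level
  ci
}
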