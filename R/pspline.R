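## Penalized cubic regression splines with an exact second-derivative penalty.
## Shared numerical core for harmonization mapping, FPCA row smoothing, and
## 24-hour median-curve smoothing.

#' Build a cubic B-spline basis with quantile-placed knots
#'
#' Knots are placed at quantiles of the observed predictor so the basis
#' resolves curvature where the data are dense (activity counts are heavily
#' right-skewed). Boundary knots are replicated to order 4.
#'
#' @param x numeric predictor values.
#' @param nbasis number of basis functions (basis dimension).
#' @return list with `knots` (full knot vector) and `range` (boundary).
#' @keywords internal
#' @noRd
spline_knots <- function(x, nbasis = 30L) {
  xu <- sort(unique(x[is.finite(x)]))
  if (length(xu) < 2L)
    stop("need at least 2 distinct predictor values", call. = FALSE)
  n_interior <- nbasis - 4L
  if (n_interior < 0L) stop("nbasis must be >= 4", call. = FALSE)
  ## cap the basis when the data cannot support it
  n_interior <- min(n_interior, max(length(xu) - 4L, 0L))
  rng <- range(xu)
  interior <- if (n_interior > 0L) {
    probs <- seq_len(n_interior) / (n_interior + 1L)
    as.numeric(stats::quantile(xu, probs, type = 7, names = FALSE))
  } else numeric(0)
  interior <- interior[interior > rng[1] & interior < rng[2]]
  interior <- unique(interior)
  knots <- c(rep(rng[1], 4L), interior, rep(rng[2], 4L))
  list(knots = knots, range = rng, nbasis = length(interior) + 4L)
}

#' Evaluate the B-spline design matrix, clamping outside the boundary
#' @keywords internal
#' @noRd
spline_design <- function(kn, x, derivs = 0L) {
  xc <- pmin(pmax(x, kn$range[1]), kn$range[2])
  splines::splineDesign(kn$knots, xc, ord = 4L,
                        derivs = rep(derivs, length(xc)), outer.ok = FALSE)
}

#' Exact second-derivative penalty matrix
#'
#' For cubic B-splines the second derivatives are piecewise linear, so their
#' pairwise products are piecewise quadratic and Simpson's rule on each
#' inter-knot interval integrates them exactly.
#' @keywords internal
#' @noRd
spline_penalty <- function(kn) {
  brk <- unique(kn$knots)
  K <- kn$nbasis
  S <- matrix(0, K, K)
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    h <- b - a
    if (h <= 0) next
    pts <- c(a, (a + b) / 2, b)
    ## evaluate just inside the interval to pick the correct polynomial piece
    eps <- h * 1e-9
    pts[1] <- pts[1] + eps; pts[3] <- pts[3] - eps
    D2 <- splines::splineDesign(kn$knots, pts, ord = 4L,
                                derivs = rep(2L, 3L))
    S <- S + (h / 6) * (tcrossprod(D2[1, ]) + 4 * tcrossprod(D2[2, ]) +
                          tcrossprod(D2[3, ]))
  }
  (S + t(S)) / 2
}

#' Fit a penalized cubic regression spline
#'
#' Minimizes `||y - f(x)||^2 + lambda * integral(f'')^2` over a cubic
#' B-spline basis. The smoothing parameter is chosen by generalized
#' cross-validation over a log-spaced grid unless supplied.
#'
#' @param x,y numeric vectors of equal length; non-finite pairs are dropped.
#' @param nbasis basis dimension (default 30).
#' @param lambda fixed smoothing parameter; `NULL` (default) selects by GCV.
#' @param lambda_grid candidate smoothing parameters for GCV.
#' @param weights optional nonnegative observation weights.
#' @return an object of class `accel_pspline` with elements `coef`, `knots`,
#'   `lambda`, `edf`, `gcv`, `sigma2` (residual variance) and `n`.
#' @examples
#' x <- seq(0, 10, length.out = 200)
#' fit <- fit_pspline(x, sin(x) + rnorm(200, sd = 0.1))
#' plot(x, predict(fit, x), type = "l")
#' @export
fit_pspline <- function(x, y, nbasis = 30L, lambda = NULL,
                        lambda_grid = 10 ^ seq(-6, 8, length.out = 29),
                        weights = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(weights)) ok <- ok & is.finite(weights) & weights >= 0
  x <- x[ok]; y <- y[ok]
  w <- if (is.null(weights)) rep(1, length(x)) else weights[ok]
  n <- length(x)
  if (n < 5L) stop("too few observations for spline fitting", call. = FALSE)
  kn <- spline_knots(x, nbasis)
  X <- spline_design(kn, x)
  S <- spline_penalty(kn)
  ## scale the penalty so the lambda grid is comparable across problems
  s_scale <- mean(diag(crossprod(X * sqrt(w)))) / max(mean(diag(S)), .Machine$double.eps)
  Ssc <- S * s_scale
  XtWX <- crossprod(X * sqrt(w))
  XtWy <- crossprod(X, w * y)
  yty <- sum(w * y ^ 2)
  solve_for <- function(lam) {
    A <- XtWX + lam * Ssc
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) {
      A <- A + diag(1e-8 * mean(diag(A)), nrow(A))
      R <- chol(A)
    }
    cf <- backsolve(R, forwardsolve(t(R), XtWy))
    edf <- sum(diag(backsolve(R, forwardsolve(t(R), XtWX))))
    rss <- max(yty - 2 * sum(cf * XtWy) + sum(cf * (XtWX %*% cf)), 0)
    list(coef = cf, edf = edf, rss = rss,
         gcv = n * rss / max(n - edf, 1e-8) ^ 2)
  }
  if (is.null(lambda)) {
    fits <- lapply(lambda_grid, solve_for)
    best <- which.min(vapply(fits, `[[`, numeric(1), "gcv"))
    lambda <- lambda_grid[best]
    ft <- fits[[best]]
  } else {
    ft <- solve_for(lambda)
  }
  structure(list(coef = drop(ft$coef), knots = kn, lambda = lambda,
                 edf = ft$edf, gcv = ft$gcv,
                 sigma2 = ft$rss / max(n - ft$edf, 1),
                 n = n),
            class = "accel_pspline")
}

#' Predict from a penalized spline fit
#'
#' Values outside the fitted range evaluate at the nearest boundary
#' (constant extrapolation).
#'
#' @param object an `accel_pspline` fit.
#' @param newdata numeric vector of predictor values.
#' @param ... unused.
#' @export
predict.accel_pspline <- function(object, newdata, ...) {
  drop(spline_design(object$knots, newdata) %*% object$coef)
}

#' @export
print.accel_pspline <- function(x, ...) {
  cat(sprintf("Penalized cubic regression spline: %d basis functions, n = %d\n",
              x$knots$nbasis, x$n))
  cat(sprintf("  lambda = %.4g, edf = %.2f, GCV = %.4g\n",
              x$lambda, x$edf, x$gcv))
  invisible(x)
}
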