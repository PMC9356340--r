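## Harmonization between minute-level activity counts (AC) and each
## open-source measure: a penalized cubic regression spline (basis
## dimension 30, second-derivative penalty, smoothing parameter by GCV)
## fitted to all valid minutes with AC > 0, evaluated on a dense log-spaced
## count grid, monotonized by isotonic projection solely for inversion.
## Monotonicity is not constrained during fitting.

#' Fit a harmonization mapping measure = f(activity count)
#'
#' Minutes with `ac == 0` are excluded from fitting: the mass of zeros
#' would otherwise dominate the fit at small counts. Zero-count minutes
#' are still mapped at prediction/inversion time.
#'
#' @param ac minute-level activity counts.
#' @param measure minute-level measure values (same length).
#' @param measure_name label stored on the model.
#' @param nbasis spline basis dimension (default 30).
#' @param grid_size evaluation-grid size (default 2000, log-spaced).
#' @param lambda optional fixed smoothing parameter; default GCV.
#' @param max_n optional cap on fitting-sample size; when exceeded a
#'   seeded uniform subsample of `max_n` pairs is used.
#' @param subsample_seed seed for the optional subsample.
#' @return object of class `harmonization_model`: the spline fit, the
#'   evaluation grid with fitted values, a monotonized inverse table, and
#'   fitting metadata.
#' @export
fit_mapping <- function(ac, measure, measure_name = "measure", nbasis = 30L,
                        grid_size = 2000L, lambda = NULL, max_n = NULL,
                        subsample_seed = 1L) {
  ok <- is.finite(ac) & is.finite(measure) & ac > 0
  ac <- ac[ok]; measure <- measure[ok]
  if (length(ac) < 100L)
    stop("fit_mapping: need at least 100 pairs with ac > 0", call. = FALSE)
  if (diff(range(ac)) == 0)
    stop("fit_mapping: constant activity count predictor", call. = FALSE)
  if (!is.null(max_n) && length(ac) > max_n) {
    old <- local_seed(subsample_seed)
    on.exit(restore_seed(old), add = TRUE)
    sel <- sample.int(length(ac), max_n)
    ac <- ac[sel]; measure <- measure[sel]
  }
  fit <- fit_pspline(ac, measure, nbasis = nbasis, lambda = lambda)
  grid <- exp(seq(log(min(ac)), log(max(ac)), length.out = grid_size))
  ## measures are nonnegative by definition; floor the fitted map at 0
  fitted_grid <- pmax(predict(fit, grid), 0)
  iso <- stats::isoreg(seq_along(grid), fitted_grid)$yf
  nonmono <- max(abs(fitted_grid - iso))
  if (nonmono > 1e-8 * max(abs(fitted_grid)))
    warning(sprintf(
      "fit_mapping(%s): nonmonotone fit corrected by isotonic projection (max |delta| = %.4g)",
      measure_name, nonmono), call. = FALSE)
  structure(list(measure_name = measure_name, fit = fit,
                 nbasis = fit$knots$nbasis, lambda = fit$lambda,
                 grid = grid, fitted = fitted_grid, fitted_mono = iso,
                 n_fit = length(ac), ac_range = range(ac),
                 nonmonotonicity = nonmono),
            class = "harmonization_model")
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat(sprintf("harmonization_model [%s]: %d basis functions, lambda = %.4g\n",
              x$measure_name, x$nbasis, x$lambda))
  cat(sprintf("  fitted on %d minutes with AC in [%.1f, %.1f] (AC = 0 excluded)\n",
              x$n_fit, x$ac_range[1], x$ac_range[2]))
  invisible(x)
}

#' Predict a measure value from an activity count
#'
#' Counts outside the fitted range (including 0) clamp to the endpoint
#' fitted values; an `extrapolated` attribute flags them.
#'
#' @param model a [harmonization_model].
#' @param ac activity count value(s), nonnegative.
#' @return fitted measure value(s).
#' @export
predict_measure <- function(model, ac) {
  stopifnot(inherits(model, "harmonization_model"))
  if (any(ac < 0, na.rm = TRUE))
    stop("predict_measure: negative activity count", call. = FALSE)
  extrap <- !is.na(ac) & (ac < model$ac_range[1] | ac > model$ac_range[2])
  out <- pmax(predict(model$fit, pmin(pmax(ac, model$ac_range[1]),
                                      model$ac_range[2])), 0)
  out[is.na(ac)] <- NA_real_
  attr(out, "extrapolated") <- extrap
  out
}

#' Map a measure value back to an activity count
#'
#' Inverse lookup on the monotonized evaluation grid with linear
#' interpolation. Values below the smallest fitted value return 0; values
#' above the largest return the grid maximum (flagged).
#'
#' @param model a [harmonization_model].
#' @param x measure value(s), nonnegative.
#' @return estimated activity count(s), with attribute `clamped_high`.
#' @export
invert_to_ac <- function(model, x) {
  stopifnot(inherits(model, "harmonization_model"))
  if (any(x < 0, na.rm = TRUE))
    stop("invert_to_ac: negative measure value", call. = FALSE)
  f <- model$fitted_mono
  g <- model$grid
  ## collapse flat segments so the inverse is a function
  keep <- c(TRUE, diff(f) > 0)
  fk <- f[keep]; gk <- g[keep]
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (length(fk) < 2L) {
    out[ok] <- ifelse(x[ok] < fk[1], 0, gk[1])
  } else {
    out[ok] <- stats::approx(fk, gk, xout = pmin(pmax(x[ok], fk[1]), fk[length(fk)]),
                             ties = "ordered")$y
    out[ok & x < fk[1]] <- 0
  }
  high <- !is.na(x) & x > f[length(f)]
  out[high] <- g[length(g)]
  attr(out, "clamped_high") <- high
  out
}

#' Translate an activity-count cut-off into a measure-scale cut-off
#'
#' @param model a [harmonization_model].
#' @param ac_cutoff count cut-off(s); must lie within the fitted count
#'   range. The published wrist cut-offs 1853, 2860, and 3940 are typical
#'   inputs.
#' @return measure value(s) equivalent to the count threshold(s).
#' @export
translate_cutoff <- function(model, ac_cutoff) {
  stopifnot(inherits(model, "harmonization_model"))
  if (any(ac_cutoff < model$ac_range[1] | ac_cutoff > model$ac_range[2]))
    stop("translate_cutoff: cut-off outside the fitted count range",
         call. = FALSE)
  as.numeric(predict_measure(model, ac_cutoff))
}

#' Serialize a harmonization model to JSON
#' @param model a [harmonization_model].
#' @param path output path.
#' @export
write_harmonization_json <- function(model, path) {
  obj <- list(measure_name = model$measure_name,
              basis = list(type = "cubic_bspline", nbasis = model$nbasis,
                           knots = model$fit$knots$knots),
              lambda = model$lambda, coef = model$fit$coef,
              grid = model$grid, fitted = model$fitted,
              fitted_mono = model$fitted_mono,
              n_fit = model$n_fit, ac_range = model$ac_range,
              nonmonotonicity = model$nonmonotonicity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## seed handling that never clobbers the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
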