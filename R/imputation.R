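## Imputation of invalid minutes from smoothed diurnal profiles via
## functional principal component analysis (FPCA) of day-by-minute
## matrices. Rows are participant-days on the 1440-minute-of-day grid;
## day curves are projected on a penalized B-spline basis, eigenfunctions
## come from the coefficient covariance in the grid inner product, and
## scores are estimated from observed entries only (ridge/BLUP form), so
## missing entries are reconstructed from mean + principal components.

#' FPCA smoothing of a day-by-minute matrix
#'
#' @param mat numeric matrix, rows = participant-days, columns = minutes of
#'   day; missing entries allowed.
#' @param k_max maximum number of principal components (default 10).
#' @param pve proportion of variance explained used to choose the number of
#'   components (default 0.95).
#' @param nbasis penalized B-spline basis dimension over minute-of-day
#'   (default 30).
#' @param min_obs_frac rows with a smaller observed fraction are excluded
#'   from fitting and reconstructed from mean + projected scores
#'   (default 0.5).
#' @return object of class `fpca_fit`: `mean` (length D), `efunctions`
#'   (D x npc, orthonormal on the grid), `evalues`, `scores` (n x npc),
#'   `fitted` (n x D smooth surface), `npc`, `sigma2`, `excluded_rows`.
#' @export
fpca_smooth <- function(mat, k_max = 10L, pve = 0.95, nbasis = 30L,
                        min_obs_frac = 0.5) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  n <- nrow(mat); D <- ncol(mat)
  grid <- seq_len(D)
  kn <- spline_knots(grid, nbasis)
  B <- spline_design(kn, grid)
  K <- kn$nbasis
  S <- spline_penalty(kn)
  s_scale <- mean(diag(crossprod(B))) / max(mean(diag(S)), .Machine$double.eps)
  Ssc <- S * s_scale
  lambda_grid <- 10 ^ seq(-4, 6, length.out = 21)

  obs_frac <- rowMeans(is.finite(mat))
  fit_rows <- which(obs_frac >= min_obs_frac)
  excluded <- setdiff(seq_len(n), fit_rows)
  if (length(excluded))
    message("fpca_smooth: ", length(excluded),
            " row(s) below the observed-fraction threshold excluded from fitting")
  if (length(fit_rows) < 2L)
    stop("fpca_smooth: need at least 2 rows with enough observed entries",
         call. = FALSE)

  ## per-row penalized projection on the shared basis, GCV smoothing
  row_coef <- function(y) {
    o <- which(is.finite(y))
    Bo <- B[o, , drop = FALSE]
    yo <- y[o]
    XtX <- crossprod(Bo); Xty <- crossprod(Bo, yo)
    best <- NULL; best_gcv <- Inf
    for (lam in lambda_grid) {
      A <- XtX + lam * Ssc
      R <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(R)) next
      cf <- backsolve(R, forwardsolve(t(R), Xty))
      edf <- sum(diag(backsolve(R, forwardsolve(t(R), XtX))))
      rss <- sum((yo - Bo %*% cf) ^ 2)
      gcv <- length(o) * rss / max(length(o) - edf, 1e-8) ^ 2
      if (gcv < best_gcv) { best_gcv <- gcv; best <- list(cf = cf, rss = rss, edf = edf, nobs = length(o)) }
    }
    best
  }
  fits <- lapply(fit_rows, function(i) row_coef(mat[i, ]))
  C <- t(vapply(fits, function(f) drop(f$cf), numeric(K)))
  sigma2 <- mean(vapply(fits, function(f) f$rss / max(f$nobs - f$edf, 1),
                        numeric(1)))

  mu_c <- colMeans(C)
  mean_fn <- drop(B %*% mu_c)
  Cc <- sweep(C, 2, mu_c)
  Sigma_c <- crossprod(Cc) / max(nrow(Cc) - 1L, 1L)
  G <- crossprod(B)
  M <- chol(G)                      # G = t(M) %*% M
  eg <- eigen(M %*% Sigma_c %*% t(M), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tot <- sum(ev)
  if (tot <= max(1e-12, 1e-10 * sum(mean_fn ^ 2))) {
    npc <- 0L
  } else {
    npc <- which(cumsum(ev) / tot >= pve)[1]
    npc <- min(npc, k_max, length(ev))
  }
  if (npc > 0L) {
    V <- backsolve(M, eg$vectors[, seq_len(npc), drop = FALSE])
    Phi <- B %*% V                 # D x npc, orthonormal on the grid
    evalues <- ev[seq_len(npc)]
  } else {
    Phi <- matrix(0, D, 0L)
    evalues <- numeric(0)
  }

  ## scores from observed entries only (ridge with eigenvalue shrinkage)
  scores <- matrix(0, n, npc)
  fitted <- matrix(rep(mean_fn, each = n), n, D)
  if (npc > 0L) {
    for (i in seq_len(n)) {
      o <- which(is.finite(mat[i, ]))
      if (length(o) < npc + 1L) next
      Po <- Phi[o, , drop = FALSE]
      yc <- mat[i, o] - mean_fn[o]
      A <- crossprod(Po) + sigma2 * diag(1 / evalues, npc)
      scores[i, ] <- drop(solve(A, crossprod(Po, yc)))
    }
    fitted <- fitted + scores %*% t(Phi)
  }
  structure(list(mean = mean_fn, efunctions = Phi, evalues = evalues,
                 scores = scores, fitted = fitted, npc = npc,
                 sigma2 = sigma2, pve = pve,
                 excluded_rows = excluded),
            class = "fpca_fit")
}

#' @export
print.fpca_fit <- function(x, ...) {
  cat(sprintf("fpca_fit: %d rows x %d minutes, %d component(s), sigma2 = %.4g\n",
              nrow(x$fitted), length(x$mean), x$npc, x$sigma2))
  invisible(x)
}

minute_of_day_index <- function(time) {
  tn <- as.numeric(floor_minute(time))
  as.integer((tn %% 86400) / 60) + 1L
}

#' Build a day-by-minute matrix for one measure
#'
#' Entries at invalid minutes are set to missing.
#'
#' @param df minute-level data frame for one participant with `time`,
#'   `valid`, and the measure column.
#' @param measure measure column name.
#' @return matrix with one row per calendar day, 1440 columns, and
#'   rownames of the form "id date" when `participant_id` is present.
#' @export
day_by_minute_matrix <- function(df, measure) {
  date <- as.Date(floor_minute(df$time), tz = "UTC")
  mod <- minute_of_day_index(df$time)
  days <- sort(unique(date))
  mat <- matrix(NA_real_, length(days), 1440L)
  vals <- df[[measure]]
  vals[!df$valid] <- NA_real_
  for (k in seq_along(days)) {
    sel <- date == days[k]
    mat[k, mod[sel]] <- vals[sel]
  }
  rownames(mat) <- as.character(days)
  mat
}

#' Impute invalid minutes from FPCA-smoothed diurnal profiles
#'
#' Performed separately for each measure and each participant: the
#' participant's day-by-minute matrix (invalid minutes missing) is smoothed
#' by [fpca_smooth] and invalid minutes are replaced by the smooth surface
#' value, floored at 0. Valid minutes are never altered. Participants with
#' a single day fall back to a penalized-spline smooth of that day.
#'
#' @param cohort minute-level data frame (`participant_id`, `time`, `valid`,
#'   measure columns).
#' @param measures measure columns to impute.
#' @param k_max,pve,nbasis FPCA settings, see [fpca_smooth].
#' @return the cohort with invalid minutes imputed.
#' @export
impute_invalid <- function(cohort,
                           measures = c("ac", "mims", "enmo", "mad", "ai"),
                           k_max = 10L, pve = 0.95, nbasis = 30L) {
  out <- cohort
  for (id in unique(cohort$participant_id)) {
    rows <- which(cohort$participant_id == id)
    d <- cohort[rows, ]
    inv <- !d$valid
    if (!any(inv)) next
    mod <- minute_of_day_index(d$time)
    date <- as.Date(floor_minute(d$time), tz = "UTC")
    days <- sort(unique(date))
    day_idx <- match(date, days)
    for (ms in measures) {
      if (!ms %in% names(d)) next
      mat <- day_by_minute_matrix(d, ms)
      if (nrow(mat) >= 2L) {
        sm <- fpca_smooth(mat, k_max = k_max, pve = pve, nbasis = nbasis)$fitted
      } else {
        obs <- which(is.finite(mat[1, ]))
        if (length(obs) < 10L) next
        fit <- fit_pspline(obs, mat[1, obs], nbasis = nbasis)
        sm <- matrix(predict(fit, seq_len(1440L)), 1L, 1440L)
      }
      imputed <- pmax(sm[cbind(day_idx[inv], mod[inv])], 0)
      out[rows[inv], ms] <- imputed
    }
  }
  out
}
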