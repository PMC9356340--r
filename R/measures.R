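## Minute-level open-source summary measures of raw tri-axial acceleration:
## MIMS (resample, extrapolate clipped runs, band-pass, rectify, integrate),
## ENMO (Euclidean norm minus one, on autocalibrated data), MAD (mean
## amplitude deviation), and AI (activity intensity from per-axis sub-epoch
## variances). Every constant is surfaced in measure_params().

#' Parameters for the minute-level summary measures
#'
#' @param mims list: `resample_hz` (default 100), `band_low_hz` (0.2),
#'   `band_high_hz` (5), `filter_order` (4), `truncation_threshold` per
#'   axis-minute (1e-4), `extrapolate` ("quadratic" or "none"),
#'   `extrap_neighbors` points used on each side of a clipped run,
#'   `extrap_cap_factor` cap on extrapolated magnitude as a multiple of the
#'   dynamic range.
#' @param ai list: `noise_variance` systematic noise variance in g^2
#'   (default 0), `sub_epoch_s` (default 1).
#' @return list of class `measure_params`.
#' @export
measure_params <- function(mims = list(), ai = list()) {
  m <- utils::modifyList(list(resample_hz = 100, band_low_hz = 0.2,
                              band_high_hz = 5, filter_order = 4,
                              truncation_threshold = 1e-4,
                              extrapolate = "quadratic",
                              extrap_neighbors = 5L,
                              extrap_cap_factor = 1.5), mims)
  a <- utils::modifyList(list(noise_variance = 0, sub_epoch_s = 1), ai)
  stopifnot(m$band_low_hz > 0, m$band_low_hz < m$band_high_hz,
            m$band_high_hz < m$resample_hz / 2, a$sub_epoch_s > 0,
            a$noise_variance >= 0)
  structure(list(mims = m, ai = a), class = "measure_params")
}

#' Euclidean vector magnitude of tri-axial acceleration, in g
#' @param x,y,z acceleration per axis (g).
#' @return sqrt(x^2 + y^2 + z^2), elementwise.
#' @export
vector_magnitude <- function(x, y, z) sqrt(x ^ 2 + y ^ 2 + z ^ 2)

#' Euclidean norm minus one (ENMO) over an epoch
#'
#' Mean over samples of max(||a|| - 1, 0), in g. Computed on calibrated
#' data when a calibration model is supplied.
#'
#' @param x,y,z samples of one epoch (g).
#' @param calibration optional [calibration_model]; `NULL` means identity.
#' @return epoch ENMO (g), or `NA` for an empty epoch.
#' @export
compute_enmo <- function(x, y, z, calibration = NULL) {
  if (length(x) == 0L) return(NA_real_)
  if (!is.null(calibration)) {
    a <- apply_calibration(calibration, x, y, z)
    x <- a$x; y <- a$y; z <- a$z
  }
  mean(pmax(vector_magnitude(x, y, z) - 1, 0))
}

#' Mean amplitude deviation (MAD) over an epoch
#'
#' Mean absolute deviation of vector magnitudes from their epoch mean, in g.
#'
#' @param x,y,z samples of one epoch (g).
#' @return epoch MAD (g), or `NA` with fewer than 2 samples.
#' @export
compute_mad <- function(x, y, z) {
  if (length(x) < 2L) return(NA_real_)
  r <- vector_magnitude(x, y, z)
  mean(abs(r - mean(r)))
}

#' Activity intensity (AI) over an epoch
#'
#' The epoch is divided into sub-epochs of `sub_epoch_s` seconds; each
#' contributes sqrt(max(mean over axes of (var - noise_variance), 0)) and
#' the epoch value is the sum of sub-epoch contributions.
#'
#' @param x,y,z samples of one epoch (g).
#' @param sample_rate_hz sampling rate.
#' @param noise_variance systematic device noise variance (g^2).
#' @param sub_epoch_s sub-epoch length in seconds.
#' @return epoch AI (g), nonnegative.
#' @export
compute_ai <- function(x, y, z, sample_rate_hz, noise_variance = 0,
                       sub_epoch_s = 1) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  n_sub <- max(1L, round(sample_rate_hz * sub_epoch_s))
  idx <- split(seq_len(n), ceiling(seq_len(n) / n_sub))
  total <- 0
  for (ii in idx) {
    if (length(ii) < 2L) {
      warning("AI sub-epoch with < 2 samples contributes 0", call. = FALSE)
      next
    }
    v <- c(stats::var(x[ii]), stats::var(y[ii]), stats::var(z[ii]))
    total <- total + sqrt(max(mean(v - noise_variance), 0))
  }
  total
}

#' Construct an axis calibration model (per-axis gain and offset)
#'
#' Calibrated acceleration is `gain * a + offset`, per axis.
#'
#' @param gain numeric length-3 gains (unitless, near 1).
#' @param offset numeric length-3 offsets (g, near 0).
#' @param diagnostics optional list of fit diagnostics.
#' @export
calibration_model <- function(gain = c(1, 1, 1), offset = c(0, 0, 0),
                              diagnostics = list()) {
  stopifnot(length(gain) == 3L, length(offset) == 3L,
            all(is.finite(gain)), all(is.finite(offset)))
  structure(list(gain = as.numeric(gain), offset = as.numeric(offset),
                 diagnostics = diagnostics),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: gain (%.4f, %.4f, %.4f), offset (%+.4f, %+.4f, %+.4f)\n",
              x$gain[1], x$gain[2], x$gain[3],
              x$offset[1], x$offset[2], x$offset[3]))
  if (length(x$diagnostics))
    cat(sprintf("  still windows: %s, |err| %.5f -> %.5f\n",
                x$diagnostics$n_still_windows %||% "?",
                x$diagnostics$err_start %||% NA,
                x$diagnostics$err_end %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a calibration model to tri-axial samples
#' @param model a [calibration_model].
#' @param x,y,z acceleration samples (g).
#' @return list with calibrated `x`, `y`, `z`.
#' @export
apply_calibration <- function(model, x, y, z) {
  stopifnot(inherits(model, "calibration_model"))
  list(x = model$gain[1] * x + model$offset[1],
       y = model$gain[2] * y + model$offset[2],
       z = model$gain[3] * z + model$offset[3])
}

#' Estimate per-axis gain and offset from still periods (autocalibration)
#'
#' Still windows (all three axes with rolling SD below `still_sd_g` over
#' `win_s`-second windows) should lie on the unit gravity sphere; gains and
#' offsets are estimated by iteratively reweighted least squares projecting
#' window means onto the sphere. Falls back to the identity model with a
#' warning if no still windows are found or the still orientations do not
#' cover the sphere (per-axis spread below `coverage_min_g`).
#'
#' @param signal a [raw_signal].
#' @param still_sd_g per-axis SD threshold defining stillness (g).
#' @param win_s still-window length in seconds.
#' @param coverage_min_g minimum per-axis spread of still-window means
#'   required for a well-posed fit (g).
#' @param max_iter,tol iteration controls.
#' @return a [calibration_model] with fit diagnostics.
#' @export
autocalibrate <- function(signal, still_sd_g = 0.013, win_s = 10,
                          coverage_min_g = 0.4, max_iter = 100L,
                          tol = 1e-10) {
  stopifnot(inherits(signal, "raw_signal"))
  fs <- signal$sample_rate_hz
  wn <- max(2L, round(win_s * fs))
  n <- length(signal$x)
  nwin <- floor(n / wn)
  identity_model <- function(msg, diag = list()) {
    warning("autocalibrate: ", msg, "; returning identity model",
            call. = FALSE)
    calibration_model(diagnostics = c(diag, list(fallback = msg)))
  }
  if (nwin < 1L) return(identity_model("signal too short for still windows"))
  grp <- rep(seq_len(nwin), each = wn)
  keep <- seq_len(nwin * wn)
  wsd <- function(v) tapply(v[keep], grp, stats::sd)
  wmean <- function(v) tapply(v[keep], grp, mean)
  still <- wsd(signal$x) < still_sd_g & wsd(signal$y) < still_sd_g &
    wsd(signal$z) < still_sd_g
  if (!any(still)) return(identity_model("no still windows detected"))
  P <- cbind(wmean(signal$x)[still], wmean(signal$y)[still],
             wmean(signal$z)[still])
  spread <- apply(P, 2, function(v) diff(range(v)))
  diag0 <- list(n_still_windows = sum(still))
  if (any(spread < coverage_min_g))
    return(identity_model(
      sprintf("insufficient sphere coverage (axis spreads %.3f/%.3f/%.3f g)",
              spread[1], spread[2], spread[3]), diag0))
  gain <- c(1, 1, 1); offset <- c(0, 0, 0)
  err_start <- mean(abs(sqrt(rowSums(P ^ 2)) - 1))
  prev_err <- Inf
  for (it in seq_len(max_iter)) {
    C <- sweep(sweep(P, 2, gain, "*"), 2, offset, "+")
    nr <- sqrt(rowSums(C ^ 2))
    target <- C / nr
    for (j in 1:3) {
      cf <- stats::lm.fit(cbind(1, P[, j]), target[, j])$coefficients
      offset[j] <- cf[1]; gain[j] <- cf[2]
    }
    err <- mean(abs(nr - 1))
    if (abs(prev_err - err) < tol) break
    prev_err <- err
  }
  C <- sweep(sweep(P, 2, gain, "*"), 2, offset, "+")
  err_end <- mean(abs(sqrt(rowSums(C ^ 2)) - 1))
  if (!is.finite(err_end) || err_end > err_start)
    return(identity_model("calibration fit did not reduce sphere residual",
                          diag0))
  calibration_model(gain, offset,
                    diagnostics = c(diag0, list(err_start = err_start,
                                                err_end = err_end,
                                                iterations = it)))
}

## --- MIMS -------------------------------------------------------------

## Replace runs clipped at the dynamic range by a local quadratic fitted
## through neighboring samples, capped at cap_factor * range.
extrapolate_clipped <- function(v, t, range_g, tol = 0.05, m = 5L,
                                cap_factor = 1.5) {
  clipped <- abs(v) >= range_g - tol
  if (!any(clipped)) return(v)
  r <- rle(clipped)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(v)
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    lo <- starts[i]; hi <- ends[i]
    left <- max(1L, lo - m):(lo - 1L)
    right <- (hi + 1L):min(n, hi + m)
    left <- left[left >= 1L & left < lo]
    right <- right[right <= n & right > hi]
    nb <- c(left, right)
    if (length(nb) < 3L) next  # not enough support at the signal edge
    tt <- t[nb] - t[lo]
    cf <- tryCatch(stats::lm.fit(cbind(1, tt, tt ^ 2), v[nb])$coefficients,
                   error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    tr <- t[lo:hi] - t[lo]
    pred <- cf[1] + cf[2] * tr + cf[3] * tr ^ 2
    cap <- cap_factor * range_g
    v[lo:hi] <- pmin(pmax(pred, -cap), cap)
  }
  v
}

#' Compute minute-level MIMS from a raw signal
#'
#' Pipeline: (1) linear interpolation of each axis to `resample_hz`;
#' (2) extrapolation of runs clipped at the dynamic range; (3) zero-phase
#' Butterworth band-pass (`band_low_hz`-`band_high_hz`); (4) rectification;
#' (5) trapezoidal integration per axis over each calendar minute (g.s);
#' (6) per-axis values below `truncation_threshold` set to 0; (7) sum of
#' the three axes. Minutes containing a raw-data gap longer than 1 s, or
#' covering less than half the expected samples, are returned as `NA`.
#'
#' @param signal a [raw_signal].
#' @param params a [measure_params] list (its `$mims` element is used).
#' @return data frame with `time` (minute start) and `mims`.
#' @export
compute_mims <- function(signal, params = measure_params()) {
  stopifnot(inherits(signal, "raw_signal"))
  p <- params$mims
  t <- signal$time
  fs_out <- p$resample_hz
  grid <- seq(t[1], t[length(t)], by = 1 / fs_out)
  ax_list <- list()
  for (ax in c("x", "y", "z")) {
    v <- stats::approx(t, signal[[ax]], xout = grid, rule = 2)$y
    if (identical(p$extrapolate, "quadratic"))
      v <- extrapolate_clipped(v, grid, signal$dynamic_range_g,
                               m = p$extrap_neighbors,
                               cap_factor = p$extrap_cap_factor)
    bf <- signal::butter(p$filter_order,
                         c(p$band_low_hz, p$band_high_hz) / (fs_out / 2),
                         type = "pass")
    ## odd-reflection padding so the slow high-pass startup transient
    ## decays inside the pad instead of contaminating the signal edges
    pad <- min(length(v) - 1L, as.integer(20 * fs_out))
    if (pad > 0L) {
      head_pad <- 2 * v[1] - v[(pad + 1L):2]
      tail_pad <- 2 * v[length(v)] - v[(length(v) - 1L):(length(v) - pad)]
      vf <- signal::filtfilt(bf, c(head_pad, v, tail_pad))
      v <- vf[(pad + 1L):(pad + length(v))]
    } else {
      v <- signal::filtfilt(bf, v)
    }
    ax_list[[ax]] <- abs(v)
  }
  minute <- floor(grid / 60) * 60
  mins <- sort(unique(minute))
  ## per-minute gap check on the original samples
  raw_minute <- floor(t / 60) * 60
  gap_ok <- vapply(mins, function(m) {
    tt <- t[raw_minute == m]
    if (length(tt) < 0.5 * 60 * signal$sample_rate_hz *
        min(1, (min(m + 60, t[length(t)]) - max(m, t[1])) / 60)) return(FALSE)
    length(tt) >= 2L && max(diff(tt)) <= 1
  }, logical(1))
  out <- numeric(length(mins))
  for (k in seq_along(mins)) {
    sel <- which(minute == mins[k])
    if (!gap_ok[k] || length(sel) < 2L) { out[k] <- NA_real_; next }
    tt <- grid[sel]
    total <- 0
    for (ax in c("x", "y", "z")) {
      v <- ax_list[[ax]][sel]
      auc <- sum(diff(tt) * (v[-1] + v[-length(v)]) / 2)
      if (auc < p$truncation_threshold) auc <- 0
      total <- total + auc
    }
    out[k] <- total
  }
  data.frame(time = as.POSIXct(mins, tz = "UTC", origin = "1970-01-01"),
             mims = out)
}

#' Summarize a raw signal into the four minute-level measures
#'
#' ENMO is computed on calibrated data (identity when `calibration` is
#' `NULL`); MIMS, MAD, and AI on uncalibrated data, mirroring the usual
#' tooling split. Minutes covering less than half their expected samples
#' are returned as `NA`.
#'
#' @param signal a [raw_signal].
#' @param params a [measure_params] list.
#' @param calibration optional [calibration_model] for ENMO.
#' @return data frame: `time`, `mims`, `enmo`, `mad`, `ai`.
#' @export
summarize_minutes <- function(signal, params = measure_params(),
                              calibration = NULL) {
  stopifnot(inherits(signal, "raw_signal"))
  fs <- signal$sample_rate_hz
  minute <- floor(signal$time / 60) * 60
  mins <- sort(unique(minute))
  enmo <- mad <- ai <- rep(NA_real_, length(mins))
  for (k in seq_along(mins)) {
    sel <- which(minute == mins[k])
    if (length(sel) < 0.5 * 60 * fs) next
    xs <- signal$x[sel]; ys <- signal$y[sel]; zs <- signal$z[sel]
    enmo[k] <- compute_enmo(xs, ys, zs, calibration)
    mad[k] <- compute_mad(xs, ys, zs)
    ai[k] <- compute_ai(xs, ys, zs, fs, params$ai$noise_variance,
                        params$ai$sub_epoch_s)
  }
  mm <- compute_mims(signal, params)
  out <- data.frame(time = as.POSIXct(mins, tz = "UTC", origin = "1970-01-01"),
                    enmo = enmo, mad = mad, ai = ai)
  out <- merge(out, mm, by = "time", all.x = TRUE)
  out[is.na(out$enmo), "mims"] <- NA_real_
  out[order(out$time), c("time", "mims", "enmo", "mad", "ai")]
}
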