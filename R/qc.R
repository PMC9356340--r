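## Raw-data quality control: three per-minute flags marking signal patterns
## unlikely to result from human movement (clipping sustained at the device
## range, stuck repeated samples, physically implausible spikes). The flags
## deliberately do not attempt nonwear detection, which is count-based and
## lives in the preprocessing step.

#' Quality-control parameters
#'
#' @param clip_run_s minimum run length (seconds) at the dynamic range for
#'   the sustained-clipping flag.
#' @param stuck_run_s minimum run length (seconds) of a bit-identical
#'   (x, y, z) triplet for the stuck-values flag.
#' @param spike_g absolute sample-to-sample change (g) on any axis above
#'   which the spike flag fires.
#' @param clip_tol_g tolerance below the dynamic range still counted as
#'   clipped.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(clip_run_s = 2, stuck_run_s = 1, spike_g = 11,
                      clip_tol_g = 0.05) {
  stopifnot(clip_run_s > 0, stuck_run_s > 0, spike_g > 0, clip_tol_g >= 0)
  structure(list(clip_run_s = clip_run_s, stuck_run_s = stuck_run_s,
                 spike_g = spike_g, clip_tol_g = clip_tol_g),
            class = "qc_params")
}

## samples marked TRUE where they belong to a TRUE-run of length >= min_len
runs_at_least <- function(flag, min_len) {
  r <- rle(flag)
  r$values <- r$values & r$lengths >= min_len
  inverse.rle(r)
}

#' Flag calendar minutes failing raw-data quality control
#'
#' A minute is flagged if any sample within it triggers the condition:
#' sustained clipping (any axis at the dynamic range for at least
#' `clip_run_s` s), stuck values (identical triplet repeated for at least
#' `stuck_run_s` s), or a spike (sample-to-sample jump above `spike_g` on
#' any axis). `qc_invalid` is the OR of the three flags.
#'
#' @param signal a [raw_signal] covering at least one full minute.
#' @param params a [qc_params] list.
#' @return data frame: `time` (minute start), `flag_clipped_sustained`,
#'   `flag_stuck_values`, `flag_spike`, `qc_invalid`.
#' @export
qc_flag_minutes <- function(signal, params = qc_params()) {
  stopifnot(inherits(signal, "raw_signal"))
  fs <- signal$sample_rate_hz
  n <- length(signal$x)
  if (n < 60 * fs) stop("signal shorter than one minute", call. = FALSE)

  clip_n <- max(1L, ceiling(params$clip_run_s * fs))
  stuck_n <- max(1L, ceiling(params$stuck_run_s * fs))
  thr <- signal$dynamic_range_g - params$clip_tol_g

  clip_samp <- rep(FALSE, n)
  for (ax in c("x", "y", "z"))
    clip_samp <- clip_samp | runs_at_least(abs(signal[[ax]]) >= thr, clip_n)

  same_prev <- c(FALSE, diff(signal$x) == 0 & diff(signal$y) == 0 &
                   diff(signal$z) == 0)
  ## a run of k identical consecutive "same as previous" marks covers k+1 samples
  r <- rle(same_prev)
  stuck_samp <- rep(FALSE, n)
  pos <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] + 1L >= stuck_n) {
      from <- pos[i] - 1L   # include the first sample of the repeated triplet
      stuck_samp[max(from, 1L):(pos[i] + r$lengths[i] - 1L)] <- TRUE
    }
  }

  spike_samp <- rep(FALSE, n)
  jump <- abs(diff(signal$x)) > params$spike_g |
    abs(diff(signal$y)) > params$spike_g |
    abs(diff(signal$z)) > params$spike_g
  if (any(jump)) {
    idx <- which(jump)
    spike_samp[idx] <- TRUE
    spike_samp[idx + 1L] <- TRUE
  }

  minute <- floor(signal$time / 60) * 60
  agg <- function(f) as.logical(tapply(f, minute, any))
  mins <- sort(unique(minute))
  out <- data.frame(
    time = as.POSIXct(mins, tz = "UTC", origin = "1970-01-01"),
    flag_clipped_sustained = agg(clip_samp),
    flag_stuck_values = agg(stuck_samp),
    flag_spike = agg(spike_samp))
  out$qc_invalid <- out$flag_clipped_sustained | out$flag_stuck_values |
    out$flag_spike
  rownames(out) <- NULL
  out
}
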