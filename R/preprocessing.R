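## Minute-level preprocessing: count-based wear detection, valid-minute /
## valid-day / participant selection, and winsorization. A minute is valid
## iff it is wear and passed raw-data QC; a valid day has at most 10%
## (144) invalid minutes; participants need at least 3 valid days.

#' Preprocessing parameters
#'
#' @param nonwear_run_minutes zero-count run length defining nonwear
#'   (default 90 minutes).
#' @param nonwear_tolerance_minutes nonzero "artifactual" minutes allowed
#'   inside a nonwear run without breaking it (default 0: the literal rule).
#' @param max_invalid_per_day invalid minutes tolerated in a valid day
#'   (default 144 = 10% of 1440).
#' @param min_valid_days valid days required to retain a participant
#'   (default 3).
#' @param winsor_quantile upper quantile used as the winsorization cap
#'   (default 0.999).
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(nonwear_run_minutes = 90L,
                              nonwear_tolerance_minutes = 0L,
                              max_invalid_per_day = 144L,
                              min_valid_days = 3L,
                              winsor_quantile = 0.999) {
  stopifnot(nonwear_run_minutes > 0, nonwear_tolerance_minutes >= 0,
            max_invalid_per_day > 0, min_valid_days > 0,
            winsor_quantile > 0, winsor_quantile < 1)
  structure(list(nonwear_run_minutes = as.integer(nonwear_run_minutes),
                 nonwear_tolerance_minutes = as.integer(nonwear_tolerance_minutes),
                 max_invalid_per_day = as.integer(max_invalid_per_day),
                 min_valid_days = as.integer(min_valid_days),
                 winsor_quantile = winsor_quantile),
            class = "preprocess_params")
}

#' Detect nonwear minutes from activity counts
#'
#' A minute is nonwear iff it lies in a maximal run of consecutive
#' zero-count minutes of length at least `run_minutes`. Missing counts are
#' treated as zero for run detection (and reported via a message). With
#' `tolerance_minutes > 0`, up to that many isolated nonzero minutes inside
#' a zero run do not break it.
#'
#' @param ac per-minute activity counts on a complete minute grid.
#' @param run_minutes run-length threshold (default 90).
#' @param tolerance_minutes allowance for artifactual nonzero minutes.
#' @return logical vector, `TRUE` = wear.
#' @export
detect_nonwear <- function(ac, run_minutes = 90L, tolerance_minutes = 0L) {
  if (anyNA(ac)) {
    message("detect_nonwear: ", sum(is.na(ac)),
            " missing counts treated as 0 for run detection")
    ac[is.na(ac)] <- 0
  }
  zero <- ac == 0
  if (tolerance_minutes > 0L) {
    ## absorb isolated nonzero runs no longer than the tolerance when
    ## flanked by zeros on both sides
    r <- rle(zero)
    if (length(r$lengths) > 2L) {
      for (i in 2:(length(r$lengths) - 1L)) {
        if (!r$values[i] && r$lengths[i] <= tolerance_minutes &&
            r$values[i - 1L] && r$values[i + 1L])
          r$values[i] <- TRUE
      }
      zero <- inverse.rle(r)
    }
  }
  nonwear <- runs_at_least(zero, as.integer(run_minutes))
  !nonwear
}

#' Combine wear and QC flags into per-minute validity
#'
#' @param wear logical wear flags.
#' @param qc_invalid logical QC flags.
#' @return logical: `wear & !qc_invalid`, with `NA` flags treated as
#'   not-wear / invalid respectively.
#' @export
flag_valid <- function(wear, qc_invalid) {
  wear[is.na(wear)] <- FALSE
  qc_invalid[is.na(qc_invalid)] <- TRUE
  wear & !qc_invalid
}

#' Flag valid days (at most `max_invalid` invalid minutes per 1440)
#'
#' Days with fewer than 1440 slots are treated as having their absent
#' minutes invalid (reported via a message).
#'
#' @param time minute-start timestamps.
#' @param valid per-minute validity flags.
#' @param max_invalid invalid-minute bound (default 144).
#' @return data frame `date`, `n_minutes`, `n_invalid`, `day_valid`.
#' @export
flag_valid_days <- function(time, valid, max_invalid = 144L) {
  date <- as.Date(floor_minute(time), tz = "UTC")
  n_min <- tapply(valid, date, length)
  n_inv <- tapply(!valid, date, sum) + (1440L - n_min)
  if (any(n_min < 1440L))
    message("flag_valid_days: ", sum(n_min < 1440L),
            " partial day(s); absent minutes counted as invalid")
  data.frame(date = as.Date(names(n_min)),
             n_minutes = as.integer(n_min),
             n_invalid = as.integer(n_inv),
             day_valid = as.integer(n_inv) <= max_invalid,
             row.names = NULL)
}

#' Retain participants with enough valid days, dropping invalid days
#'
#' @param cohort minute-level data frame with `participant_id`, `time`,
#'   `valid` columns.
#' @param min_valid_days retention threshold (default 3).
#' @param max_invalid invalid-minute bound per day (default 144).
#' @return list: `data` (retained cohort, valid days only), `day_report`
#'   (per participant-day validity), `retained_ids`.
#' @export
select_participants <- function(cohort, min_valid_days = 3L,
                                max_invalid = 144L) {
  ids <- unique(cohort$participant_id)
  reports <- lapply(ids, function(id) {
    d <- cohort[cohort$participant_id == id, ]
    rep <- flag_valid_days(d$time, d$valid, max_invalid)
    rep$participant_id <- id
    rep
  })
  day_report <- do.call(rbind, reports)
  n_valid <- tapply(day_report$day_valid, day_report$participant_id, sum)
  retained <- names(n_valid)[n_valid >= min_valid_days]
  keep_days <- day_report[day_report$day_valid &
                            day_report$participant_id %in% retained, ]
  key <- paste(cohort$participant_id,
               as.Date(floor_minute(cohort$time), tz = "UTC"))
  data_out <- cohort[key %in% paste(keep_days$participant_id, keep_days$date), ]
  list(data = data_out,
       day_report = day_report[, c("participant_id", "date", "n_minutes",
                                   "n_invalid", "day_valid")],
       retained_ids = retained)
}

#' Winsorize a measure at an upper empirical quantile
#'
#' The cap is the pooled empirical `q`-quantile, taken as the inverse
#' empirical CDF (type-1) order statistic so that winsorization is exactly
#' idempotent; values above the cap are replaced by it, values at or below
#' it and missing values are untouched.
#'
#' @param values numeric vector (pooled across all retained minutes of one
#'   measure).
#' @param q upper quantile (default 0.999).
#' @return winsorized vector with attribute `cap`.
#' @export
winsorize <- function(values, q = 0.999) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0L) stop("winsorize: all values missing", call. = FALSE)
  cap <- as.numeric(stats::quantile(obs, q, type = 1, names = FALSE))
  out <- values
  out[!is.na(out) & out > cap] <- cap
  attr(out, "cap") <- cap
  out
}
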