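## Evaluation statistics: participant-specific Pearson correlations and
## their regression on demographics; percentage errors of mapped daily
## total activity counts (MPE/MAPE/MdPE/MdAPE); cut-off classification
## accuracy/sensitivity/specificity; smoothed 24-hour median curves by
## age group and their curve-level MAPE.

#' Participant-specific Pearson correlations between AC and a measure
#'
#' Computed over each participant's valid minutes only.
#'
#' @param cohort minute-level data frame with `participant_id`, `ac`,
#'   `valid`, and the measure column.
#' @param measure measure column name.
#' @param metadata optional data frame (`participant_id`, `age_years`,
#'   `sex`, `bmi_kg_m2`) merged onto the result.
#' @return data frame `participant_id`, `r`, plus covariates if supplied.
#' @export
participant_correlations <- function(cohort, measure, metadata = NULL) {
  ids <- unique(cohort$participant_id)
  r <- vapply(ids, function(id) {
    d <- cohort[cohort$participant_id == id & cohort$valid, ]
    ok <- is.finite(d$ac) & is.finite(d[[measure]])
    if (sum(ok) < 2L || stats::sd(d$ac[ok]) == 0 ||
        stats::sd(d[[measure]][ok]) == 0) {
      message("participant_correlations: zero-variance or short series for ",
              id, "; r set to NA")
      return(NA_real_)
    }
    stats::cor(d$ac[ok], d[[measure]][ok])
  }, numeric(1))
  out <- data.frame(participant_id = ids, r = r, row.names = NULL)
  if (!is.null(metadata))
    out <- merge(out, metadata, by = "participant_id", sort = FALSE)
  out
}

#' Regress participant-specific correlations on demographics
#'
#' `adjusted = FALSE` fits the intercept-only model (cohort mean r and its
#' SE); `adjusted = TRUE` adjusts for age, BMI, and sex (female as the
#' reference level).
#'
#' @param records output of [participant_correlations] with covariates.
#' @param adjusted include age, BMI, sex covariates.
#' @param alpha significance level for the `significant` flag (default .05).
#' @return coefficient table: `term`, `estimate`, `se`, `p_value`,
#'   `significant`.
#' @export
correlation_regression <- function(records, adjusted = FALSE, alpha = 0.05) {
  records <- records[is.finite(records$r), ]
  if (nrow(records) < 10L)
    stop("correlation_regression: need at least 10 participants",
         call. = FALSE)
  if (adjusted) {
    stopifnot(all(c("age_years", "bmi_kg_m2", "sex") %in% names(records)))
    records$sex <- stats::relevel(factor(records$sex), ref = "female")
    fml <- r ~ age_years + bmi_kg_m2 + sex
  } else fml <- r ~ 1
  fit <- stats::lm(fml, data = records)
  if (adjusted && any(is.na(stats::coef(fit))))
    stop("correlation_regression: collinear covariates", call. = FALSE)
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             p_value = sm[, 4], significant = sm[, 4] < alpha,
             row.names = NULL)
}

pct_err_stats <- function(e) {
  c(mpe = mean(e), mape = mean(abs(e)),
    mdpe = stats::median(e), mdape = stats::median(abs(e)))
}

#' Percentage errors of mapped daily total activity counts
#'
#' For each participant-day, the observed total count T is compared with
#' the total of counts estimated by inverting the harmonization mapping of
#' the measure; the daily percentage error is 100 (T_hat - T) / T. Daily
#' errors are averaged within participant (MPE, MAPE, MdPE, MdAPE) and
#' aggregated across participants as mean (SD). Days with T = 0 are
#' excluded.
#'
#' @param cohort gap-free (imputed) minute-level data frame.
#' @param model a [harmonization_model] for the measure.
#' @param measure measure column name (defaults to the model's).
#' @return list: `per_participant` data frame and `cohort` mean/SD summary.
#' @export
total_ac_errors <- function(cohort, model, measure = model$measure_name) {
  ac_hat <- as.numeric(invert_to_ac(model, cohort[[measure]]))
  date <- as.Date(floor_minute(cohort$time), tz = "UTC")
  key <- paste(cohort$participant_id, date)
  T_obs <- tapply(cohort$ac, key, sum)
  T_hat <- tapply(ac_hat, key, sum)
  pid <- tapply(cohort$participant_id, key, `[`, 1L)
  zero <- T_obs == 0 | is.na(T_obs) | is.na(T_hat)
  if (any(zero))
    message("total_ac_errors: ", sum(zero), " day(s) with zero/NA total excluded")
  e <- 100 * (T_hat[!zero] - T_obs[!zero]) / T_obs[!zero]
  pp <- do.call(rbind, lapply(split(e, pid[!zero]), pct_err_stats))
  per_participant <- data.frame(participant_id = rownames(pp), pp,
                                row.names = NULL)
  cohort_summary <- data.frame(
    statistic = colnames(pp),
    mean = apply(pp, 2, mean),
    sd = apply(pp, 2, stats::sd),
    row.names = NULL)
  list(per_participant = per_participant, cohort = cohort_summary)
}

#' Cut-off classification metrics for mapped counts
#'
#' Per participant, minutes are classified as above/below the count
#' cut-off using the observed count (truth) and the mapped count
#' (prediction), both with strict inequality; accuracy, sensitivity, and
#' specificity are aggregated across participants as mean (SD).
#'
#' @param cohort minute-level data frame with `ac`, `valid`, the measure.
#' @param model a [harmonization_model].
#' @param ac_cutoff count cut-off (e.g. 1853).
#' @param measure measure column name.
#' @return list: `per_participant` and `cohort` mean/SD summary.
#' @export
cutoff_classification <- function(cohort, model, ac_cutoff,
                                  measure = model$measure_name) {
  d <- cohort[cohort$valid & is.finite(cohort$ac) &
                is.finite(cohort[[measure]]), ]
  ac_hat <- as.numeric(invert_to_ac(model, d[[measure]]))
  truth <- d$ac > ac_cutoff
  pred <- ac_hat > ac_cutoff
  per <- lapply(split(seq_len(nrow(d)), d$participant_id), function(ii) {
    tp <- sum(truth[ii] & pred[ii]); tn <- sum(!truth[ii] & !pred[ii])
    fp <- sum(!truth[ii] & pred[ii]); fn <- sum(truth[ii] & !pred[ii])
    sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    if (tp + fn == 0)
      message("cutoff_classification: no positive minutes for a participant; sensitivity NA")
    c(accuracy = (tp + tn) / length(ii), sensitivity = sens,
      specificity = spec)
  })
  pp <- do.call(rbind, per)
  per_participant <- data.frame(participant_id = rownames(pp), pp,
                                row.names = NULL)
  cohort_summary <- data.frame(
    statistic = colnames(pp),
    mean = apply(pp, 2, mean, na.rm = TRUE),
    sd = apply(pp, 2, stats::sd, na.rm = TRUE),
    row.names = NULL)
  list(per_participant = per_participant, cohort = cohort_summary,
       ac_cutoff = ac_cutoff)
}

#' Smoothed 24-hour median activity-count curves by age group
#'
#' Per age group and minute of day, the median over all participant-days
#' of the observed count and of the mapped count; each 1440-point median
#' curve is smoothed by a penalized cubic spline (GCV). The curve-level
#' MAPE is 100 * sum(|mapped - observed|) / sum(observed), pooled over all
#' minutes and groups.
#'
#' @param cohort gap-free minute-level data frame with `ac` and the
#'   measure column.
#' @param model a [harmonization_model].
#' @param metadata participant metadata with `age_years`.
#' @param age_breaks age-group boundaries; defaults to <60, 60-67, 68-74,
#'   >=75.
#' @param measure measure column name.
#' @param smooth smooth the median curves (default TRUE).
#' @return list: `curves` (long data frame: group, minute, ac_median,
#'   mapped_median, smoothed versions) and `curve_mape`.
#' @export
daily_median_curves <- function(cohort, model, metadata,
                                age_breaks = c(-Inf, 60, 68, 75, Inf),
                                measure = model$measure_name,
                                smooth = TRUE) {
  md <- metadata[, c("participant_id", "age_years")]
  md$age_group <- cut(md$age_years, breaks = age_breaks, right = FALSE)
  d <- merge(cohort, md, by = "participant_id", sort = FALSE)
  d$ac_hat <- as.numeric(invert_to_ac(model, d[[measure]]))
  d$mod <- minute_of_day_index(d$time)
  curves <- list()
  for (g in levels(droplevels(d$age_group))) {
    dg <- d[!is.na(d$age_group) & d$age_group == g, ]
    if (nrow(dg) == 0L) { message("daily_median_curves: empty group ", g); next }
    med_ac <- tapply(dg$ac, dg$mod, stats::median)
    med_hat <- tapply(dg$ac_hat, dg$mod, stats::median)
    mod <- as.integer(names(med_ac))
    cv <- data.frame(age_group = g, minute = mod,
                     ac_median = as.numeric(med_ac),
                     mapped_median = as.numeric(med_hat))
    if (smooth && length(mod) >= 10L) {
      cv$ac_smooth <- predict(fit_pspline(mod, cv$ac_median), mod)
      cv$mapped_smooth <- predict(fit_pspline(mod, cv$mapped_median), mod)
    } else {
      cv$ac_smooth <- cv$ac_median
      cv$mapped_smooth <- cv$mapped_median
    }
    curves[[g]] <- cv
  }
  if (length(curves) == 0L)
    stop("daily_median_curves: no nonempty age groups", call. = FALSE)
  curves <- do.call(rbind, curves)
  rownames(curves) <- NULL
  curve_mape <- 100 * sum(abs(curves$mapped_smooth - curves$ac_smooth)) /
    sum(curves$ac_smooth)
  list(curves = curves, curve_mape = curve_mape)
}
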