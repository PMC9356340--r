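## End-to-end pipeline: simulate (or read) a minute-level cohort, apply
## wear/validity preprocessing, winsorize, impute, fit harmonization
## mappings, translate cut-offs, and produce evaluation reports. A fully
## resolved copy of the configuration and a stage log with row counts are
## written next to every output.

#' Default pipeline configuration
#'
#' @return nested named list of every pipeline parameter. Unknown keys in
#'   a user configuration are rejected by [run_pipeline].
#' @export
default_config <- function() {
  list(
    seed = 42L,
    out_dir = "accelharm-output",
    input = list(minutes_csv = NULL, metadata_csv = NULL),
    simulate = list(enabled = TRUE, n_participants = 30L,
                    days_per_participant = 7L),
    preprocess = list(nonwear_run_minutes = 90L,
                      nonwear_tolerance_minutes = 0L,
                      max_invalid_per_day = 144L, min_valid_days = 3L,
                      winsor_quantile = 0.999),
    impute = list(k_max = 10L, pve = 0.95, nbasis = 30L),
    harmonize = list(nbasis = 30L, grid_size = 2000L, max_n = 50000L),
    evaluate = list(cutoffs = c(1853, 2860, 3940),
                    age_breaks = c(-Inf, 60, 68, 75, Inf)),
    measures = c("mims", "enmo", "mad", "ai"))
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown configuration key: ", path, extra[1], call. = FALSE)
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]]))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "$"))
  invisible(TRUE)
}

#' Validate and resolve a pipeline configuration
#'
#' Merges user settings over [default_config], rejecting unknown keys and
#' out-of-range values before any computation.
#'
#' @param config partial configuration list (or path to a YAML file).
#' @return fully resolved configuration list.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ref <- default_config()
  check_config_keys(config, ref)
  cfg <- utils::modifyList(ref, config)
  ## range validation delegated to the parameter constructors
  do.call(preprocess_params, cfg$preprocess)
  stopifnot(cfg$impute$pve > 0, cfg$impute$pve <= 1,
            cfg$harmonize$nbasis >= 4, all(cfg$evaluate$cutoffs > 0))
  cfg
}

log_stage <- function(log, stage, rows_in, rows_out, note = "") {
  rbind(log, data.frame(stage = stage, rows_in = rows_in,
                        rows_out = rows_out,
                        dropped = rows_in - rows_out, note = note))
}

#' Run the full minute-level harmonization pipeline
#'
#' Stages: simulate or read the minute-level cohort; wear detection and
#' validity flagging; valid-day participant selection; winsorization;
#' FPCA imputation; harmonization fitting per measure; cut-off
#' translation; evaluation (total-count percentage errors, cut-off
#' classification, smoothed median curves). All artifacts are written to
#' `out_dir`: minute CSVs, model JSONs, report CSVs, the resolved
#' configuration, and a stage log.
#'
#' @param config configuration list or YAML path; see [default_config].
#' @return invisibly, a list with the cohort, models, reports, and log.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- resolve_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- data.frame(stage = character(), rows_in = integer(),
                    rows_out = integer(), dropped = integer(),
                    note = character())

  ## --- input -----------------------------------------------------------
  if (!is.null(cfg$input$minutes_csv)) {
    data <- read_minute_summary(cfg$input$minutes_csv)
    metadata <- read_metadata_csv(cfg$input$metadata_csv)
    truth <- NULL
  } else if (isTRUE(cfg$simulate$enabled)) {
    prof <- sim_profile(seed = cfg$seed,
                        n_participants = cfg$simulate$n_participants,
                        days_per_participant = cfg$simulate$days_per_participant)
    sim <- generate_minute_cohort(prof)
    data <- sim$data; metadata <- sim$metadata; truth <- sim$truth
  } else stop("no input: supply input$minutes_csv or enable simulate",
              call. = FALSE)
  log <- log_stage(log, "input", nrow(data), nrow(data))

  ## --- wear / validity -------------------------------------------------
  n0 <- nrow(data)
  wear <- unlist(lapply(split(data$ac, data$participant_id)[
    unique(data$participant_id)], detect_nonwear,
    run_minutes = cfg$preprocess$nonwear_run_minutes,
    tolerance_minutes = cfg$preprocess$nonwear_tolerance_minutes),
    use.names = FALSE)
  data$wear <- wear
  data$valid <- flag_valid(data$wear, data$qc_invalid)
  log <- log_stage(log, "wear_validity", n0, sum(data$valid),
                   "rows_out = valid minutes")

  ## --- valid-day / participant selection -------------------------------
  sel <- select_participants(data, cfg$preprocess$min_valid_days,
                             cfg$preprocess$max_invalid_per_day)
  log <- log_stage(log, "valid_days", n0, nrow(sel$data),
                   sprintf("%d of %d participants retained",
                           length(sel$retained_ids),
                           length(unique(data$participant_id))))
  data <- sel$data
  data.table::fwrite(sel$day_report, file.path(cfg$out_dir, "day_report.csv"))

  ## --- winsorization ---------------------------------------------------
  caps <- list()
  for (ms in c("ac", cfg$measures)) {
    w <- winsorize(data[[ms]], cfg$preprocess$winsor_quantile)
    caps[[ms]] <- attr(w, "cap")
    data[[ms]] <- as.numeric(w)
  }
  log <- log_stage(log, "winsorize", nrow(data), nrow(data),
                   paste0("caps: ", paste(sprintf("%s=%.4g", names(caps),
                                                  unlist(caps)),
                                          collapse = ", ")))

  ## --- imputation ------------------------------------------------------
  imputed <- impute_invalid(data, measures = c("ac", cfg$measures),
                            k_max = cfg$impute$k_max, pve = cfg$impute$pve,
                            nbasis = cfg$impute$nbasis)
  log <- log_stage(log, "impute", nrow(data), nrow(imputed),
                   sprintf("%d invalid minutes imputed", sum(!data$valid)))
  write_minute_summary(imputed, file.path(cfg$out_dir, "minutes_imputed.csv"))

  ## --- harmonization ---------------------------------------------------
  models <- list()
  cutoff_rows <- list()
  for (ms in cfg$measures) {
    sub <- data[data$valid, ]
    models[[ms]] <- fit_mapping(sub$ac, sub[[ms]], measure_name = ms,
                                nbasis = cfg$harmonize$nbasis,
                                grid_size = cfg$harmonize$grid_size,
                                max_n = cfg$harmonize$max_n,
                                subsample_seed = cfg$seed)
    write_harmonization_json(models[[ms]],
                             file.path(cfg$out_dir,
                                       paste0("model_", ms, ".json")))
    cuts <- cfg$evaluate$cutoffs
    cuts <- cuts[cuts >= models[[ms]]$ac_range[1] &
                   cuts <= models[[ms]]$ac_range[2]]
    if (length(cuts))
      cutoff_rows[[ms]] <- data.frame(measure = ms, ac_cutoff = cuts,
                                      measure_cutoff = translate_cutoff(models[[ms]], cuts))
  }
  cutoff_table <- do.call(rbind, cutoff_rows)
  data.table::fwrite(cutoff_table, file.path(cfg$out_dir, "cutoff_table.csv"))
  log <- log_stage(log, "harmonize", nrow(data[data$valid, ]),
                   nrow(data[data$valid, ]),
                   paste(length(models), "mappings fitted"))

  ## --- evaluation ------------------------------------------------------
  err_rows <- cls_rows <- curve_rows <- corr_rows <- list()
  curve_mapes <- list()
  for (ms in cfg$measures) {
    recs <- participant_correlations(data, ms, metadata)
    rr <- recs$r[is.finite(recs$r)]
    if (length(rr) >= 10L) {
      reg <- correlation_regression(recs)
      corr_rows[[ms]] <- data.frame(measure = ms, mean_r = reg$estimate[1],
                                    se = reg$se[1])
    } else {
      ## too few participants for the regression summary: report the
      ## sample mean and its standard error directly
      corr_rows[[ms]] <- data.frame(measure = ms, mean_r = mean(rr),
                                    se = stats::sd(rr) / sqrt(length(rr)))
    }
    err <- total_ac_errors(imputed, models[[ms]], ms)
    err$cohort$measure <- ms
    err_rows[[ms]] <- err$cohort
    for (cc in cfg$evaluate$cutoffs) {
      if (cc < models[[ms]]$ac_range[1] || cc > models[[ms]]$ac_range[2]) next
      cl <- cutoff_classification(data, models[[ms]], cc, ms)
      cl$cohort$measure <- ms; cl$cohort$ac_cutoff <- cc
      cls_rows[[paste(ms, cc)]] <- cl$cohort
    }
    cur <- daily_median_curves(imputed, models[[ms]], metadata,
                               age_breaks = cfg$evaluate$age_breaks,
                               measure = ms)
    cur$curves$measure <- ms
    curve_rows[[ms]] <- cur$curves
    curve_mapes[[ms]] <- data.frame(measure = ms,
                                    curve_mape = cur$curve_mape)
  }
  reports <- list(correlations = do.call(rbind, corr_rows),
                  errors = do.call(rbind, err_rows),
                  classification = do.call(rbind, cls_rows),
                  curves = do.call(rbind, curve_rows),
                  curve_mape = do.call(rbind, curve_mapes),
                  cutoff_table = cutoff_table)
  for (nm in c("correlations", "errors", "classification", "curve_mape"))
    data.table::fwrite(reports[[nm]],
                       file.path(cfg$out_dir, paste0(nm, ".csv")))
  data.table::fwrite(reports$curves, file.path(cfg$out_dir, "curves.csv"))
  log <- log_stage(log, "evaluate", nrow(imputed), nrow(imputed))

  ## --- provenance ------------------------------------------------------
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config_resolved.yaml"))
  data.table::fwrite(log, file.path(cfg$out_dir, "stage_log.csv"))
  jsonlite::write_json(list(stages = log, caps = caps),
                       file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(config = cfg, data = data, imputed = imputed,
                 metadata = metadata, truth = truth, models = models,
                 reports = reports, log = log))
}
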