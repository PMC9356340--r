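## CSV dialects for raw accelerometry, minute-level summaries, and metadata.
## All timestamps are treated as local clock time on a timezone-naive clock
## (internally UTC, never shifted): the analysis day is the calendar day
## 12:00 AM - 11:59 PM.

MINUTE_COLUMNS <- c("participant_id", "time", "ac", "mims", "enmo", "mad",
                    "ai", "qc_invalid", "wear", "valid")

#' Construct a raw tri-axial acceleration signal
#'
#' @param time `POSIXct` (or numeric seconds) sample timestamps.
#' @param x,y,z acceleration per axis, in g.
#' @param sample_rate_hz nominal sampling rate (Hz).
#' @param dynamic_range_g device dynamic range (g); samples clip at +/- this.
#' @return object of class `raw_signal`.
#' @export
raw_signal <- function(time, x, y, z, sample_rate_hz = 80,
                       dynamic_range_g = 8) {
  n <- length(x)
  if (n < 1L || length(y) != n || length(z) != n || length(time) != n)
    stop("x, y, z, time must be equal-length, nonempty", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("non-finite acceleration values", call. = FALSE)
  if (sample_rate_hz <= 0 || dynamic_range_g <= 0)
    stop("sample_rate_hz and dynamic_range_g must be positive", call. = FALSE)
  time <- as.POSIXct(time, tz = "UTC", origin = "1970-01-01")
  structure(list(time = as.numeric(time), start_time = time[1],
                 x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 sample_rate_hz = sample_rate_hz,
                 dynamic_range_g = dynamic_range_g),
            class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("raw_signal: %d samples at %g Hz (%.1f min), range +/- %g g\n",
              length(x$x), x$sample_rate_hz,
              length(x$x) / x$sample_rate_hz / 60, x$dynamic_range_g))
  invisible(x)
}

parse_clock <- function(s) {
  t <- as.POSIXct(s, tz = "UTC",
                  tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y/%m/%d %H:%M:%OS",
                                 "%m/%d/%Y %H:%M:%OS"))
  t
}

## Locate the header row of a raw CSV: vendor exports carry a ~10-line
## preamble; the header is the first line starting with a timestamp-like
## column name.
sniff_header_line <- function(path) {
  head_lines <- readLines(path, n = 25L, warn = FALSE)
  hit <- grep("^\"?(timestamp|time|datetime|header_timestamp)\"?\\s*,",
              head_lines, ignore.case = TRUE)
  if (length(hit) == 0L)
    stop("no header line naming a timestamp column found in ", path,
         call. = FALSE)
  hit[1]
}

#' Read raw tri-axial accelerometry from CSV
#'
#' Accepts both a bare `timestamp,X,Y,Z` file and the vendor variant with a
#' preamble before the header (autodetected). Verifies the sampling rate
#' implied by the timestamps against `expected_hz`.
#'
#' @param path CSV file path.
#' @param expected_hz expected sampling rate; the median inter-sample gap
#'   must match within 1%.
#' @param dynamic_range_g device range recorded on the returned signal.
#' @return a [raw_signal].
#' @export
read_raw_csv <- function(path, expected_hz = 80, dynamic_range_g = 8) {
  hdr <- sniff_header_line(path)
  dt <- data.table::fread(path, skip = hdr - 1L, header = TRUE,
                          colClasses = list(character = 1L),
                          showProgress = FALSE)
  nms <- tolower(names(dt))
  ts_col <- which(nms %in% c("timestamp", "time", "datetime",
                             "header_timestamp"))[1]
  ax_col <- function(axis) {
    i <- which(nms == tolower(axis) |
                 grepl(paste0("accelerometer[ ._]?", tolower(axis), "$"), nms))
    if (length(i) == 0L)
      stop("missing axis column '", axis, "' in ", path, call. = FALSE)
    i[1]
  }
  xs <- ax_col("X"); ys <- ax_col("Y"); zs <- ax_col("Z")
  num <- function(col, label) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("unparseable %s value at data row %d of %s",
                   label, bad[1], path), call. = FALSE)
    v
  }
  x <- num(xs, "X"); y <- num(ys, "Y"); z <- num(zs, "Z")
  tm <- parse_clock(dt[[ts_col]])
  bad_t <- which(is.na(tm))
  if (length(bad_t))
    stop(sprintf("unparseable timestamp at data row %d of %s", bad_t[1], path),
         call. = FALSE)
  if (length(tm) > 1L) {
    gap <- stats::median(diff(as.numeric(tm)))
    if (abs(gap * expected_hz - 1) > 0.01)
      stop(sprintf(
        "sampling rate mismatch: median gap %.6fs implies %.2f Hz, expected %g Hz",
        gap, 1 / gap, expected_hz), call. = FALSE)
  }
  raw_signal(tm, x, y, z, sample_rate_hz = expected_hz,
             dynamic_range_g = dynamic_range_g)
}

#' Write a raw signal to CSV (timestamp,X,Y,Z; 6-decimal values)
#' @param signal a [raw_signal].
#' @param path output path.
#' @export
write_raw_csv <- function(signal, path) {
  stopifnot(inherits(signal, "raw_signal"))
  dt <- data.table::data.table(
    timestamp = format(as.POSIXct(signal$time, tz = "UTC",
                                  origin = "1970-01-01"),
                       "%Y-%m-%d %H:%M:%OS4"),
    X = sprintf("%.6f", signal$x),
    Y = sprintf("%.6f", signal$y),
    Z = sprintf("%.6f", signal$z))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

floor_minute <- function(t) {
  tn <- as.numeric(as.POSIXct(t, tz = "UTC", origin = "1970-01-01"))
  as.POSIXct(floor(tn / 60) * 60, tz = "UTC", origin = "1970-01-01")
}

#' Complete a minute series to full 1440-minute calendar days
#'
#' Inserts missing-valued rows so every covered calendar day has a slot for
#' each of its 1440 minutes. Observed values are never altered.
#'
#' @param df data frame with a `time` column of minute-start timestamps.
#' @return the completed data frame, ordered by time.
#' @export
complete_minute_grid <- function(df) {
  stopifnot("time" %in% names(df))
  t0 <- floor_minute(min(df$time))
  t1 <- floor_minute(max(df$time))
  day0 <- as.POSIXct(trunc(t0, "days"), tz = "UTC")
  day1 <- as.POSIXct(trunc(t1, "days"), tz = "UTC") + 86340
  grid <- data.frame(time = seq(day0, day1, by = 60))
  out <- merge(grid, df, by = "time", all.x = TRUE, sort = TRUE)
  out[order(out$time), , drop = FALSE]
}

#' Read a minute-level activity-count CSV
#'
#' One row per minute (`timestamp,count`-style header). Gaps in the minute
#' grid are filled with missing counts so every day has 1440 slots.
#'
#' @param path CSV file path.
#' @param participant_id id attached to the returned series.
#' @return data frame with columns `participant_id`, `time`, `ac`.
#' @export
read_minute_ac_csv <- function(path, participant_id = NA_character_) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L),
                          showProgress = FALSE)
  nms <- tolower(names(dt))
  ts_col <- which(nms %in% c("timestamp", "time", "datetime"))[1]
  ac_col <- which(nms %in% c("count", "counts", "ac", "activity_count",
                             "vectormagnitude", "axis1"))[1]
  if (is.na(ts_col) || is.na(ac_col))
    stop("minute CSV must name timestamp and count columns: ", path,
         call. = FALSE)
  tm <- parse_clock(dt[[ts_col]])
  if (anyNA(tm))
    stop("unparseable minute timestamp at row ", which(is.na(tm))[1],
         call. = FALSE)
  if (any(as.numeric(tm) %% 60 != 0))
    stop("minute timestamps must be aligned to :00 seconds", call. = FALSE)
  if (anyDuplicated(tm))
    stop("duplicate minute timestamp: ",
         format(tm[duplicated(tm)][1], "%Y-%m-%d %H:%M"), call. = FALSE)
  ac <- suppressWarnings(as.numeric(dt[[ac_col]]))
  if (any(ac < 0, na.rm = TRUE))
    stop("negative activity counts", call. = FALSE)
  out <- complete_minute_grid(data.frame(time = tm, ac = ac))
  out$participant_id <- participant_id
  out[, c("participant_id", "time", "ac")]
}

#' Write a minute-level summary CSV
#'
#' Stable column order: participant_id, time, ac, mims, enmo, mad, ai,
#' qc_invalid, wear, valid. Flags are serialized as 0/1 and missing values
#' as empty fields.
#'
#' @param series minute-level data frame (see [read_minute_summary]).
#' @param path output path.
#' @export
write_minute_summary <- function(series, path) {
  if (nrow(series) == 0L) {
    writeLines(paste(MINUTE_COLUMNS, collapse = ","), path)
    message("write_minute_summary: empty series, header-only file written")
    return(invisible(path))
  }
  missing_cols <- setdiff(MINUTE_COLUMNS, names(series))
  for (mc in missing_cols) series[[mc]] <- NA
  out <- data.table::as.data.table(series[, MINUTE_COLUMNS])
  out$time <- format(series$time, "%Y-%m-%d %H:%M:%S")
  for (fc in c("qc_invalid", "wear", "valid"))
    out[[fc]] <- as.integer(out[[fc]])
  data.table::fwrite(out, path, na = "", quote = FALSE)
  invisible(path)
}

#' Read back a minute-level summary CSV written by [write_minute_summary]
#' @param path CSV path.
#' @return minute-level data frame with logical flags.
#' @export
read_minute_summary <- function(path) {
  dt <- data.table::fread(path, header = TRUE, showProgress = FALSE,
                          colClasses = list(character = c(1L, 2L)))
  if (nrow(dt) == 0L) {
    out <- data.frame(participant_id = character(), time = as.POSIXct(character(), tz = "UTC"),
                      ac = numeric(), mims = numeric(), enmo = numeric(),
                      mad = numeric(), ai = numeric(), qc_invalid = logical(),
                      wear = logical(), valid = logical())
    return(out)
  }
  out <- as.data.frame(dt)
  out$time <- parse_clock(out$time)
  for (fc in c("qc_invalid", "wear", "valid"))
    out[[fc]] <- as.logical(as.integer(out[[fc]]))
  for (nc in c("ac", "mims", "enmo", "mad", "ai"))
    out[[nc]] <- as.numeric(out[[nc]])
  out[, MINUTE_COLUMNS]
}

#' Read a participant metadata CSV (id, age, sex, bmi)
#'
#' Sex is coded as a factor with levels `female`, `male` (female = reference).
#'
#' @param path CSV path.
#' @return data frame `participant_id`, `age_years`, `sex`, `bmi_kg_m2`.
#' @export
read_metadata_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, showProgress = FALSE)
  nms <- tolower(names(dt))
  pick <- function(cands, label) {
    i <- which(nms %in% cands)[1]
    if (is.na(i)) stop("metadata CSV missing ", label, " column", call. = FALSE)
    i
  }
  out <- data.frame(
    participant_id = as.character(dt[[pick(c("id", "participant_id"), "id")]]),
    age_years = as.numeric(dt[[pick(c("age", "age_years"), "age")]]),
    sex = factor(tolower(as.character(dt[[pick("sex", "sex")]])),
                 levels = c("female", "male")),
    bmi_kg_m2 = as.numeric(dt[[pick(c("bmi", "bmi_kg_m2"), "bmi")]]))
  out
}

#' Write a cohort in tidy long format keyed by (participant, minute, variable)
#' @param series minute-level data frame.
#' @param path output CSV path.
#' @export
write_tidy_long <- function(series, path) {
  dt <- data.table::as.data.table(series)
  dt$time <- format(series$time, "%Y-%m-%d %H:%M:%S")
  long <- data.table::melt(dt, id.vars = c("participant_id", "time"),
                           variable.name = "variable", value.name = "value")
  data.table::fwrite(long, path, na = "", quote = FALSE)
  invisible(path)
}
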