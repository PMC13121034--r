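#' Read a log table
#'
#' Reads a timestamped food-log table from CSV (RFC 4180, header row) or
#' JSONL (one object per line). Required columns: `participant_id`,
#' `log_time`, `raw_text`, `log_type`; `server_time` is optional. Rows with
#' an unparseable `log_time` or empty `raw_text` are skipped with a warning
#' naming the row numbers; a missing required column is an error. Timestamps
#' are truncated to minute resolution. Records are returned sorted by
#' `(participant_id, log_time)` with logical-day columns attached.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`; the default guesses from the file
#'   extension.
#' @return a tibble of log records with columns `participant_id`,
#'   `log_time`, `server_time`, `raw_text`, `log_type`, `logical_date`,
#'   `minute_of_day`.
#' @export
read_log_table <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  raw <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", check.names = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      data.frame(participant_id = character(), log_time = character(),
                 raw_text = character(), log_type = character())
    } else {
      jsonlite::stream_in(textConnection(lines), verbose = FALSE)
    }
  }
  raw <- tibble::as_tibble(raw)
  required <- c("participant_id", "log_time", "raw_text", "log_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("log table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"server_time" %in% names(raw)) raw$server_time <- NA_character_
  if (nrow(raw) == 0) return(empty_log_table())

  lt <- suppressWarnings(parse_minute_time(raw$log_time))
  st <- suppressWarnings(parse_minute_time(raw$server_time))
  bad <- which(is.na(lt) | is.na(raw$raw_text) | !nzchar(trimws(raw$raw_text)))
  if (length(bad) > 0) {
    warning(sprintf("skipped %d malformed row(s): %s", length(bad),
                    paste(utils::head(bad, 20), collapse = ", ")))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id[keep]),
    log_time = lt[keep],
    server_time = st[keep],
    raw_text = as.character(raw$raw_text[keep]),
    log_type = as.character(raw$log_type[keep])
  )
  out <- dplyr::bind_cols(out, to_logical_day(out$log_time))
  dplyr::arrange(out, .data$participant_id, .data$log_time)
}

empty_log_table <- function() {
  tibble::tibble(participant_id = character(), log_time = as.POSIXct(character(), tz = "UTC"),
                 server_time = as.POSIXct(character(), tz = "UTC"),
                 raw_text = character(), log_type = character(),
                 logical_date = as.Date(character()), minute_of_day = integer())
}

# Minute-truncating timestamp parser accepting "YYYY-mm-dd HH:MM[:SS]",
# ISO "T" separators, and date-only strings (midnight).
parse_minute_time <- function(x) {
  x <- as.character(x)
  x <- sub("T", " ", x, fixed = TRUE)
  t <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  t2 <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M")
  t[is.na(t)] <- t2[is.na(t)]
  t3 <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d")
  t[is.na(t) & grepl("^\\d{4}-\\d{2}-\\d{2}$", trimws(x))] <-
    t3[is.na(t) & grepl("^\\d{4}-\\d{2}-\\d{2}$", trimws(x))]
  trunc_minute(t)
}

trunc_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, tz = "UTC",
             origin = "1970-01-01")
}

#' Read a demographics table
#'
#' CSV keyed by `participant_id` with columns `age_years`, `sex`,
#' `work_schedule`. Unknown levels are mapped to `"unknown"` (work
#' schedule) or `"other_unknown"` (sex).
#'
#' @param path file path.
#' @return a tibble with one row per participant.
#' @export
read_demographics <- function(path) {
  raw <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  stopifnot(all(c("participant_id", "age_years", "sex", "work_schedule") %in% names(raw)))
  tibble::tibble(
    participant_id = as.character(raw$participant_id),
    age_years = as.integer(raw$age_years),
    sex = ifelse(raw$sex %in% c("male", "female"), as.character(raw$sex), "other_unknown"),
    work_schedule = ifelse(raw$work_schedule %in% WORK_SCHEDULES,
                           as.character(raw$work_schedule), "unknown")
  )
}

#' Recognised work-schedule levels
#' @export
WORK_SCHEDULES <- c("regular", "morning_shift", "evening_shift", "night_shift",
                    "rotating_shift", "flexible", "long_hours", "unknown")

#' Write participant metrics to disk
#'
#' Writes a metrics table as CSV or JSON. Minute-valued columns (names
#' ending `_minute` or `_min`) are additionally emitted as `"HH:MM"` clock
#' strings (`*_hhmm`) and decimal clock hours (`*_hours`) for the
#' positional metrics, so the file is readable without the 04:00 anchor in
#' mind. A read back with [read_metrics_table()] reproduces the numeric
#' values exactly.
#'
#' @param metrics a data frame of per-participant metrics.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path, format = c("csv", "json")) {
  format <- match.arg(format)
  out <- as.data.frame(metrics)
  pos_cols <- grep("_minute$", names(out), value = TRUE)
  for (cl in pos_cols) {
    out[[paste0(sub("_minute$", "", cl), "_hhmm")]] <- minute_to_hhmm(out[[cl]])
    out[[paste0(sub("_minute$", "", cl), "_hours")]] <- minute_to_hours(out[[cl]])
  }
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Read back a metrics table written by [write_metrics_table()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @return a tibble.
#' @export
read_metrics_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
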