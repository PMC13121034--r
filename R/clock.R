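#' Clock conventions: the 04:00-anchored logical day
#'
#' All timing statistics in this package operate on "day minutes": integer
#' minutes elapsed since 04:00 of the logical day the log belongs to. A
#' logical day runs from 04:00 on one calendar day to 03:59:59 the next,
#' so logs between midnight and 03:59 are assigned to the previous calendar
#' date. Anchoring at 04:00 (the trough of human activity) makes the time
#' domain linear: medians and percentiles of eating times near midnight are
#' well defined, and no statistic wraps across the day boundary.
#'
#' @name clock-conventions
#' @keywords internal
NULL

#' Minutes from 04:00 at which the logical day starts (as clock minutes).
#' @keywords internal
DAY_ANCHOR_MIN <- 240L

#' Minutes in a logical day.
#' @keywords internal
DAY_MINUTES <- 1440L

#' Assign timestamps to logical days
#'
#' Maps each minute-resolved timestamp to its logical date (the calendar
#' date whose 04:00 starts the logical day containing it) and its day
#' minute (minutes since that 04:00, in `[0, 1440)`). Seconds, if present,
#' are truncated.
#'
#' @param log_time a `POSIXct` vector (or anything coercible via
#'   [as.POSIXct()]); interpreted as local wall time, no timezone
#'   arithmetic is attempted.
#' @return a tibble with columns `logical_date` ([Date]) and
#'   `minute_of_day` (integer in `[0, 1440)`).
#' @examples
#' to_logical_day(as.POSIXct("2023-05-01 03:30", tz = "UTC"))
#' # logical_date 2023-04-30, minute_of_day 1410
#' @export
to_logical_day <- function(log_time) {
  log_time <- as.POSIXct(log_time, tz = "UTC")
  lt <- as.POSIXlt(log_time)
  clock_min <- lt$hour * 60L + lt$min
  before_anchor <- clock_min < DAY_ANCHOR_MIN
  logical_date <- as.Date(format(log_time, "%Y-%m-%d")) - ifelse(before_anchor, 1L, 0L)
  minute_of_day <- ifelse(before_anchor,
                          clock_min + DAY_MINUTES - DAY_ANCHOR_MIN,
                          clock_min - DAY_ANCHOR_MIN)
  tibble::tibble(logical_date = logical_date,
                 minute_of_day = as.integer(minute_of_day))
}

#' Invert the logical-day mapping
#'
#' @param logical_date a `Date` vector.
#' @param minute_of_day integer day minutes in `[0, 1440)`.
#' @return a `POSIXct` vector (UTC-encoded local wall time).
#' @export
from_logical_day <- function(logical_date, minute_of_day) {
  stopifnot(all(minute_of_day >= 0 & minute_of_day < DAY_MINUTES))
  as.POSIXct(as.Date(logical_date), tz = "UTC") +
    (as.numeric(minute_of_day) + DAY_ANCHOR_MIN) * 60
}

#' Render day minutes as clock time
#'
#' @param minute_of_day numeric day minutes (minutes since 04:00); values
#'   are wrapped into a 24 h clock for display.
#' @return character `"HH:MM"` clock times.
#' @export
minute_to_hhmm <- function(minute_of_day) {
  clock <- (round(minute_of_day) + DAY_ANCHOR_MIN) %% DAY_MINUTES
  sprintf("%02d:%02d", clock %/% 60, clock %% 60)
}

#' Day minutes as decimal clock hours
#'
#' @inheritParams minute_to_hhmm
#' @return numeric clock hours in `[0, 24)` (e.g. 13.5 for 13:30).
#' @export
minute_to_hours <- function(minute_of_day) {
  ((minute_of_day + DAY_ANCHOR_MIN) %% DAY_MINUTES) / 60
}

#' Parse "HH:MM" clock time into day minutes
#'
#' @param hhmm character clock times.
#' @return integer day minutes since 04:00.
#' @export
hhmm_to_minute <- function(hhmm) {
  parts <- strsplit(hhmm, ":", fixed = TRUE)
  clock <- vapply(parts, function(p) as.integer(p[1]) * 60L + as.integer(p[2]), integer(1))
  as.integer((clock - DAY_ANCHOR_MIN) %% DAY_MINUTES)
}
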