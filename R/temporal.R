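#' Count eating occasions in a sorted minute vector
#'
#' @param minutes sorted day minutes of one participant-day's caloric logs.
#' @param gap_min gap defining a new occasion (default 15): a log starts a
#'   new occasion iff it is `gap_min` or more minutes after the previous
#'   log.
#' @return integer occasion count.
#' @keywords internal
n_eating_events <- function(minutes, gap_min = 15) {
  if (length(minutes) == 0) return(0L)
  sum(c(TRUE, diff(minutes) >= gap_min))
}

#' Group one day's caloric logs into eating occasions
#'
#' Chain-merging: successive caloric logs less than `gap_min` minutes
#' apart belong to the same occasion; a gap of `gap_min` or more starts a
#' new one (logs at 09:45, 09:56 and 10:10 are one occasion; a log at
#' 10:26 starts another). Occasions partition the day's logs.
#'
#' @param minutes day minutes of one participant-day's caloric logs
#'   (any order; duplicates allowed).
#' @param gap_min merging gap (default 15).
#' @return tibble with one row per occasion: `event`, `start_minute`,
#'   `end_minute`, `n_logs`.
#' @export
group_eating_events <- function(minutes, gap_min = 15) {
  if (length(minutes) == 0) {
    return(tibble::tibble(event = integer(), start_minute = numeric(),
                          end_minute = numeric(), n_logs = integer()))
  }
  minutes <- sort(minutes)
  event <- cumsum(c(TRUE, diff(minutes) >= gap_min))
  out <- tibble::tibble(minute = minutes, event = event) |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(start_minute = min(.data$minute),
                     end_minute = max(.data$minute),
                     n_logs = dplyr::n(), .groups = "drop")
  tibble::as_tibble(out)
}

#' TF50: median caloric log time
#'
#' The day minute by which half of a participant's caloric (food or
#' beverage, excluding water) logs have occurred: the median log time over
#' the whole observation period. Even counts take the mean of the two
#' central order statistics.
#'
#' @param minutes day minutes of all the participant's caloric logs.
#' @return median day minute (numeric scalar).
#' @export
tf50 <- function(minutes) {
  if (length(minutes) == 0) stop("tf50 is undefined with no caloric logs")
  stats::median(minutes)
}

#' 95% eating window
#'
#' Pools all of a participant's caloric log times, removes the earliest
#' and latest 2.5%, and reports the remaining span: start = 2.5th
#' percentile, end = 97.5th percentile of the day-minute values. The
#' quantile is linear interpolation between order statistics by default
#' (`type = 7`); `method = "nearest"` uses the nearest-rank quantile
#' (`type = 1`), which changes windows by minutes at small n.
#'
#' @param minutes pooled caloric log day-minutes (length >= 2).
#' @param method `"linear"` or `"nearest"`.
#' @return named numeric: `start`, `end`, `duration` (minutes).
#' @export
p95_window <- function(minutes, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(minutes) < 2) stop("p95_window needs at least 2 caloric logs")
  qtype <- if (method == "linear") 7 else 1
  q <- stats::quantile(minutes, c(0.025, 0.975), type = qtype, names = FALSE)
  c(start = q[1], end = q[2], duration = q[2] - q[1])
}

#' Average eating window
#'
#' Mean over compliant days of the span between the day's first and last
#' caloric logs.
#'
#' @param day_spans numeric vector of daily first-to-last spans (minutes),
#'   one per qualifying (compliant) day.
#' @return mean span in minutes.
#' @export
avg_window <- function(day_spans) {
  if (length(day_spans) == 0) stop("avg_window is undefined with no compliant days")
  mean(day_spans)
}

#' Day-to-day first/last intake shift
#'
#' Eating-time irregularity: mean absolute difference, between successive
#' compliant days, of the time of a given intake event (the day's first or
#' last caloric log). "Successive" means successive compliant days by
#' default; `adjacent_only = TRUE` restricts to calendar-adjacent pairs.
#'
#' @param dates logical dates of the compliant days.
#' @param minutes day minute of the event on each of those days.
#' @param adjacent_only require consecutive calendar dates.
#' @return mean absolute shift in minutes (`NA` with fewer than 2 usable
#'   pairs).
#' @export
intake_shift <- function(dates, minutes, adjacent_only = FALSE) {
  if (length(dates) < 2) return(NA_real_)
  ord <- order(dates)
  dates <- dates[ord]; minutes <- minutes[ord]
  d <- abs(diff(minutes))
  if (adjacent_only) d <- d[diff(as.numeric(dates)) == 1]
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

#' Per-item TF50
#'
#' Median log time of one item over the logs of a filtered user set (e.g.
#' regular consumers who logged the item on >= 7 distinct days vs
#' occasional consumers with <= 2).
#'
#' @param item_minutes day minutes of the item's logs by the filtered
#'   users.
#' @return median day minute.
#' @export
item_tf50 <- function(item_minutes) {
  if (length(item_minutes) == 0) stop("item_tf50 undefined: no logs")
  stats::median(item_minutes)
}

#' Binned time-of-day distribution
#'
#' Histogram of day minutes over half-open bins `[b, b + bin_min)`
#' covering the 04:00-anchored 24 h day.
#'
#' @param minutes day minutes.
#' @param bin_min bin width in minutes; must divide 1440 (60 for hourly
#'   bins, 15 for the 96-bin profiles used in clustering).
#' @return tibble `bin_start`, `count`, `fraction` (fractions sum to 1
#'   when there is any data).
#' @export
binned_distribution <- function(minutes, bin_min = 60) {
  stopifnot(DAY_MINUTES %% bin_min == 0)
  starts <- seq(0L, DAY_MINUTES - bin_min, by = bin_min)
  idx <- pmin(floor(minutes / bin_min), length(starts) - 1L)
  counts <- tabulate(idx + 1L, nbins = length(starts))
  tibble::tibble(bin_start = starts, count = counts,
                 fraction = if (sum(counts) > 0) counts / sum(counts) else
                   rep(0, length(counts)))
}

#' Per-participant eating-pattern metrics
#'
#' Computes, for every eligible participant, the full set of timing
#' metrics from their caloric logs on compliant days: TF50, average eating
#' window, 95% eating window (start, end, duration), mean day-to-day
#' first- and last-intake shifts, logs and occasions per day, and the
#' compliant-day count. Only caloric logs on compliant days within the
#' first `horizon_days` logical days enter any metric.
#'
#' @param parsed_items parsed-item tibble (`participant_id`,
#'   `logical_date`, `minute_of_day`, `caloric`).
#' @param gap_min occasion gap (default 15).
#' @param quantile_method `"linear"` or `"nearest"` for the 95% window.
#' @param adjacent_only restrict shifts to calendar-adjacent compliant
#'   days.
#' @param min_days,horizon_days eligibility rule (defaults 10 of 14).
#' @return tibble with one row per eligible participant: `tf50_minute`,
#'   `avg_window_min`, `p95_start_minute`, `p95_end_minute`,
#'   `p95_window_min`, `first_shift_min`, `last_shift_min`, `logs_per_day`,
#'   `events_per_day`, `compliant_day_count`.
#' @export
participant_metrics <- function(parsed_items, gap_min = 15,
                                quantile_method = "linear",
                                adjacent_only = FALSE,
                                min_days = 10, horizon_days = 14) {
  days <- compliance_days(parsed_items, gap_min = gap_min)
  elig <- eligible_participants(days, min_days, horizon_days)
  ok <- elig$participant_id[elig$eligible]
  cdays <- dplyr::filter(days, .data$compliant, .data$participant_id %in% ok)
  cal <- parsed_items |>
    dplyr::filter(.data$caloric) |>
    dplyr::distinct(.data$participant_id, .data$logical_date, .data$minute_of_day) |>
    dplyr::semi_join(cdays, by = c("participant_id", "logical_date"))

  per_day <- cdays |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$logical_date, .by_group = TRUE) |>
    dplyr::summarise(
      avg_window_min = mean(.data$span_min),
      first_shift_min = intake_shift(.data$logical_date, .data$first_minute,
                                     adjacent_only),
      last_shift_min = intake_shift(.data$logical_date, .data$last_minute,
                                    adjacent_only),
      logs_per_day = mean(.data$n_caloric_logs),
      events_per_day = mean(.data$n_events),
      compliant_day_count = dplyr::n(),
      .groups = "drop")

  pooled <- cal |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      tf50_minute = tf50(.data$minute_of_day),
      p95_start_minute = p95_window(.data$minute_of_day, quantile_method)[["start"]],
      p95_end_minute = p95_window(.data$minute_of_day, quantile_method)[["end"]],
      .groups = "drop") |>
    dplyr::mutate(p95_window_min = .data$p95_end_minute - .data$p95_start_minute)

  tibble::as_tibble(dplyr::inner_join(pooled, per_day, by = "participant_id"))
}

#' Caloric pseudo-items from user-assigned log types
#'
#' For timing-only analyses (or generated cohorts) the user-assigned log
#' type already identifies caloric logs: food and beverage logs are
#' caloric, water/medication/selfcare are not. Returns a parsed-item-shaped
#' table with one row per log.
#'
#' @param logs a log table.
#' @return tibble with `participant_id`, `log_time`, `logical_date`,
#'   `minute_of_day`, `log_id`, `name` (NA), `item_type`, `caloric`.
#' @export
items_from_log_types <- function(logs) {
  tibble::tibble(
    participant_id = logs$participant_id,
    log_time = logs$log_time,
    logical_date = logs$logical_date,
    minute_of_day = logs$minute_of_day,
    log_id = seq_len(nrow(logs)),
    name = NA_character_,
    item_type = logs$log_type,
    caloric = logs$log_type %in% c("food", "beverage"))
}
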