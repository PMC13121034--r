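#' Classify log latency
#'
#' A log whose server receipt time differs from its stated ingestion time
#' by more than `threshold_min` minutes (strictly greater) is a delayed
#' log; an exactly 15-minute gap is still real time. Logs without a server
#' time are treated as real time, since classification is only by the
#' measured gap.
#'
#' @param logs a log table with `log_time` and `server_time` columns.
#' @param threshold_min latency threshold in minutes (default 15).
#' @return character vector, `"real_time"` or `"delayed"`, one per log.
#' @export
classify_log_latency <- function(logs, threshold_min = 15) {
  gap <- abs(as.numeric(logs$server_time) - as.numeric(logs$log_time)) / 60
  ifelse(!is.na(gap) & gap > threshold_min, "delayed", "real_time")
}

#' Detect backlogged logs from minute-of-hour preference
#'
#' Delayed logs split into two kinds: transmission delays (accurate
#' ingestion time, minute-of-hour distributed like real-time logs) and
#' backlogs, where the user reconstructed the time from memory and
#' preferentially typed rounded minutes (multiples of five). The detector
#' (i) runs a chi-squared test of independence comparing the 60-bin
#' minute-of-hour distributions of delayed vs real-time logs (df = 59);
#' (ii) flags every minute whose share among delayed logs exceeds its
#' real-time share by more than `excess_ratio` (share_delayed >
#' share_realtime * (1 + excess_ratio)); (iii) relabels every delayed log
#' at a flagged minute as a backlog. Because non-backlog delayed logs
#' still carry accurate times, the report's `realtime_equivalent_fraction`
#' is `1 - backlog_fraction_of_all`.
#'
#' @param logs log table.
#' @param latency_class character vector from [classify_log_latency()]
#'   (computed if missing).
#' @param excess_ratio flagging threshold on the share excess (default
#'   0.5, i.e. 50% above the real-time share). A heuristic; configurable.
#' @param threshold_min passed to [classify_log_latency()] when needed.
#' @return a `backlog_report` list: `delayed_fraction`,
#'   `backlog_fraction_of_delayed`, `backlog_fraction_of_all`,
#'   `realtime_equivalent_fraction`, `flagged_minutes`, `chi2_stat`,
#'   `chi2_df`, `p_value`, and `latency_class` (per-log classes with
#'   backlogs relabelled).
#' @export
detect_backlogs <- function(logs, latency_class = NULL, excess_ratio = 0.5,
                            threshold_min = 15) {
  if (is.null(latency_class)) latency_class <- classify_log_latency(logs, threshold_min)
  minute_of_hour <- as.POSIXlt(logs$log_time)$min
  delayed <- latency_class == "delayed"
  n <- length(latency_class)
  delayed_fraction <- if (n > 0) mean(delayed) else 0

  if (!any(delayed)) {
    return(structure(list(
      delayed_fraction = 0, backlog_fraction_of_delayed = 0,
      backlog_fraction_of_all = 0, realtime_equivalent_fraction = 1,
      flagged_minutes = integer(0), chi2_stat = NA_real_, chi2_df = NA_integer_,
      p_value = NA_real_, latency_class = latency_class), class = "backlog_report"))
  }
  stopifnot(any(!delayed))

  bins <- factor(minute_of_hour, levels = 0:59)
  counts_d <- table(bins[delayed])
  counts_r <- table(bins[!delayed])
  chi <- suppressWarnings(stats::chisq.test(rbind(as.integer(counts_d),
                                                  as.integer(counts_r))))
  share_d <- as.numeric(counts_d) / sum(counts_d)
  share_r <- as.numeric(counts_r) / sum(counts_r)
  flagged <- which(share_d > share_r * (1 + excess_ratio)) - 1L

  is_backlog <- delayed & minute_of_hour %in% flagged
  latency_class[is_backlog] <- "backlog"
  backlog_of_delayed <- sum(is_backlog) / sum(delayed)
  backlog_of_all <- sum(is_backlog) / n

  structure(list(
    delayed_fraction = delayed_fraction,
    backlog_fraction_of_delayed = backlog_of_delayed,
    backlog_fraction_of_all = backlog_of_all,
    realtime_equivalent_fraction = 1 - backlog_of_all,
    flagged_minutes = flagged,
    chi2_stat = unname(chi$statistic), chi2_df = unname(chi$parameter),
    p_value = chi$p.value,
    latency_class = latency_class), class = "backlog_report")
}

#' @export
print.backlog_report <- function(x, ...) {
  cat(sprintf(paste0("<backlog_report> delayed %.2f%%; backlogs %.2f%% of delayed",
                     " (%.2f%% of all; real-time-equivalent %.2f%%)\n"),
              100 * x$delayed_fraction, 100 * x$backlog_fraction_of_delayed,
              100 * x$backlog_fraction_of_all, 100 * x$realtime_equivalent_fraction))
  cat("flagged minutes:", paste(x$flagged_minutes, collapse = " "), "\n")
  if (!is.na(x$chi2_stat))
    cat(sprintf("chi-squared = %.2f, df = %d, p %s\n", x$chi2_stat, x$chi2_df,
                format.pval(x$p_value)))
  invisible(x)
}

#' Build per-participant compliance days
#'
#' Groups a participant's caloric items by logical day, merges them into
#' eating occasions ([group_eating_events()]) and applies the compliance
#' rule: a logical day is compliant iff it has at least two caloric eating
#' occasions and at least `min_span_min` minutes (default 300, i.e. 5 h)
#' between the first and last caloric log of the day.
#'
#' @param parsed_items tibble of parsed items (one row per item) with
#'   columns `participant_id`, `logical_date`, `minute_of_day`, `caloric`.
#' @param gap_min occasion-merging gap in minutes (default 15).
#' @param min_events minimum caloric occasions per compliant day.
#' @param min_span_min minimum first-to-last caloric span (minutes).
#' @return tibble with one row per participant-day: `participant_id`,
#'   `logical_date`, `n_caloric_logs`, `n_events`, `first_minute`,
#'   `last_minute`, `span_min`, `compliant`.
#' @export
compliance_days <- function(parsed_items, gap_min = 15, min_events = 2,
                            min_span_min = 300) {
  cal <- dplyr::filter(parsed_items, .data$caloric)
  if (nrow(cal) == 0) {
    return(tibble::tibble(participant_id = character(),
                          logical_date = as.Date(character()),
                          n_caloric_logs = integer(), n_events = integer(),
                          first_minute = numeric(), last_minute = numeric(),
                          span_min = numeric(), compliant = logical()))
  }
  # distinct caloric log times: items sharing a log share one time
  cal <- dplyr::distinct(cal, .data$participant_id, .data$logical_date,
                         .data$minute_of_day)
  out <- cal |>
    dplyr::group_by(.data$participant_id, .data$logical_date) |>
    dplyr::summarise(
      n_caloric_logs = dplyr::n(),
      n_events = n_eating_events(sort(.data$minute_of_day), gap_min),
      first_minute = min(.data$minute_of_day),
      last_minute = max(.data$minute_of_day),
      .groups = "drop") |>
    dplyr::mutate(span_min = .data$last_minute - .data$first_minute,
                  compliant = .data$n_events >= min_events &
                    .data$span_min >= min_span_min)
  tibble::as_tibble(out)
}

#' Is a single day compliant?
#'
#' Day-level form of the compliance rule for pre-grouped minutes.
#'
#' @param minutes sorted or unsorted caloric log day-minutes of one day.
#' @param gap_min,min_events,min_span_min see [compliance_days()].
#' @return logical scalar.
#' @export
is_compliant_day <- function(minutes, gap_min = 15, min_events = 2,
                             min_span_min = 300) {
  minutes <- sort(unique(minutes))
  length(minutes) > 0 &&
    n_eating_events(minutes, gap_min) >= min_events &&
    (max(minutes) - min(minutes)) >= min_span_min
}

#' Participant eligibility from the first 14 days
#'
#' A participant is eligible when at least `min_days` of their first
#' `horizon_days` logical days of logging (counted from their first log's
#' logical date) are compliant. Monotone: adding a compliant day never
#' revokes eligibility.
#'
#' @param days output of [compliance_days()] (all participants).
#' @param min_days minimum compliant days (default 10).
#' @param horizon_days logging horizon (default 14).
#' @return tibble `participant_id`, `compliant_days`, `eligible`.
#' @export
eligible_participants <- function(days, min_days = 10, horizon_days = 14) {
  out <- days |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(.in_horizon = .data$logical_date <
                    min(.data$logical_date) + horizon_days) |>
    dplyr::summarise(
      compliant_days = sum(.data$compliant & .data$.in_horizon),
      .groups = "drop") |>
    dplyr::mutate(eligible = .data$compliant_days >= min_days)
  tibble::as_tibble(out)
}

#' Strip non-descriptive phrases for diversity analyses
#'
#' Removes items whose canonical name is one of the non-descriptive
#' phrases (e.g. "breakfast", "snack"), recomputes day compliance from the
#' remaining caloric items, and drops participants left ineligible by the
#' removal (including those all of whose logs were a single generic
#' phrase).
#'
#' @param parsed_items parsed-item tibble.
#' @param nondescriptive character vector of phrases to strip (default
#'   the shipped 16-phrase list).
#' @param min_days,horizon_days eligibility parameters re-applied after
#'   stripping.
#' @return list with `items` (stripped tibble) and `dropped_participants`
#'   (character vector).
#' @export
filter_nondescriptive <- function(parsed_items,
                                  nondescriptive = default_nondescriptive(),
                                  min_days = 10, horizon_days = 14) {
  if (length(nondescriptive) == 0) {
    return(list(items = parsed_items, dropped_participants = character(0)))
  }
  kept <- dplyr::filter(parsed_items, !(.data$name %in% nondescriptive))
  elig <- eligible_participants(compliance_days(kept), min_days, horizon_days)
  before <- unique(parsed_items$participant_id)
  ok <- elig$participant_id[elig$eligible]
  dropped <- setdiff(before, ok)
  list(items = dplyr::filter(kept, .data$participant_id %in% ok),
       dropped_participants = dropped)
}
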