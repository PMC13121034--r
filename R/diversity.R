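#' Per-user food diversity
#'
#' Food diversity is the number of unique dictionary-matched caloric item
#' names a participant logged, after removing non-descriptive phrases
#' ("breakfast", "snack", ...) and ingredient-like items (condiments,
#' sauces, cooking ingredients). Returned cumulatively over logging days
#' 1..`n_days` so day-1 diversity (one diary day) can be compared with the
#' full-period diversity.
#'
#' @param parsed_items parsed-item tibble for one cohort.
#' @param nondescriptive,ingredients character vectors of excluded names
#'   (defaults: the shipped lists).
#' @param n_days horizon in days (default 14).
#' @return tibble with one row per participant: `day_01` .. `day_14`
#'   cumulative unique-item counts and `final_diversity`.
#' @export
user_diversity <- function(parsed_items,
                           nondescriptive = default_nondescriptive(),
                           ingredients = default_ingredients(),
                           n_days = 14) {
  excl <- c(nondescriptive, ingredients)
  cal <- parsed_items |>
    dplyr::filter(.data$caloric, !(.data$name %in% excl))
  day_cols <- sprintf("day_%02d", seq_len(n_days))
  if (nrow(cal) == 0) {
    out <- tibble::tibble(participant_id = character())
    for (cl in day_cols) out[[cl]] <- integer()
    out$final_diversity <- integer()
    return(out)
  }
  cal <- cal |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(day_index = as.integer(.data$logical_date -
                                           min(.data$logical_date)) + 1L) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$day_index <= n_days)

  firsts <- cal |>
    dplyr::group_by(.data$participant_id, .data$name) |>
    dplyr::summarise(first_day = min(.data$day_index), .groups = "drop")

  out <- firsts |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(cum = list(cumsum(tabulate(.data$first_day, nbins = n_days))),
                     .groups = "drop")
  mat <- do.call(rbind, out$cum)
  colnames(mat) <- day_cols
  res <- dplyr::bind_cols(tibble::tibble(participant_id = out$participant_id),
                          tibble::as_tibble(mat))
  res$final_diversity <- unname(mat[, n_days])
  res
}

#' Item popularity across the cohort
#'
#' Popularity of an item is the percentage of eligible users who logged it
#' at least once. Items are ranked by descending popularity with ties
#' broken by total log count (descending) then name, so rankings are
#' reproducible.
#'
#' @param parsed_items parsed-item tibble (caloric items only are
#'   ranked).
#' @param n_users cohort size for the percentage denominator (default:
#'   number of distinct participants in `parsed_items`).
#' @return tibble per item: `name`, `item_type`, `n_logs`, `n_users`,
#'   `popularity_pct`, `rank`.
#' @export
item_popularity <- function(parsed_items, n_users = NULL) {
  cal <- dplyr::filter(parsed_items, .data$caloric)
  denom <- if (is.null(n_users)) {
    dplyr::n_distinct(parsed_items$participant_id)
  } else n_users
  out <- cal |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(item_type = .data$item_type[1],
                     n_logs = dplyr::n(),
                     n_users = dplyr::n_distinct(.data$participant_id),
                     .groups = "drop")
  out$popularity_pct <- 100 * out$n_users / denom
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$popularity_pct), dplyr::desc(.data$n_logs),
                   .data$name) |>
    dplyr::mutate(rank = dplyr::row_number())
  tibble::as_tibble(out)
}

#' Habitual items
#'
#' A habitual item is one consumed by at least `min_users` participants on
#' at least `min_days` distinct logical days each (the study's rule: >=
#' 100 participants, ~0.5% of the cohort, on >= 7 of 14 days).
#'
#' @param parsed_items parsed-item tibble.
#' @param min_users minimum habitual consumers (default 100).
#' @param min_days minimum distinct days per consumer (default 7).
#' @return tibble per habitual item: `name`, `n_habitual_users`.
#' @export
habitual_items <- function(parsed_items, min_users = 100, min_days = 7) {
  counts <- user_item_days(parsed_items)
  out <- counts |>
    dplyr::filter(.data$n_days >= min_days) |>
    dplyr::count(.data$name, name = "n_habitual_users") |>
    dplyr::filter(.data$n_habitual_users >= min_users) |>
    dplyr::arrange(dplyr::desc(.data$n_habitual_users), .data$name)
  tibble::as_tibble(out)
}

#' Distinct consumption days per user and item
#'
#' @param parsed_items parsed-item tibble.
#' @return tibble `participant_id`, `name`, `n_days` (distinct logical
#'   days with >= 1 log of the item), `n_logs`.
#' @export
user_item_days <- function(parsed_items) {
  out <- parsed_items |>
    dplyr::filter(.data$caloric) |>
    dplyr::group_by(.data$participant_id, .data$name) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$logical_date),
                     n_logs = dplyr::n(), .groups = "drop")
  tibble::as_tibble(out)
}

#' Dense ranks of consumption counts
#'
#' Dense ranking by descending count: tied counts share a rank and the
#' next distinct count takes the next integer rank, so `{A:5, B:3, C:3,
#' D:1}` ranks A=1, B=C=2, D=3.
#'
#' @param counts named or unnamed numeric vector of per-item consumption
#'   counts.
#' @return integer ranks aligned with `counts`.
#' @export
dense_ranks <- function(counts) {
  dplyr::dense_rank(dplyr::desc(counts))
}

#' Items needed to cover a fraction of a user's logs
#'
#' Smallest k such that the user's k most frequently consumed items
#' (descending count, ties by name) jointly account for at least
#' `fraction` of all their item occurrences.
#'
#' @param counts named numeric vector: per-item occurrence counts for one
#'   user.
#' @param fraction target coverage in `(0, 1]`.
#' @return integer k.
#' @export
coverage_count <- function(counts, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  if (length(counts) == 0 || sum(counts) == 0)
    stop("coverage_count undefined for empty counts")
  nm <- if (is.null(names(counts))) as.character(seq_along(counts)) else names(counts)
  ord <- order(-counts, nm)
  cum <- cumsum(counts[ord]) / sum(counts)
  unname(which(cum >= fraction - 1e-12)[1])
}

#' Timing of habitual vs novel consumption
#'
#' Classifies each user's items as habitual (cohort-habitual per
#' [habitual_items()] and consumed by this user on >= `min_days` days) or
#' novel (consumed exactly once in the period), pools the log times of the
#' two classes, and reports binned distributions plus the difference of
#' medians (novel minus habitual; positive when novelty comes later in
#' the day).
#'
#' @param parsed_items parsed-item tibble.
#' @param min_users,min_days habituality rule (defaults 100 and 7).
#' @param bin_min histogram bin width (default 60).
#' @return list: `habitual` and `novel` binned distributions
#'   ([binned_distribution()]), `median_habitual`, `median_novel`,
#'   `median_diff_min`, and log counts per class.
#' @export
timing_by_familiarity <- function(parsed_items, min_users = 100, min_days = 7,
                                  bin_min = 60) {
  hab <- habitual_items(parsed_items, min_users, min_days)
  uid <- user_item_days(parsed_items)
  hab_pairs <- dplyr::filter(uid, .data$name %in% hab$name,
                             .data$n_days >= min_days)
  nov_pairs <- dplyr::filter(uid, .data$n_logs == 1)
  cal <- dplyr::filter(parsed_items, .data$caloric)
  hab_logs <- dplyr::semi_join(cal, hab_pairs, by = c("participant_id", "name"))
  nov_logs <- dplyr::semi_join(cal, nov_pairs, by = c("participant_id", "name"))
  med_h <- if (nrow(hab_logs) > 0) stats::median(hab_logs$minute_of_day) else NA_real_
  med_n <- if (nrow(nov_logs) > 0) stats::median(nov_logs$minute_of_day) else NA_real_
  list(habitual = binned_distribution(hab_logs$minute_of_day, bin_min),
       novel = binned_distribution(nov_logs$minute_of_day, bin_min),
       median_habitual = med_h, median_novel = med_n,
       median_diff_min = med_n - med_h,
       n_habitual_logs = nrow(hab_logs), n_novel_logs = nrow(nov_logs))
}

#' Per-item TF50 for regular vs occasional consumers
#'
#' For each habitual item, the median log time among regular consumers
#' (logged it on >= `regular_days` distinct days) and among occasional
#' consumers (<= `occasional_days` distinct days).
#'
#' @param parsed_items parsed-item tibble.
#' @param min_users,min_days habituality rule.
#' @param regular_days,occasional_days consumer-class thresholds
#'   (defaults 7 and 2).
#' @return tibble per habitual item: `name`, `n_habitual_users`,
#'   `tf50_regular`, `tf50_occasional`.
#' @export
habitual_item_tf50 <- function(parsed_items, min_users = 100, min_days = 7,
                               regular_days = 7, occasional_days = 2) {
  hab <- habitual_items(parsed_items, min_users, min_days)
  if (nrow(hab) == 0) return(dplyr::mutate(hab, tf50_regular = numeric(0),
                                           tf50_occasional = numeric(0)))
  uid <- dplyr::filter(user_item_days(parsed_items), .data$name %in% hab$name)
  cal <- dplyr::filter(parsed_items, .data$caloric, .data$name %in% hab$name)
  classed <- dplyr::mutate(uid, class = dplyr::case_when(
    .data$n_days >= regular_days ~ "regular",
    .data$n_days <= occasional_days ~ "occasional",
    TRUE ~ NA_character_))
  logs <- dplyr::inner_join(cal,
                            dplyr::select(classed, "participant_id", "name", "class"),
                            by = c("participant_id", "name")) |>
    dplyr::filter(!is.na(.data$class))
  tf <- logs |>
    dplyr::group_by(.data$name, .data$class) |>
    dplyr::summarise(tf50 = stats::median(.data$minute_of_day), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "tf50",
                       names_prefix = "tf50_")
  out <- dplyr::left_join(hab, tf, by = "name")
  if (!"tf50_regular" %in% names(out)) out$tf50_regular <- NA_real_
  if (!"tf50_occasional" %in% names(out)) out$tf50_occasional <- NA_real_
  tibble::as_tibble(out)
}
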