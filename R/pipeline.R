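#' Run the full analysis pipeline
#'
#' Orchestrates parse -> quality control -> timing metrics -> diversity ->
#' subgroup comparison -> diurnal clustering over a log table and
#' demographics, writing the standard outputs (metrics, decile tables,
#' subgroup JSON, clusters, and a Markdown report with the headline
#' numbers) into `out_dir`. Deterministic given the inputs and `seed`; the
#' resolved configuration is serialised alongside the outputs for
#' provenance.
#'
#' @param logs a log table ([read_log_table()] / [generate_cohort()]).
#' @param demographics demographics tibble ([read_demographics()]).
#' @param out_dir output directory (created if needed).
#' @param dict,typo_dict parsing dictionaries.
#' @param top_k items tracked for popularity/clustering (default 100,
#'   capped at the matched vocabulary).
#' @param k clusters (default 5).
#' @param B JSD permutations (default 1000).
#' @param seed RNG seed for the permutation test.
#' @param latency_threshold,gap_min,quantile_method,min_days,horizon_days
#'   module parameters (see the respective functions).
#' @param min_habitual_users habituality threshold scaled to the cohort
#'   (default `max(5, round(0.005 * n_users))`, the ~0.5% rule).
#' @return invisibly, a list with every stage's result (`backlog`,
#'   `eligibility`, `metrics`, `decile_tables`, `diversity`, `popularity`,
#'   `habitual`, `subgroup`, `clusters`, `coverage`).
#' @export
run_pipeline <- function(logs, demographics, out_dir,
                         dict = default_food_dictionary(),
                         typo_dict = default_typo_dictionary(),
                         top_k = 100, k = 5, B = 1000, seed = 1,
                         latency_threshold = 15, gap_min = 15,
                         quantile_method = "linear",
                         min_days = 10, horizon_days = 14,
                         min_habitual_users = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # parse
  parsed <- parse_logs(logs, dict, typo_dict)
  items <- parsed$items

  # quality control
  backlog <- detect_backlogs(logs, threshold_min = latency_threshold)
  days <- compliance_days(items, gap_min = gap_min)
  elig <- eligible_participants(days, min_days, horizon_days)
  ok <- elig$participant_id[elig$eligible]
  items <- dplyr::filter(items, .data$participant_id %in% ok)
  n_users <- length(ok)
  if (is.null(min_habitual_users)) min_habitual_users <- max(5, round(0.005 * n_users))

  # timing metrics and decile structure
  metrics <- participant_metrics(items, gap_min = gap_min,
                                 quantile_method = quantile_method,
                                 min_days = min_days, horizon_days = horizon_days)
  write_metrics_table(metrics, file.path(out_dir, "metrics.csv"))
  decile_cols <- c("tf50_minute", "avg_window_min", "p95_window_min",
                   "p95_start_minute", "p95_end_minute",
                   "first_shift_min", "last_shift_min")
  decile_tables <- dplyr::bind_rows(lapply(decile_cols, function(cl) {
    v <- metrics[[cl]][!is.na(metrics[[cl]])]
    if (length(v) < 10) return(NULL)
    dplyr::mutate(decile_table(v), metric = cl, .before = 1)
  }))
  utils::write.csv(decile_tables, file.path(out_dir, "decile_tables.csv"),
                   row.names = FALSE)

  # diversity / popularity / habituality
  strip <- filter_nondescriptive(items, min_days = min_days,
                                 horizon_days = horizon_days)
  diversity <- user_diversity(strip$items, n_days = horizon_days)
  popularity <- item_popularity(items)
  habitual <- habitual_item_tf50(items, min_users = min_habitual_users)
  utils::write.csv(diversity, file.path(out_dir, "diversity.csv"), row.names = FALSE)
  utils::write.csv(popularity, file.path(out_dir, "popularity.csv"), row.names = FALSE)

  # subgroup comparison (sex, on the top-K popularity distributions)
  top_k <- min(top_k, nrow(popularity))
  top <- utils::head(popularity$name, top_k)
  demo <- dplyr::filter(demographics, .data$participant_id %in% ok)
  subgroup <- NULL
  two_sex <- demo$participant_id[demo$sex %in% c("male", "female")]
  if (length(unique(demo$sex[demo$participant_id %in% two_sex])) == 2) {
    inc <- incidence_matrix(dplyr::filter(items, .data$participant_id %in% two_sex),
                            items = top)
    lab <- demo$sex[match(rownames(inc), demo$participant_id)]
    jt <- jsd_permutation_test(inc, lab, B = B, seed = seed)
    groups <- split(demo$participant_id[demo$sex %in% c("female", "male")],
                    demo$sex[demo$sex %in% c("female", "male")])
    subgroup <- list(comparison = "female_vs_male",
                     jsd = jt$observed, jsd_p = jt$p_value, B = B,
                     rank_changes = rank_change_table(items, groups, top_k))
    jsonlite::write_json(
      list(comparison = subgroup$comparison, jsd = subgroup$jsd,
           jsd_p = subgroup$jsd_p, B = B,
           rank_changes = subgroup$rank_changes),
      file.path(out_dir, "subgroup.json"), digits = NA, auto_unbox = TRUE)
  }

  # diurnal clustering of top items
  profiles <- build_profiles(items, top)
  clusters <- NULL
  if (nrow(profiles) >= k) {
    clusters <- cluster_profiles(profiles, items, k = k)
    utils::write.csv(tibble::tibble(name = names(clusters$labels),
                                    cluster = unname(clusters$labels)),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
  }

  report <- c(
    "# chronoeat pipeline report", "",
    sprintf("- logs: %d; parse coverage: %.1f%%", nrow(logs), 100 * parsed$coverage),
    sprintf("- eligible participants: %d of %d", n_users, nrow(elig)),
    sprintf("- delayed logs: %.2f%%; backlogs: %.2f%% of all (real-time-equivalent %.2f%%)",
            100 * backlog$delayed_fraction, 100 * backlog$backlog_fraction_of_all,
            100 * backlog$realtime_equivalent_fraction),
    sprintf("- mean TF50: %s; mean 95%% window: %.0f min (start %s, end %s)",
            minute_to_hhmm(mean(metrics$tf50_minute)), mean(metrics$p95_window_min),
            minute_to_hhmm(mean(metrics$p95_start_minute)),
            minute_to_hhmm(mean(metrics$p95_end_minute))),
    sprintf("- mean average window: %.0f min; first/last shift: %.0f / %.0f min",
            mean(metrics$avg_window_min), mean(metrics$first_shift_min, na.rm = TRUE),
            mean(metrics$last_shift_min, na.rm = TRUE)),
    sprintf("- mean 14-day diversity: %.1f unique items; %d habitual item(s)",
            mean(diversity$final_diversity), nrow(habitual)),
    if (!is.null(subgroup))
      sprintf("- sex JSD on top-%d items: %.4f (p = %.4g, B = %d)",
              top_k, subgroup$jsd, subgroup$jsd_p, B),
    if (!is.null(clusters)) c("", "## Cluster TF50s", "",
                              sprintf("- cluster %d (%d items): %s",
                                      clusters$summary$cluster,
                                      clusters$summary$n_items,
                                      clusters$summary$tf50_hhmm)))
  writeLines(report, file.path(out_dir, "report.md"))
  jsonlite::write_json(
    list(top_k = top_k, k = k, B = B, seed = seed,
         latency_threshold = latency_threshold, gap_min = gap_min,
         quantile_method = quantile_method, min_days = min_days,
         horizon_days = horizon_days, min_habitual_users = min_habitual_users),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(backlog = backlog, eligibility = elig, metrics = metrics,
                 decile_tables = decile_tables, diversity = diversity,
                 popularity = popularity, habitual = habitual,
                 subgroup = subgroup, clusters = clusters,
                 coverage = parsed$coverage))
}
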