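#!/usr/bin/env Rscript
# Step 4 — dietary diversity, popularity, habituality and coverage.
#
# After stripping the 16 non-descriptive phrases and the ingredient-style
# exclusion list, counts each participant's cumulative unique caloric
# items over days 1..14; ranks items by cohort popularity; identifies
# habitual items (>= 0.5% of the cohort on >= 7 distinct days) and
# compares per-item TF50 between regular and occasional consumers; and
# summarises per-user consumption concentration (dense ranks, items
# covering 50/75/90% of logs) and the timing of habitual vs novel
# consumption.

suppressPackageStartupMessages(library(chronoeat))
dir.create("results", showWarnings = FALSE)

items <- read.csv("scratch/synth/parsed_items.csv")
items$logical_date <- as.Date(items$logical_date)
items$caloric <- as.logical(items$caloric)

strip <- filter_nondescriptive(items)
cat(sprintf("%d participants dropped by non-descriptive filtering\n",
            length(strip$dropped_participants)))
div <- user_diversity(strip$items)
write.csv(div, "results/diversity.csv", row.names = FALSE)
cat(sprintf("mean diversity: day 1 %.1f, day 7 %.1f, day 14 %.1f unique items\n",
            mean(div$day_01), mean(div$day_07), mean(div$day_14)))

pop <- item_popularity(items)
write.csv(pop, "results/popularity.csv", row.names = FALSE)
cat(sprintf("most popular item: %s (%.1f%% of users); 20th: %s (%.1f%%)\n",
            pop$name[1], pop$popularity_pct[1],
            pop$name[20], pop$popularity_pct[20]))

min_hab <- max(5, round(0.005 * dplyr::n_distinct(items$participant_id)))
hab <- habitual_item_tf50(items, min_users = min_hab)
write.csv(hab, "results/habitual_items.csv", row.names = FALSE)
both <- !is.na(hab$tf50_regular) & !is.na(hab$tf50_occasional)
cat(sprintf("%d habitual items; regular-consumer TF50 earlier for %d of %d\n",
            nrow(hab), sum(hab$tf50_regular[both] < hab$tf50_occasional[both]),
            sum(both)))

# per-user consumption concentration
counts <- user_item_days(items)
conc <- dplyr::bind_rows(lapply(split(counts, counts$participant_id), function(u) {
  cnt <- stats::setNames(u$n_logs, u$name)
  tibble::tibble(participant_id = u$participant_id[1],
                 top_item_logs = max(cnt),
                 cover50 = coverage_count(cnt, 0.5),
                 cover75 = coverage_count(cnt, 0.75),
                 cover90 = coverage_count(cnt, 0.9),
                 max_rank_gt1 = max(dense_ranks(cnt)[cnt > 1], 0))
}))
write.csv(conc, "results/concentration.csv", row.names = FALSE)
cat(sprintf("median items covering 50/75/90%% of a user's logs: %d / %d / %d\n",
            median(conc$cover50), median(conc$cover75), median(conc$cover90)))
cat(sprintf("a user's top item is logged %.1f times on average\n",
            mean(conc$top_item_logs)))

fam <- timing_by_familiarity(items, min_users = min_hab)
cat(sprintf("median novel consumption %s vs habitual %s (novel %d min later)\n",
            minute_to_hhmm(fam$median_novel), minute_to_hhmm(fam$median_habitual),
            round(fam$median_diff_min)))
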