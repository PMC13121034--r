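#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates a synthetic logging cohort under the default study conditions
# (500 users, 14 days, 04:00-anchored day, bimodal event timing peaking at
# 12:00 and 18:00, negatively associated window start/length, day-to-day
# first/last-intake jitter, Zipf item popularity over five diurnal
# archetypes, habitual items consumed ahead of their typical time, and
# latency/typo/non-descriptive logging noise). Raw tables go to scratch/
# (they are inputs for the later steps); ground truth is kept alongside.

suppressPackageStartupMessages(library(chronoeat))

seed <- 2026
dir.create("scratch/synth", showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config()
cohort <- generate_cohort(cfg, seed = seed)

write.csv(cohort$logs, "scratch/synth/logs.csv", row.names = FALSE)
write.csv(cohort$demographics, "scratch/synth/demographics.csv", row.names = FALSE)
write.csv(cohort$truth$parsed_items, "scratch/synth/truth_items.csv", row.names = FALSE)
write.csv(cohort$truth$users, "scratch/synth/truth_users.csv", row.names = FALSE)
write.csv(cohort$truth$items, "scratch/synth/truth_item_archetypes.csv", row.names = FALSE)
write.csv(cohort$truth$logs, "scratch/synth/truth_logs.csv", row.names = FALSE)

cat(sprintf("simulated %d logs from %d users over %d days (seed %d)\n",
            nrow(cohort$logs), cfg$n_users, cfg$n_days, seed))
cat(sprintf("log types: %s\n",
            paste(sprintf("%s %d", names(table(cohort$logs$log_type)),
                          table(cohort$logs$log_type)), collapse = ", ")))
cat(sprintf("injected latency classes: %s\n",
            paste(sprintf("%s %.2f%%", names(table(cohort$truth$logs$latency_class)),
                          100 * prop.table(table(cohort$truth$logs$latency_class))),
                  collapse = ", ")))
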