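# chronoeat

Chrononutrition analysis of timestamped free-text food diaries.

Smartphone logging apps produce multi-day records of *when* people eat
and *what* they say they ate — one row per log, with the phone-local
ingestion time, the server receipt time, and a natural-language
description ("latte, croissant and leftover pizza"). chronoeat turns
such tables into the standard temporal eating-pattern and food-choice
statistics used in chrononutrition and nutritional epidemiology. It is
aimed at researchers analysing app-collected diaries, and at
methodologists who need a fully synthetic, ground-truthed testbed for
these metrics.

## What it computes

All times live on a 04:00-anchored "logical day" (a log at 03:30 belongs
to the previous day), so statistics near midnight are well defined. For
each participant with ≥ 10 compliant days of their first 14 (a
compliant day has ≥ 2 caloric eating occasions — maximal chains of
caloric logs with gaps < 15 min — spanning ≥ 5 h):

* **TF50** — the median caloric log time, `median(t_1..t_n)`;
  distinguishes early from late eaters.
* **Average eating window** — `mean_d(t_last(d) − t_first(d))` over
  compliant days d.
* **95% eating window** — `Q_0.975(t) − Q_0.025(t)` over all pooled
  caloric log times; the envelope that day-to-day variation makes wider
  than the average window.
* **First/last intake shift** — `mean_d |t_first(d+1) − t_first(d)|`
  (resp. `t_last`): day-to-day eating-time irregularity.

Around these sit: a deterministic free-text parser (typo correction,
joined-word splitting, greedy longest-phrase matching against a typed
dictionary); latency quality control that separates genuinely delayed
transmissions from memory-reconstructed "backlogs" via minute-of-hour
rounding preference (chi-squared, df = 59); diversity, popularity,
dense-rank, coverage and habituality statistics; subgroup comparison by
Jensen–Shannon distance permutation tests (base-2, `p = (1+#{perm ≥
obs})/(B+1)`) plus Mann–Whitney/Cliff's delta, Wilcoxon/rank-biserial,
Kruskal–Wallis/Dunn–Holm contracts; hierarchical clustering of per-item
96-bin diurnal profiles (correlation distance, Ward linkage, clusters
ordered by pooled TF50); and a seeded synthetic-cohort generator whose
ground truth makes every stage testable. The methods vignette
(`vignettes/chronoeat-methods.Rmd`) documents every model, parameter
and numerical choice.

## Worked example

```r
library(chronoeat)

cohort <- generate_cohort(synthetic_config(n_users = 100), seed = 42)
parsed <- parse_logs(cohort$logs)          # free text -> typed items

detect_backlogs(cohort$logs)
#> <backlog_report> delayed 15.48%; backlogs 41.94% of delayed
#>   (6.49% of all; real-time-equivalent 93.51%)
#> flagged minutes: 0 5 10 15 20 25 30 35 40 45 50 55
#> chi-squared = 275.09, df = 59, p < 2.22e-16

metrics <- participant_metrics(parsed$items)
minute_to_hhmm(mean(metrics$tf50_minute))            #> "14:51"
round(mean(metrics$p95_window_min))                  #> 993
round(mean(metrics$first_shift_min, na.rm = TRUE))   #> 96

top <- head(item_popularity(parsed$items)$name, 50)
cluster_profiles(build_profiles(parsed$items, top), parsed$items, k = 5)$summary
#>   cluster n_items tf50_minute tf50_hhmm
#> 1       1       7         290 08:50
#> 2       2      13         525 12:45
#> 3       3      14         673 15:13
#> 4       4      10         855 18:15
#> 5       5       6        1077 21:57
```

Reading the output: 15.48% of this cohort's logs arrived at the server
more than 15 min after their stated time; the minutes-of-the-hour of
delayed logs pile up on multiples of five, so 41.94% of them are
reclassified as memory-reconstructed backlogs, leaving 93.51% of logs
with trustworthy real-time stamps. The average participant reaches half
their caloric logs by 14:51 and eats within a 993-minute (≈ 16.5 h)
95% envelope that is much wider than any single day's span, and their
first intake moves by ~1.6 h between consecutive days. The 50 most
popular items fall into five diurnal clusters whose pooled TF50s march
from breakfast (08:50) to late evening (21:57).

## The analysis workflow

The `analysis/` directory is a numbered, re-runnable account of the full
study on a simulated cohort; each script states what it found on stdout
and writes its tables under `results/` (bulky intermediates go to
`scratch/`):

```sh
Rscript analysis/01_simulate.R     # cohort + ground truth
Rscript analysis/02_parse_qc.R     # parsing, latency QC, eligibility
Rscript analysis/03_metrics.R      # timing metrics, deciles, start-vs-length
Rscript analysis/04_diversity.R    # diversity, popularity, habituality, coverage
Rscript analysis/05_subgroups.R    # work/age/sex contrasts, JSD permutation tests
Rscript analysis/06_clustering.R   # diurnal profile clusters vs ground truth
```

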