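---
title: "Methods: temporal eating-pattern metrics from free-text food logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal eating-pattern metrics from free-text food logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chronoeat analyses timestamped free-text food and beverage diaries of the
kind collected by logging apps: each record carries a participant id, the
phone-local time the user says the intake happened, the time the record
reached the server, a natural-language description, and a user-assigned
log type. This vignette documents the models and conventions behind each
stage, the tunable parameters, the synthetic-cohort generator used to
validate the pipeline, and the numerical choices that matter.

## The logical day

All timing statistics operate on "day minutes": integer minutes since
04:00 of the logical day a log belongs to, so a log at 03:30 belongs to
the previous calendar date at day minute 1410. Anchoring the day at the
overnight activity trough makes the time axis linear — medians and
percentiles of eating times near midnight are otherwise ill-defined —
and no downstream statistic ever wraps across the boundary. Timestamps
are taken as phone-local wall time at face value (no timezone
arithmetic; participants who cross timezones are characterised by the
local times they reported), and seconds are truncated to minutes.

One display caveat follows from the anchor: means of *positional*
metrics (window start, window end, TF50) must be averaged on the
day-minute scale and converted to clock time afterwards. Averaging
wrapped clock hours gives meaningless values for windows that end past
midnight.

## Parsing free text into typed items

Logs are split at commas into sub-logs; each sub-log is lowercased,
stripped of punctuation, common English stopwords, standalone numbers
and measurement tokens (`oz`, `cup`, ...), and plural forms are reduced
to roots ("eggs" to "egg"). Root reduction is deliberately a small
plural stemmer with an exception list ("fries", "hummus", ...) rather
than a full lemmatizer: heavier stemming risks collisions between
distinct food names, and plural normalisation is the only inflection the
domain needs. Tokens are then corrected against a typo/abbreviation map,
incorrectly joined words are split when an exact two-word vocabulary
decomposition exists (ambiguity resolved leftmost-longest, i.e. the
longest valid first word wins), and the cleaned tokens are matched
greedily against a typed phrase dictionary: scanning left to right, the
longest matching phrase (up to five words) at each position is consumed.
Modifiers ("warm", "leftover") and dictionary stopwords are matched and
discarded; everything else becomes an item typed food, beverage, water,
medication or selfcare. An item is *caloric* iff it is food or beverage —
water is never caloric, while black coffee and non-caloric teas are
typed beverage because they break a fast.

Synonym grouping (whole wheat bread to "bread") lives in the dictionary
itself through an optional `canonical_name` column, not in code, so the
grouping policy is data a user can edit. The shipped dictionary is a
reduced open lexicon (roughly 230 foods, 50 beverages, plus modifier,
stopword, water, medication and selfcare lists, and a ~50-entry typo
map). It is large enough to exercise every code path and to drive the
synthetic cohort; scaling to a production lexicon of thousands of
phrases only requires longer files in the same two/three-column CSV
format.

## Compliance and latency quality control

A *compliant day* has at least two caloric eating occasions and at least
5 h (300 min) between the day's first and last caloric logs; occasions
are maximal chains of caloric logs with successive gaps under 15 min (a
gap of exactly 15 min starts a new occasion). A participant is
*eligible* when at least 10 of their first 14 logical days are
compliant. The two-occasion rule counts merged occasions, not raw logs,
and the 5 h rule is applied per day.

A log whose server receipt differs from its stated time by strictly more
than 15 min is a *delayed log*. Delayed logs split into transmission
delays (accurate times) and *backlogs* (times reconstructed from memory,
which users round): backlogs are detected from minute-of-hour
preference. The detector compares the 60-bin minute distributions of
delayed and real-time logs with a chi-squared test of independence
(df = 59) and flags every minute whose delayed-log share exceeds its
real-time share by more than `excess_ratio` (default 0.5 — a documented
heuristic, since "large difference from expectation" has no canonical
definition). Delayed logs at flagged minutes are relabelled backlog.
Because non-backlog delayed logs still carry accurate times, the report
also exposes a real-time-equivalent share, `1 − backlog share`, which is
the figure comparable to a "logged in real time" headline; the strict
latency classes themselves always sum to one.

## Timing metrics

For each eligible participant, over caloric logs on compliant days:

* **TF50** — the median caloric log time. Even counts take the mean of
  the two central order statistics.
* **Average eating window** — the mean over compliant days of the span
  between the day's first and last caloric logs. This understates the
  envelope of eating whenever day-to-day jitter exists, which is why the
  95% window is the preferred envelope metric.
* **95% eating window** — the span between the 2.5th and 97.5th
  percentiles of all pooled caloric log times. Quantiles interpolate
  linearly between order statistics (R type 7) by default; a
  nearest-rank mode (type 1) is available because the choice moves
  windows by minutes at small n. The interpolated quantile can exclude
  up to one extra point per tail, so the window contains at least
  `95% − 2/n` of logs.
* **First/last intake shift** — the mean absolute difference, between
  successive compliant days, of the day's first (last) caloric log
  time. "Successive" means successive compliant days by default;
  a calendar-adjacent-only mode is provided since the convention is not
  canonical.

Metrics pool caloric logs on compliant days only. Pooling all days
instead changes values marginally for eligible participants (who by
construction have at most 4 of 14 non-compliant days) but would let
single-log days perturb the shift statistics.

## Diversity, popularity, habituality

Food diversity is the count of unique caloric item names after removing
16 non-descriptive phrases ("breakfast", "snack", ...) and an
ingredient-style exclusion list (condiments, sauces, cooking
ingredients; shipped as an editable file). Participants left ineligible
once generic phrases are removed are dropped from diversity analyses.
Popularity is the percentage of eligible users logging an item at least
once; rankings break ties by total log count then name so they are
reproducible. A *habitual item* is consumed by at least 100 participants
(~0.5% of the study-scale cohort; the threshold scales as 0.5% for
smaller cohorts, floored at 5) on at least 7 of 14 distinct logical
days; a *novel* item is one a given user logged exactly once. Dense
ranking (ties share a rank, next distinct count increments by one) and
coverage counts (smallest k items covering 50/75/90% of a user's logs,
ties by name) summarise consumption concentration.

## Subgroup comparison

Users are split into near-equal decile (or percentile) bins by ranking
metric values; with remainder r the lowest r bins take one extra user
and ties keep input order, so bins always partition the cohort and
per-bin means recombine exactly to the cohort mean. Two-group
comparisons report the Mann–Whitney U with Cliff's delta; paired
designs the Wilcoxon signed-rank with rank-biserial correlation;
multi-group designs a Kruskal–Wallis omnibus followed by Dunn's pairwise
z tests on mean ranks (tie-corrected) with Holm adjustment — Holm is the
default because no adjustment is canonical here and it is uniformly
valid. Associations between decile membership and demographics use the
chi-squared test of independence.

Item-preference differences between groups use the Jensen–Shannon
distance between group popularity distributions restricted to the
global top-100 items and renormalised (a full-vocabulary mode exists).
Base-2 logarithms make the maximum exactly 1. Significance comes from a
one-sided permutation test shuffling group labels, with
`p = (1 + #{perm ≥ obs}) / (B + 1)`: the add-one convention makes the
smallest attainable p exactly `1/(B+1)` (0.000999 at B = 1000) and keeps
the test valid at any B.

## Diurnal profile clustering

Each top item's consumption is binned into 96 fifteen-minute bins over
the anchored day and normalised to sum to one, so popular items do not
dominate distances. Profiles are clustered agglomeratively and the tree
is cut at k = 5. The distance is correlation distance (1 − Pearson),
which compares profile shape rather than amplitude. The default linkage
is Ward (`ward.D2`): on binned profiles estimated from a few hundred
logs per item, average linkage chains — it peels off noisy outlier items
as singletons before separating genuinely distinct dayparts — whereas
Ward's variance criterion recovers planted archetype partitions exactly
in the shipped tests. Average linkage remains available. Cluster labels
are re-ordered by pooled TF50 ascending so cluster 1 is always the
earliest and partitions are reproducible and input-order invariant.

## The synthetic cohort generator

No raw cohort of this kind is publicly deposited, so the package ships a
seeded generative model that produces log tables, demographics and
ground truth, making every stage testable end to end. Per user, a 95%
window start is drawn (mean 07:47, s.d. 60 min — the s.d. chosen so that
the decile spread of start times under normality matches the spread the
emulated study reports) and a window length with a negative
start–length association (`length = 809 − 0.8·(start − mean) + noise`,
noise s.d. 100 min): people who start eating later have shorter windows.
Per day, the first and last intakes are jittered (s.d. 80 and 100 min —
back-solved from target mean day-to-day shifts of ~91 and ~113 min via
the closed form below), the event count is `2 + Poisson(2.7)`, and
interior event times are drawn from a two-component truncated-normal
mixture peaking at 12:00 and 18:00 inside the day's window.

Items follow a Zipf law (exponent 1) over the dictionary vocabulary,
with each item assigned one of five diurnal archetypes (morning;
all-day with a major breakfast peak; lunch-leaning; dinner-dominant;
late evening) cycled across popularity ranks so every popularity stratum
contains all archetypes. At an event at time t, the item is drawn with
probability proportional to Zipf weight times archetype density at t.
Each user holds a habitual item set (mean 4 items) spanning archetype
niches — users keep habitual breakfast *and* dinner items. Habitual
picks evaluate the selection density ahead of the event time and novel
picks behind it (offset 120 min), so habitual consumption of an item
runs earlier than its population-typical time and novel consumption
later; this, not the event-time shift alone, is what plants the
regular-vs-occasional TF50 ordering, because item choice conditioned on
time is otherwise insensitive to when the event happens. Logging noise
comprises delayed logs (15.57%), backlogs (41.49% of delayed logs
ending on 5-minute marks — defined as the *net* on-mark fraction, the
quantity the detector measures, so the generator snaps on top of the
20% of continuous minutes that land on marks by chance), typos (2%) and
non-descriptive phrases (3%, both modest rates consistent with the
~98% match coverage and ~4% generic-phrase usage of the emulated
study). Work schedules shift window start additively (night shift
largest) and widen jitter multiplicatively; age shifts start and length
by fractions of a minute per year. These demographic magnitudes are
illustrative defaults, not estimates.

`expected_statistics()` computes Monte-Carlo expectations (with
standard errors) of TF50, 95% window duration and the shift means by
simulating the timing layer directly — demographics and habitual/novel
offsets included, but no text rendering, parsing or compliance
filtering — and attaches closed forms where they exist: a first-intake
jitter of s.d. sigma yields an expected mean absolute day-to-day shift
of `2·sigma/sqrt(pi)` (the mean absolute difference of two independent
normals). Recovery tests compare pipeline estimates against these
expectations using the combined standard error of both Monte-Carlo
quantities.

What the generator does *not* emulate: portion sizes or energy content
(never collected), menu semantics beyond typed item names, weekday
effects, seasonal drift, timezone travel, or users abandoning the diary
mid-study. Passing recovery tests therefore demonstrates that the
pipeline measures what the generative model encodes, not that real
cohorts satisfy the model.

## Problem sizes and determinism

The shipped tests and the acceptance script use cohorts of 60–1,400
users (the largest only for the latency decomposition, where the
binomial tolerance calls for ~10^5 logs) and 200–1,000 permutations or
Monte-Carlo replicates; these sizes give stable statistics for every
check while keeping a full run in minutes on one core. The emulated
study's scale (21,006 users, 2.7 million logs) is documented throughout
but is not a default. Every stochastic step takes an explicit seed;
identical seeds give byte-identical cohorts, reports and p-values.

## Known limitations

* The backlog flagging threshold is a heuristic; cohorts whose genuine
  transmission delays correlate with rounded minutes would be
  over-flagged.
* The plural stemmer is English-only and intentionally conservative.
* The shipped dictionary is a reduced lexicon; absolute diversity and
  coverage numbers scale with dictionary size and are comparable only
  within a fixed dictionary.
* Night-shift workers are characterised on the same 04:00-anchored day
  as everyone else, which can misdescribe sleep-anchored behaviour.
* With compliant-day pooling, participants near the 10-of-14 eligibility
  boundary contribute fewer pooled logs, widening their window
  estimates slightly relative to fully compliant users.
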