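# Independent oracles, kept deliberately naive.
oracle_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracle_quantile7 <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
}
oracle_shift <- function(dates, minutes) {
  ord <- order(dates); m <- minutes[ord]
  d <- numeric(0)
  for (i in seq_len(length(m) - 1)) d <- c(d, abs(m[i + 1] - m[i]))
  mean(d)
}

test_that("eating-occasion grouping merges chains under 15 minutes", {
  # 09:45, 09:56, 10:10 are one occasion; 10:26 starts another
  m <- hhmm_to_minute(c("09:45", "09:56", "10:10", "10:26"))
  ev <- group_eating_events(m)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start_minute[1], hhmm_to_minute("09:45"))
  expect_equal(ev$end_minute[1], hhmm_to_minute("10:10"))
  expect_equal(ev$n_logs, c(3L, 1L))
  # a gap of exactly 15 minutes separates occasions
  expect_equal(nrow(group_eating_events(hhmm_to_minute(c("09:00", "09:15")))), 2)
  expect_equal(nrow(group_eating_events(rep(500, 5))), 1)
  expect_equal(nrow(group_eating_events(numeric(0))), 0)
})

test_that("tf50 is the median log time with the even-count convention", {
  expect_equal(tf50(hhmm_to_minute(c("08:00", "12:00", "20:00"))),
               hhmm_to_minute("12:00"))
  expect_equal(tf50(hhmm_to_minute(c("08:00", "12:00"))), hhmm_to_minute("10:00"))
  expect_error(tf50(numeric(0)), "undefined")
  set.seed(1)
  x <- sample.int(1440, 1001, replace = TRUE) - 1
  expect_equal(tf50(x), oracle_median(x))
})

test_that("95% window matches the order-statistic oracle", {
  expect_equal(unname(p95_window(rep(600, 10))["duration"]), 0)
  x <- 1:40
  w <- p95_window(x)
  expect_equal(unname(w["start"]), oracle_quantile7(x, 0.025))
  expect_equal(unname(w["end"]), oracle_quantile7(x, 0.975))
  set.seed(2)
  for (i in 1:200) {
    x <- sample.int(1440, sample(2:60, 1), replace = TRUE) - 1
    w <- p95_window(x)
    expect_equal(unname(w["start"]), oracle_quantile7(x, 0.025))
    expect_equal(unname(w["end"]), oracle_quantile7(x, 0.975))
    # interpolated quantiles can exclude up to one extra point per tail
    expect_gte(mean(x >= w["start"] - 1e-9 & x <= w["end"] + 1e-9),
               0.95 - 2 / length(x) - 1e-9)
  }
  expect_error(p95_window(5), "at least 2")
})

test_that("large uniform samples approach the analytic 95% span", {
  set.seed(3)
  x <- runif(20000, 360, 1200)
  expect_equal(unname(p95_window(x)["duration"]), 0.95 * 840, tolerance = 0.02)
})

test_that("average window and intake shifts follow their definitions", {
  expect_equal(avg_window(c(600, 720)), 660)
  expect_equal(avg_window(300), 300)
  d <- as.Date("2023-05-01") + 0:2
  expect_equal(intake_shift(d, hhmm_to_minute(c("08:00", "09:30", "08:30"))), 75)
  expect_equal(intake_shift(d, rep(500, 3)), 0)
  expect_true(is.na(intake_shift(d[1], 500)))
  set.seed(4)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    dates <- as.Date("2023-05-01") + sort(sample.int(20, n))
    m <- sample.int(1440, n, replace = TRUE) - 1
    expect_equal(intake_shift(dates, m), oracle_shift(dates, m))
    # invariance under global time translation
    expect_equal(intake_shift(dates, m + 17), intake_shift(dates, m))
  }
  # adjacent-only mode uses calendar-adjacent pairs only
  dd <- as.Date("2023-05-01") + c(0, 1, 5)
  expect_equal(intake_shift(dd, c(100, 160, 400), adjacent_only = TRUE), 60)
})

test_that("binned distributions cover the day and normalise", {
  b <- binned_distribution(hhmm_to_minute("12:00"), 60)
  expect_equal(nrow(b), 24)
  expect_equal(b$count[b$bin_start == hhmm_to_minute("12:00")], 1)
  expect_equal(sum(b$fraction), 1)
  b96 <- binned_distribution(c(0, 100, 1439), 15)
  expect_equal(nrow(b96), 96)
  expect_equal(sum(b96$count), 3)
})

test_that("participant metrics satisfy their structural invariants", {
  m <- participant_metrics(small_cohort()$truth$parsed_items)
  expect_true(all(m$p95_window_min >= 0))
  expect_true(all(m$p95_start_minute <= m$tf50_minute &
                    m$tf50_minute <= m$p95_end_minute))
  expect_true(all(m$first_shift_min >= 0 & m$last_shift_min >= 0, na.rm = TRUE))
  expect_equal(m$p95_window_min, m$p95_end_minute - m$p95_start_minute)
  # the 95% window exceeds the average window when day-to-day jitter exists
  expect_true(mean(m$p95_window_min > m$avg_window_min) > 0.9)
})

test_that("per-item TF50 distinguishes regular from occasional consumers", {
  expect_equal(item_tf50(hhmm_to_minute("18:00")), hhmm_to_minute("18:00"))
  expect_error(item_tf50(numeric(0)), "no logs")
  items <- default_cohort()$truth$parsed_items
  ht <- habitual_item_tf50(items, min_users = 10)
  both <- !is.na(ht$tf50_regular) & !is.na(ht$tf50_occasional)
  expect_gt(sum(both), 5)
  # habitual-set draws are generated earlier in the day
  expect_gt(mean(ht$tf50_occasional[both] > ht$tf50_regular[both]), 0.8)
})
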