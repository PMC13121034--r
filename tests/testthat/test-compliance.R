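test_that("latency classification uses a strict 15-minute threshold", {
  logs <- make_logs(rep("u1", 3), rep("2023-05-01 12:00", 3), "x",
                    server_time = c("2023-05-01 12:10", "2023-05-01 12:15",
                                    "2023-05-01 12:16"))
  expect_equal(classify_log_latency(logs),
               c("real_time", "real_time", "delayed"))
  # absent server time => real time by convention
  logs$server_time <- as.POSIXct(NA)
  expect_equal(unique(classify_log_latency(logs)), "real_time")
})

test_that("backlog detection flags preferential minutes and relabels delayed logs", {
  # real-time logs uniform over minutes; delayed logs only at 5-min marks
  base <- as.POSIXct("2023-05-01 10:00", tz = "UTC")
  rt_min <- rep(0:59, 20)
  dl_min <- rep(c(0, 5, 15, 30, 45), 40)
  logs <- make_logs(rep("u1", length(rt_min) + length(dl_min)),
                    base + c(rt_min, dl_min) * 60, "x")
  cls <- c(rep("real_time", length(rt_min)), rep("delayed", length(dl_min)))
  rep <- detect_backlogs(logs, latency_class = cls)
  expect_setequal(rep$flagged_minutes, c(0, 5, 15, 30, 45))
  expect_equal(rep$backlog_fraction_of_delayed, 1)
  expect_equal(rep$backlog_fraction_of_all,
               rep$delayed_fraction * rep$backlog_fraction_of_delayed,
               tolerance = 1e-9)
  expect_equal(rep$chi2_df, 59)
  expect_lt(rep$p_value, 0.001)
  expect_equal(sum(rep$latency_class == "backlog"), length(dl_min))
})

test_that("identical minute distributions yield no flags and a null chi-squared", {
  base <- as.POSIXct("2023-05-01 10:00", tz = "UTC")
  mins <- rep(0:59, 10)
  logs <- make_logs(rep("u1", 2 * length(mins)), base + c(mins, mins) * 60, "x")
  cls <- rep(c("real_time", "delayed"), each = length(mins))
  rep <- detect_backlogs(logs, latency_class = cls)
  expect_length(rep$flagged_minutes, 0)
  expect_gt(rep$p_value, 0.99)
  expect_equal(rep$backlog_fraction_of_all, 0)
})

test_that("no delayed logs gives a zero report without a test", {
  logs <- make_logs("u1", "2023-05-01 10:00", "x")
  rep <- detect_backlogs(logs, latency_class = "real_time")
  expect_equal(rep$delayed_fraction, 0)
  expect_length(rep$flagged_minutes, 0)
  expect_true(is.na(rep$chi2_stat))
})

test_that("day compliance needs two occasions and a 5-hour span, water excluded", {
  expect_true(is_compliant_day(c(240, 900)))          # 08:00 and 19:00
  expect_false(is_compliant_day(c(240, 420)))         # 08:00 and 11:00: 3 h
  expect_false(is_compliant_day(720))                 # single caloric log
  # one caloric log + water logs: water never reaches the caloric set
  items <- make_items("u1", rep("2023-05-01", 4), c(240, 300, 600, 900),
                      item_type = c("food", "water", "water", "water"))
  days <- compliance_days(items)
  expect_false(days$compliant)
  expect_equal(days$n_caloric_logs, 1)
})

test_that("two caloric logs 5 h apart but within one occasion-merge never happen;
           occasions are the unit of the two-event rule", {
  # 300-minute span with a chain of logs every 10 min forms one occasion
  minutes <- seq(240, 540, by = 10)
  expect_false(is_compliant_day(minutes))
  # same span with a 15-min break forms two occasions
  expect_true(is_compliant_day(c(seq(240, 400, 10), seq(420, 540, 10))))
})

test_that("eligibility needs 10 compliant of the first 14 days and is monotone", {
  mk <- function(n_compliant, n_days = 14) {
    dates <- as.Date("2023-05-01") + seq_len(n_days) - 1
    mins <- lapply(seq_len(n_days), function(d)
      if (d <= n_compliant) c(240, 900) else 720)
    make_items("u1", rep(dates, lengths(mins)), unlist(mins))
  }
  for (nc in c(9, 10, 14)) {
    elig <- eligible_participants(compliance_days(mk(nc)))
    expect_equal(elig$eligible, nc >= 10, info = paste("compliant days:", nc))
  }
  # monotone: upgrading a non-compliant day cannot revoke eligibility
  base <- eligible_participants(compliance_days(mk(10)))$eligible
  more <- eligible_participants(compliance_days(mk(11)))$eligible
  expect_true(more >= base)
  # days beyond the first-14 horizon are ignored
  late <- mk(9)
  extra <- make_items("u1", rep(as.Date("2023-05-20"), 2), c(240, 900))
  extra$log_id <- extra$log_id + 100
  elig <- eligible_participants(compliance_days(dplyr::bind_rows(late, extra)))
  expect_false(elig$eligible)
})

test_that("non-descriptive filtering strips phrases and drops users left ineligible", {
  dates <- as.Date("2023-05-01") + 0:13
  good <- make_items("u1", rep(dates, each = 2), rep(c(300, 900), 14),
                     name = rep(c("coffee", "salad"), 14))
  generic <- make_items("u2", rep(dates, each = 2), rep(c(300, 900), 14),
                        name = "meal")
  items <- dplyr::bind_rows(good, generic)
  res <- filter_nondescriptive(items)
  expect_equal(res$dropped_participants, "u2")
  expect_setequal(unique(res$items$participant_id), "u1")
  # empty exclusion list is the identity
  res2 <- filter_nondescriptive(items, nondescriptive = character(0))
  expect_identical(res2$items, items)
})
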