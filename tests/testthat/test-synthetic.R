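test_that("generation is deterministic given the seed", {
  a <- generate_cohort(synthetic_config(n_users = 20), seed = 3)
  b <- generate_cohort(synthetic_config(n_users = 20), seed = 3)
  expect_identical(a$logs, b$logs)
  expect_identical(a$truth$users, b$truth$users)
  c <- generate_cohort(synthetic_config(n_users = 20), seed = 4)
  expect_false(identical(a$logs$raw_text, c$logs$raw_text))
})

test_that("unknown config keys and infeasible windows are rejected", {
  expect_error(synthetic_config(not_a_key = 1), "unknown config key")
  expect_error(generate_cohort(synthetic_config(n_users = 5, length_base = 100,
                                                min_length = 90,
                                                min_day_span = 300), seed = 1),
               "infeasible")
})

test_that("the degenerate zero-jitter cohort recovers its fixed window", {
  cfg <- synthetic_config(n_users = 40, start_sd = 0, length_sd = 0,
                          jitter_first_sd = 0, jitter_last_sd = 0,
                          start_mean = 240, length_base = 720,
                          length_slope = 0, age_start_effect = 0,
                          age_length_effect = 0,
                          work_start_shift = stats::setNames(
                            rep(0, 8), names(synthetic_config()$work_probs)),
                          work_jitter_mult = stats::setNames(
                            rep(1, 8), names(synthetic_config()$work_probs)),
                          events_per_day_lambda = 8)
  cohort <- generate_cohort(cfg, seed = 6)
  m <- participant_metrics(cohort$truth$parsed_items)
  expect_equal(nrow(m), 40)
  expect_true(all(m$first_shift_min == 0))
  expect_true(all(m$last_shift_min == 0))
  # every day spans exactly [240, 960]; the 2.5/97.5 percentiles sit within
  expect_true(all(m$avg_window_min == 720))
  expect_true(all(m$p95_window_min <= 720))
  expect_gt(mean(m$p95_window_min), 0.9 * 720)
})

test_that("generated cohorts are fully compliant under default conditions", {
  cohort <- small_cohort()
  days <- compliance_days(cohort$truth$parsed_items)
  expect_true(all(days$compliant))
  elig <- eligible_participants(days)
  expect_true(all(elig$eligible))
  expect_equal(nrow(elig), 60)
})

test_that("noise-free logs parse back to their ground-truth items", {
  cohort <- small_cohort()   # typo and non-descriptive rates are zero
  parsed <- parse_logs(cohort$logs)
  expect_gt(parsed$coverage, 0.99)
  got <- dplyr::count(dplyr::filter(parsed$items, .data$caloric),
                      .data$participant_id, .data$log_id, .data$name)
  want <- dplyr::count(cohort$truth$parsed_items,
                       .data$participant_id, .data$log_id, .data$name)
  joined <- dplyr::full_join(want, got,
                             by = c("participant_id", "log_id", "name"),
                             suffix = c("_want", "_got"))
  frac_exact <- mean(!is.na(joined$n_want) & !is.na(joined$n_got) &
                       joined$n_want == joined$n_got)
  expect_gt(frac_exact, 0.99)
})

test_that("injected latency classes follow the configured decomposition", {
  cohort <- default_cohort()
  tl <- cohort$truth$logs
  cls <- classify_log_latency(cohort$logs)
  # strict latency classes: delayed iff injected delay > 15 min
  expect_equal(mean(cls == "delayed"),
               mean(tl$latency_class != "real_time"), tolerance = 1e-9)
  # injected on-mark share among delayed approximates the target
  delayed <- tl$latency_class != "real_time"
  expect_equal(mean(tl$latency_class[delayed] == "backlog"), 0.4149,
               tolerance = 0.05)
})

test_that("expected statistics attach closed forms and honest standard errors", {
  cfg <- synthetic_config(work_probs = c(regular = 1, morning_shift = 0,
                                         evening_shift = 0, night_shift = 0,
                                         rotating_shift = 0, flexible = 0,
                                         long_hours = 0, unknown = 0))
  es <- expected_statistics(cfg, n_rep = 200, seed = 2)
  expect_equal(es$closed_form$first_shift, 2 * cfg$jitter_first_sd / sqrt(pi))
  expect_equal(es$closed_form$last_shift, 2 * cfg$jitter_last_sd / sqrt(pi))
  # the simulated mean shift agrees with the closed form within 5%
  expect_equal(unname(es$first_shift["mean"]), es$closed_form$first_shift,
               tolerance = 0.05)
  expect_equal(unname(es$last_shift["mean"]), es$closed_form$last_shift,
               tolerance = 0.05)
  expect_true(all(c(es$tf50["se"], es$p95_duration["se"]) > 0))
})
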