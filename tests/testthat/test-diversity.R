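oracle_dense_rank <- function(counts) {
  u <- sort(unique(counts), decreasing = TRUE)
  match(counts, u)
}
oracle_coverage <- function(counts, fraction) {
  nm <- names(counts)
  ord <- order(-counts, nm)
  s <- counts[ord]
  for (k in seq_along(s)) {
    if (sum(s[seq_len(k)]) / sum(s) >= fraction - 1e-12) return(k)
  }
  length(s)
}

test_that("diversity counts unique caloric items cumulatively, with exclusions", {
  dates <- as.Date("2023-05-01") + c(0, 0, 0, 1, 1, 2)
  items <- make_items("u1", dates, c(300, 500, 900, 300, 900, 600),
                      name = c("coffee", "egg", "salad", "coffee", "salt", "pasta"))
  div <- user_diversity(items, nondescriptive = character(0),
                        ingredients = "salt", n_days = 14)
  expect_equal(div$day_01, 3)                 # coffee, egg, salad
  expect_equal(div$day_02, 3)                 # salt excluded, coffee repeated
  expect_equal(div$day_03, 4)
  expect_equal(div$final_diversity, 4)
  expect_true(all(diff(as.numeric(div[1, paste0("day_", sprintf("%02d", 1:14))])) >= 0))
})

test_that("repeated logging of one item counts once", {
  items <- make_items("u1", rep("2023-05-01", 10), seq(300, 390, 10),
                      name = "coffee")
  expect_equal(user_diversity(items, character(0), character(0))$final_diversity, 1)
})

test_that("item popularity is the percentage of users logging the item", {
  items <- dplyr::bind_rows(
    make_items("u1", "2023-05-01", 300, name = "coffee"),
    make_items("u2", "2023-05-01", 300, name = "coffee"),
    make_items("u3", "2023-05-01", 300, name = "coffee"),
    make_items("u4", "2023-05-01", 300, name = "tea"))
  pop <- item_popularity(items)
  expect_equal(pop$popularity_pct[pop$name == "coffee"], 75)
  expect_equal(pop$popularity_pct[pop$name == "tea"], 25)
  expect_false("never_logged" %in% pop$name)
  expect_equal(pop$rank, seq_len(nrow(pop)))
})

test_that("habituality needs min_users consumers with min_days distinct days", {
  mk_user <- function(uid, n_days, per_day = 1) {
    dates <- rep(as.Date("2023-05-01") + seq_len(n_days) - 1, each = per_day)
    make_items(uid, dates, rep(600, length(dates)), name = "coffee")
  }
  cohort7 <- dplyr::bind_rows(lapply(sprintf("u%03d", 1:100), mk_user, n_days = 7))
  expect_equal(habitual_items(cohort7, min_users = 100)$name, "coffee")
  cohort99 <- dplyr::bind_rows(lapply(sprintf("u%03d", 1:99), mk_user, n_days = 7))
  expect_equal(nrow(habitual_items(cohort99, min_users = 100)), 0)
  # 14 logs on a single day is one distinct day, not habitual
  burst <- dplyr::bind_rows(lapply(sprintf("u%03d", 1:100), mk_user,
                                   n_days = 1, per_day = 14))
  expect_equal(nrow(habitual_items(burst, min_users = 100)), 0)
})

test_that("dense ranking ties share ranks and agree with the sort oracle", {
  expect_equal(dense_ranks(c(A = 5, B = 3, C = 3, D = 1)), c(1L, 2L, 2L, 3L))
  expect_equal(dense_ranks(c(2, 2, 2)), rep(1L, 3))
  set.seed(5)
  for (i in 1:300) {
    x <- sample.int(20, sample(1:30, 1), replace = TRUE)
    expect_equal(dense_ranks(x), oracle_dense_rank(x))
  }
})

test_that("coverage counts match the prefix-sum oracle and are monotone", {
  counts <- c(A = 6, B = 2, C = 1, D = 1)
  expect_equal(coverage_count(counts, 0.5), 1)
  expect_equal(coverage_count(counts, 0.9), 3)
  expect_equal(coverage_count(counts, 1), 4)
  expect_error(coverage_count(numeric(0), 0.5), "undefined")
  set.seed(6)
  for (i in 1:300) {
    n <- sample(1:25, 1)
    x <- stats::setNames(sample.int(15, n, replace = TRUE),
                         paste0("i", seq_len(n)))
    f1 <- runif(1, 0.05, 0.95); f2 <- min(1, f1 + runif(1, 0, 0.5))
    expect_equal(coverage_count(x, f1), oracle_coverage(x, f1))
    expect_lte(coverage_count(x, f1), coverage_count(x, f2))
  }
})

test_that("novel items are consumed later than habitual items in the generated cohort", {
  items <- default_cohort()$truth$parsed_items
  fam <- timing_by_familiarity(items, min_users = 10)
  expect_gt(fam$n_habitual_logs, 0)
  expect_gt(fam$n_novel_logs, 0)
  expect_gt(fam$median_diff_min, 0)
  expect_equal(sum(fam$habitual$fraction), 1)
  expect_equal(sum(fam$novel$fraction), 1)
})
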