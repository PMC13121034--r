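oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}
# independent JSD via the entropy identity JS = H(m) - (H(p) + H(q)) / 2
oracle_jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q); m <- (p + q) / 2
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  sqrt(H(m) - (H(p) + H(q)) / 2)
}

test_that("decile assignment partitions users with the remainder rule", {
  b <- decile_assign(rnorm(20))
  expect_equal(as.integer(table(b)), rep(2L, 10))
  # 21,006 users: remainder 6 -> six bins of 2,101 and four of 2,100
  sizes <- as.integer(table(decile_assign(seq_len(21006))))
  expect_equal(sizes, c(rep(2101L, 6), rep(2100L, 4)))
  expect_equal(sum(sizes), 21006L)
  # all-equal values still balance via the stable tie-break
  expect_equal(as.integer(table(decile_assign(rep(1, 25)))),
               rep(c(3L, 2L), c(5, 5)))
  expect_error(decile_assign(1:5), "at least 10")
})

test_that("decile tables recombine to cohort statistics", {
  set.seed(7)
  x <- rnorm(1003)
  tab <- decile_table(x)
  expect_equal(sum(tab$n), length(x))
  expect_equal(sum(tab$n * tab$mean) / sum(tab$n), mean(x), tolerance = 1e-9)
  expect_true(all(diff(tab$median) >= 0))
})

test_that("start-time percentiles expose the start-vs-length association", {
  m <- participant_metrics(default_cohort()$truth$parsed_items)
  pct <- start_time_percentiles(m, n_bins = 20)
  expect_equal(sum(pct$n), nrow(m))
  # negative start-length association: decreasing trend of mean duration
  trend <- stats::cor(pct$bin, pct$mean_window_min, method = "spearman")
  expect_lt(trend, -0.5)
  expect_lt(stats::cor(m$p95_start_minute, m$p95_window_min), 0)
})

test_that("jsd matches hand values and the entropy-identity oracle", {
  expect_equal(jsd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  expect_equal(jsd(c(1, 0), c(0.5, 0.5)), 0.5579230, tolerance = 1e-6)
  expect_error(jsd(c(0, 0), c(1, 0)), "zero-sum")
  set.seed(8)
  for (i in 1:100) {
    p <- runif(6); q <- runif(6)
    expect_equal(jsd(p, q), oracle_jsd(p, q), tolerance = 1e-12)
    expect_equal(jsd(p, q), jsd(q, p))                     # symmetry
    r <- runif(6)                                          # metric spot-check
    expect_lte(jsd(p, q), jsd(p, r) + jsd(r, q) + 1e-12)
    expect_gte(jsd(p, q), 0); expect_lte(jsd(p, q), 1)
  }
})

test_that("permutation test is deterministic, label-symmetric and bounded below", {
  set.seed(9)
  inc <- matrix(rbinom(40 * 25, 1, 0.3), 40, 25,
                dimnames = list(paste0("u", 1:40), paste0("i", 1:25)))
  lab <- rep(c("a", "b"), each = 20)
  r1 <- jsd_permutation_test(inc, lab, B = 99, seed = 4)
  r2 <- jsd_permutation_test(inc, lab, B = 99, seed = 4)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- jsd_permutation_test(inc, rev(lab), B = 99, seed = 4)
  expect_equal(r3$observed, r1$observed)
  expect_gte(r1$p_value, 1 / 100)
  expect_error(jsd_permutation_test(inc, rep("a", 40), B = 9), "two levels")
})

test_that("a fully extreme observation attains p = 1/(B+1)", {
  # two groups with disjoint item repertoires: observed JSD = 1,
  # unbeatable by any label permutation
  inc <- cbind(matrix(rep(c(1L, 0L), each = 20), 40, 10),
               matrix(rep(c(0L, 1L), each = 20), 40, 10))
  rownames(inc) <- paste0("u", 1:40); colnames(inc) <- paste0("i", 1:20)
  lab <- rep(c("a", "b"), each = 20)
  res <- jsd_permutation_test(inc, lab, B = 1000, seed = 10)
  expect_equal(res$observed, 1)
  expect_equal(res$p_value, 1 / 1001)
})

test_that("two-group tests report U, p and Cliff's delta consistent with oracles", {
  set.seed(11)
  for (i in 1:50) {
    a <- sample.int(30, sample(3:12, 1), replace = TRUE)
    b <- sample.int(30, sample(3:12, 1), replace = TRUE)
    res <- group_difference_tests(c(a, b), rep(c("A", "B"), c(length(a), length(b))))
    u <- oracle_u(a, b)
    expect_equal(res$U, u)
    expect_equal(res$cliffs_delta, 2 * u / (length(a) * length(b)) - 1)
  }
  same <- group_difference_tests(c(1:8, 1:8), rep(c("A", "B"), each = 8))
  expect_equal(same$cliffs_delta, 0)
  sep <- group_difference_tests(c(11:15, 1:5), rep(c("A", "B"), each = 5))
  expect_equal(abs(sep$cliffs_delta), 1)
  expect_error(group_difference_tests(1:3, c("A", "A", "B")), "n >= 2")
})

test_that("paired and multi-group contracts hold", {
  set.seed(12)
  x <- rnorm(30); y <- x + rnorm(30, 0.5)
  pr <- group_difference_tests(x, paired_with = y)
  expect_equal(pr$method, "wilcoxon_signed_rank")
  expect_true(abs(pr$rank_biserial) <= 1)
  g <- rep(c("a", "b", "c"), each = 15)
  v <- rnorm(45) + rep(c(0, 0, 2), each = 15)
  mg <- group_difference_tests(v, g)
  expect_equal(mg$method, "kruskal_wallis")
  expect_equal(nrow(mg$pairwise), 3)
  # the shifted group should separate after Holm adjustment
  sig <- mg$pairwise$p_adjusted[mg$pairwise$group2 == "c" |
                                  mg$pairwise$group1 == "c"]
  expect_true(all(sig < 0.05))
  expect_true(all(mg$pairwise$p_adjusted >= mg$pairwise$p_value))
})

test_that("rank changes are zero for identical groups and signed for swaps", {
  items <- dplyr::bind_rows(
    make_items("u1", "2023-05-01", c(300, 400), name = c("coffee", "tea")),
    make_items("u2", "2023-05-01", c(300, 400), name = c("coffee", "tea")),
    make_items("u3", "2023-05-01", c(300, 400), name = c("coffee", "egg")))
  same <- rank_change_table(items, list(A = c("u1", "u2", "u3"),
                                        B = c("u1", "u2", "u3")), top_k = 3)
  expect_true(all(same$shift == 0))
  # u3 lacks tea; group B = {u3} has egg above tea
  ab <- rank_change_table(items, list(A = c("u1", "u2"), B = "u3"), top_k = 3)
  expect_true(any(ab$shift != 0))
  expect_equal(ab$missing_in[ab$name == "egg"], "A")
})

test_that("decile membership association contract (chi-squared)", {
  set.seed(13)
  v <- rnorm(200)
  f <- sample(c("x", "y"), 200, replace = TRUE)
  res <- decile_association(v, f)
  expect_s3_class(res, "htest")
  expect_equal(unname(res$parameter), 9)
})
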