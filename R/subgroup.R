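#' Assign users to decile (or percentile) bins
#'
#' Ranks values ascending and splits users into `n_bins` near-equal bins.
#' With remainder r, the lowest r bins get one extra user; ties keep the
#' incoming (user id) order so the assignment is reproducible.
#'
#' @param values numeric metric values, one per user.
#' @param n_bins number of bins (10 for deciles, 100 for percentiles).
#' @return integer bin index per user (1 = lowest values).
#' @export
decile_assign <- function(values, n_bins = 10) {
  n <- length(values)
  if (n < n_bins) stop("need at least ", n_bins, " users for ", n_bins, " bins")
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  bins <- rep(seq_len(n_bins), times = sizes)
  out <- integer(n)
  out[order(values)] <- bins   # stable sort: ties keep input order
  out
}

#' Per-bin summary table for a metric
#'
#' The decile-table structure used for cohort metrics: per bin n, mean,
#' s.d., median, IQR and 2.5th/97.5th percentiles. Bins partition the
#' users, so the per-bin means recombine (weighted by n) to the cohort
#' mean.
#'
#' @param values numeric metric values.
#' @param n_bins number of bins (default 10).
#' @return tibble with one row per bin.
#' @export
decile_table <- function(values, n_bins = 10) {
  bin <- decile_assign(values, n_bins)
  out <- tibble::tibble(value = values, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
      median = stats::median(.data$value), iqr = stats::IQR(.data$value),
      p2.5 = stats::quantile(.data$value, 0.025, names = FALSE),
      p97.5 = stats::quantile(.data$value, 0.975, names = FALSE),
      .groups = "drop")
  tibble::as_tibble(out)
}

#' Window length by start-time percentile
#'
#' Orders users by the start of their 95% eating window, bins them into
#' percentiles, and reports the mean and s.d. of window duration (and of
#' start time) per bin, exposing the start-vs-length association. With
#' fewer than `n_bins` users a coarser binning is used with a warning.
#'
#' @param metrics a [participant_metrics()] table.
#' @param n_bins number of bins (default 100).
#' @return tibble per bin: `bin`, `n`, `mean_start_minute`,
#'   `sd_start_minute`, `mean_window_min`, `sd_window_min`.
#' @export
start_time_percentiles <- function(metrics, n_bins = 100) {
  n <- nrow(metrics)
  if (n < n_bins) {
    n_bins <- max(1L, n %/% 2L)
    warning("fewer users than bins; using ", n_bins, " bins")
  }
  bin <- decile_assign(metrics$p95_start_minute, n_bins)
  out <- metrics |>
    dplyr::mutate(bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_start_minute = mean(.data$p95_start_minute),
                     sd_start_minute = stats::sd(.data$p95_start_minute),
                     mean_window_min = mean(.data$p95_window_min),
                     sd_window_min = stats::sd(.data$p95_window_min),
                     .groups = "drop")
  tibble::as_tibble(out)
}

#' Rank changes of top items between two groups
#'
#' Ranks the globally top-K items within each group by within-group
#' popularity (ties by total logs then name) and reports the signed shift
#' `rank_in_B - rank_in_A` (positive = preferred by / climbed for group
#' A). An item never logged by a group takes rank K + 1 and is flagged.
#' Shifts with magnitude above 10 are classed as substantial.
#'
#' @param parsed_items parsed-item tibble for the whole cohort.
#' @param groups named list of two character vectors of participant ids
#'   (`list(A = ..., B = ...)`).
#' @param top_k number of globally top items to track (default 100).
#' @return tibble per item: `name`, `rank_A`, `rank_B`, `shift`,
#'   `substantial`, `missing_in`.
#' @export
rank_change_table <- function(parsed_items, groups, top_k = 100) {
  stopifnot(length(groups) == 2)
  glob <- item_popularity(parsed_items)
  top <- utils::head(glob$name, top_k)
  rank_in <- function(ids) {
    sub <- dplyr::filter(parsed_items, .data$participant_id %in% ids,
                         .data$name %in% top)
    pop <- item_popularity(sub, n_users = length(ids))
    # rank among the top-K only, missing items -> K + 1
    r <- stats::setNames(rep(top_k + 1L, length(top)), top)
    pop <- dplyr::filter(pop, .data$name %in% top)
    r[pop$name] <- seq_len(nrow(pop))
    r
  }
  rA <- rank_in(groups[[1]]); rB <- rank_in(groups[[2]])
  tibble::tibble(
    name = top,
    rank_A = as.integer(rA[top]), rank_B = as.integer(rB[top]),
    shift = as.integer(rB[top] - rA[top])) |>
    dplyr::mutate(substantial = abs(.data$shift) > 10,
                  missing_in = dplyr::case_when(
                    .data$rank_A > top_k & .data$rank_B > top_k ~ "both",
                    .data$rank_A > top_k ~ names(groups)[1],
                    .data$rank_B > top_k ~ names(groups)[2],
                    TRUE ~ ""))
}

#' Jensen-Shannon distance
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms, so
#' the distance is a metric bounded in `[0, 1]` (0 iff the distributions
#' are equal, 1 for disjoint supports). Inputs are normalised to sum to 1;
#' zero-sum vectors are an error.
#'
#' @param p,q non-negative numeric vectors on the same support.
#' @return JSD in `[0, 1]`.
#' @export
jsd <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (sum(p) == 0 || sum(q) == 0) stop("jsd undefined for zero-sum vectors")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d2 <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(d2, 0))
}

#' Group popularity vectors over a set of items
#'
#' The per-group item popularity distribution used for JSD: the fraction
#' of the group's users that logged each item, restricted to `items`
#' (typically the global top-100) and renormalised. `items = NULL` uses
#' the full vocabulary.
#'
#' @param incidence binary user x item matrix (rownames = participant
#'   ids, colnames = item names).
#' @param ids participant ids of the group.
#' @param items item names to keep (`NULL` = all).
#' @return numeric popularity vector (not yet normalised).
#' @keywords internal
group_popularity <- function(incidence, ids, items = NULL) {
  sub <- incidence[rownames(incidence) %in% ids, , drop = FALSE]
  pop <- colMeans(sub)
  if (!is.null(items)) pop <- pop[items]
  pop
}

#' Build a binary user-by-item incidence matrix
#'
#' @param parsed_items parsed-item tibble.
#' @param items restrict to these item names (`NULL` = all caloric
#'   items).
#' @return binary matrix, rownames participant ids, colnames item names.
#' @export
incidence_matrix <- function(parsed_items, items = NULL) {
  cal <- dplyr::filter(parsed_items, .data$caloric)
  if (!is.null(items)) cal <- dplyr::filter(cal, .data$name %in% items)
  users <- sort(unique(cal$participant_id))
  nms <- if (is.null(items)) sort(unique(cal$name)) else items
  m <- matrix(0L, length(users), length(nms), dimnames = list(users, nms))
  pairs <- dplyr::distinct(cal, .data$participant_id, .data$name)
  m[cbind(match(pairs$participant_id, users), match(pairs$name, nms))] <- 1L
  m
}

#' Permutation test for subgroup JSD
#'
#' Observed statistic: JSD between the two groups' item-popularity
#' distributions (fraction of users logging each item, renormalised).
#' Null distribution: group labels shuffled `B` times. One-sided p-value
#' `(1 + #{perm >= observed}) / (B + 1)`, so a fully extreme observation
#' at B = 1000 gives p = 1/1001 ~ 0.001 and the minimum attainable p is
#' `1/(B+1)`.
#'
#' @param incidence binary user x item matrix ([incidence_matrix()]).
#' @param labels logical or two-level vector over the matrix rows.
#' @param B number of permutations (default 1000).
#' @param seed RNG seed for reproducibility (optional).
#' @return list: `observed` JSD, `p_value`, `B`, `null` (permutation
#'   JSDs).
#' @export
jsd_permutation_test <- function(incidence, labels, B = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  g <- labels == levels(labels)[1]
  if (all(g) || !any(g)) stop("degenerate single-group labels")
  stat <- function(grp) {
    p <- colMeans(incidence[grp, , drop = FALSE])
    q <- colMeans(incidence[!grp, , drop = FALSE])
    if (sum(p) == 0 || sum(q) == 0) return(NA_real_)
    jsd(p, q)
  }
  observed <- stat(g)
  null <- vapply(seq_len(B), function(i) stat(sample(g)), numeric(1))
  p <- (1 + sum(null >= observed, na.rm = TRUE)) / (B + 1)
  list(observed = observed, p_value = p, B = B, null = null)
}

#' Cliff's delta
#'
#' Nonparametric effect size for a two-group comparison: the probability
#' that a value from A exceeds one from B minus the reverse; -1/0/1 for
#' full separation/overlap/full separation the other way.
#'
#' @param a,b numeric vectors.
#' @return delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a); n2 <- length(b)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for a
  2 * u / (n1 * n2) - 1
}

#' Nonparametric group-difference test contracts
#'
#' Two-group: Mann-Whitney rank-sum (two-sided) with Cliff's delta.
#' Paired: Wilcoxon signed-rank with the rank-biserial correlation.
#' Multi-group: Kruskal-Wallis omnibus followed by Dunn's pairwise z
#' tests on mean ranks with Holm adjustment.
#'
#' @param values numeric vector (or, paired, the first measurement).
#' @param groups group labels aligned with `values` (ignored when
#'   `paired_with` is given).
#' @param paired_with second measurement for the paired design.
#' @return a list with `method`, the test statistic(s), `p_value`(s) and
#'   effect size(s); multi-group results include a `pairwise` tibble.
#' @export
group_difference_tests <- function(values, groups = NULL, paired_with = NULL) {
  if (!is.null(paired_with)) {
    stopifnot(length(values) == length(paired_with))
    if (length(values) < 2) stop("need at least 2 pairs")
    w <- stats::wilcox.test(values, paired_with, paired = TRUE, exact = FALSE)
    d <- values - paired_with
    d <- d[d != 0]
    r <- rank(abs(d))
    rb <- (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)   # rank-biserial
    return(list(method = "wilcoxon_signed_rank", statistic = unname(w$statistic),
                p_value = w$p.value, rank_biserial = rb))
  }
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  if (nlevels(groups) == 2) {
    a <- values[groups == levels(groups)[1]]
    b <- values[groups == levels(groups)[2]]
    w <- stats::wilcox.test(a, b, exact = FALSE)
    list(method = "mann_whitney", U = unname(w$statistic), p_value = w$p.value,
         cliffs_delta = cliffs_delta(a, b))
  } else {
    kw <- stats::kruskal.test(values, groups)
    list(method = "kruskal_wallis", statistic = unname(kw$statistic),
         df = unname(kw$parameter), p_value = kw$p.value,
         pairwise = dunn_pairwise(values, groups))
  }
}

# Dunn's pairwise post-hoc z tests on mean ranks with a tie correction,
# Holm-adjusted.
dunn_pairwise <- function(values, groups, adjust = "holm") {
  groups <- as.factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  res <- apply(combs, 2, function(pr) {
    i <- groups == pr[1]; j <- groups == pr[2]
    ni <- sum(i); nj <- sum(j)
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  tibble::tibble(group1 = combs[1, ], group2 = combs[2, ],
                 z = res["z", ], p_value = res["p", ],
                 p_adjusted = stats::p.adjust(res["p", ], method = adjust))
}

#' Decile-membership association with a demographic factor
#'
#' Chi-squared test of independence between decile membership for a
#' metric and a categorical demographic variable.
#'
#' @param values metric values.
#' @param factor_var categorical variable aligned with `values`.
#' @param n_bins bins for [decile_assign()] (default 10).
#' @return `htest` from [stats::chisq.test()].
#' @export
decile_association <- function(values, factor_var, n_bins = 10) {
  stats::chisq.test(table(decile_assign(values, n_bins), factor_var))
}
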