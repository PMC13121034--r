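#' Diurnal consumption profiles for top items
#'
#' Builds, for each requested item, its normalised 96-bin (15-minute)
#' time-of-day consumption profile over the 04:00-anchored day. Profiles
#' are per-item normalised (bins sum to 1) so popular items do not
#' dominate distances; `normalization = "raw_counts"` keeps counts.
#' Items with zero logs are excluded with a warning.
#'
#' @param parsed_items parsed-item tibble.
#' @param items item names to profile (e.g. the top-100 by popularity).
#' @param bin_min bin width in minutes (default 15; 96 bins).
#' @param normalization `"fraction_of_item"` or `"raw_counts"`.
#' @return numeric matrix, one row per item, `1440 / bin_min` columns.
#' @export
build_profiles <- function(parsed_items, items, bin_min = 15,
                           normalization = c("fraction_of_item", "raw_counts")) {
  normalization <- match.arg(normalization)
  cal <- dplyr::filter(parsed_items, .data$caloric, .data$name %in% items)
  nb <- DAY_MINUTES %/% bin_min
  prof <- matrix(0, length(items), nb, dimnames = list(items, NULL))
  for (i in seq_along(items)) {
    m <- cal$minute_of_day[cal$name == items[i]]
    prof[i, ] <- binned_distribution(m, bin_min)[[
      if (normalization == "fraction_of_item") "fraction" else "count"]]
  }
  empty <- rowSums(prof) == 0
  if (any(empty)) {
    warning("excluding ", sum(empty), " item(s) with no logs: ",
            paste(utils::head(items[empty], 5), collapse = ", "))
    prof <- prof[!empty, , drop = FALSE]
  }
  prof
}

#' Hierarchically cluster diurnal profiles
#'
#' Agglomerative clustering of per-item profile vectors, tree cut at `k`
#' clusters. Default distance is correlation distance (1 - Pearson
#' correlation between profiles), which captures profile shape over
#' amplitude; default linkage is Ward (`"ward.D2"`), which resists the
#' outlier chaining that average linkage shows on noisy binned profiles
#' (average linkage remains available). Cluster labels are relabelled by
#' pooled TF50 ascending (cluster 1 = earliest), making the partition
#' reproducible and order-invariant.
#'
#' @param profiles matrix from [build_profiles()].
#' @param parsed_items parsed-item tibble (for pooled cluster TF50s).
#' @param k number of clusters (default 5).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage any [stats::hclust()] method (default `"ward.D2"`).
#' @param bin_min bin width used for the profiles.
#' @return list: `labels` (named integer vector, 1..k by ascending pooled
#'   TF50), `tree` (`hclust`), `summary` tibble (per cluster: size,
#'   pooled TF50 in day minutes and as clock time).
#' @export
cluster_profiles <- function(profiles, parsed_items, k = 5,
                             distance = c("correlation", "euclidean"),
                             linkage = "ward.D2", bin_min = 15) {
  distance <- match.arg(distance)
  if (k > nrow(profiles)) stop("k exceeds the number of profiled items")
  d <- if (distance == "correlation") {
    stats::as.dist(1 - stats::cor(t(profiles)))
  } else {
    stats::dist(profiles)
  }
  tree <- stats::hclust(d, method = linkage)
  raw_labels <- stats::cutree(tree, k = k)

  cal <- dplyr::filter(parsed_items, .data$caloric,
                       .data$name %in% rownames(profiles))
  cal$cluster_raw <- raw_labels[cal$name]
  pooled <- cal |>
    dplyr::group_by(.data$cluster_raw) |>
    dplyr::summarise(tf50_minute = stats::median(.data$minute_of_day),
                     .groups = "drop") |>
    dplyr::arrange(.data$tf50_minute)
  relabel <- stats::setNames(seq_len(k), pooled$cluster_raw)
  labels <- stats::setNames(as.integer(relabel[as.character(raw_labels)]),
                            names(raw_labels))
  summary <- tibble::tibble(
    cluster = seq_len(k),
    n_items = as.integer(table(labels)[as.character(seq_len(k))]),
    tf50_minute = pooled$tf50_minute,
    tf50_hhmm = minute_to_hhmm(pooled$tf50_minute))
  list(labels = labels, tree = tree, summary = summary)
}

#' Pooled TF50 and cumulative consumption curve of one cluster
#'
#' @param parsed_items parsed-item tibble.
#' @param member_items item names in the cluster.
#' @param bin_min curve resolution in minutes (default 15).
#' @return list: `tf50_minute`, `n_logs`, and `curve` (tibble
#'   `bin_start`, `cumulative_fraction`, monotone from 0 to 1).
#' @export
cluster_summary <- function(parsed_items, member_items, bin_min = 15) {
  cal <- dplyr::filter(parsed_items, .data$caloric,
                       .data$name %in% member_items)
  if (nrow(cal) == 0) stop("cluster has no logs")
  dist <- binned_distribution(cal$minute_of_day, bin_min)
  list(tf50_minute = stats::median(cal$minute_of_day),
       n_logs = nrow(cal),
       curve = tibble::tibble(bin_start = dist$bin_start,
                              cumulative_fraction = cumsum(dist$fraction)))
}
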