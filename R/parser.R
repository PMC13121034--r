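#' Free-text food-log parsing
#'
#' A deterministic text-processing pipeline turning a natural-language log
#' ("latte, croissant and leftover pizza") into typed canonical items. A
#' log is split at commas into sub-logs; each sub-log is lowercased,
#' stripped of punctuation, stopwords, standalone numbers and measurement
#' tokens, plural-stemmed, spell-corrected against the typo map, joined
#' words are split ("blueberrymuffin" -> "blueberry muffin"), and the
#' remaining tokens are matched greedily (longest phrase first, left to
#' right) against the typed dictionary. Modifiers and dictionary stopwords
#' are matched and discarded; an item is "caloric" iff its type is food or
#' beverage (water, medication and selfcare items are never caloric).
#'
#' @name food-parsing
#' @keywords internal
NULL

# Common English stopwords removed before matching; configurable via the
# `stopwords` argument of parse_log().
DEFAULT_STOPWORDS <- c(
  "the", "a", "an", "and", "or", "of", "with", "in", "on", "at", "to",
  "for", "is", "was", "my", "me", "i", "had", "have", "some", "few",
  "bit", "lot", "it", "then", "plus", "also", "just"
)

# Tokens that indicate amounts or measurements; removed outright.
MEASUREMENT_TOKENS <- c(
  "oz", "ounce", "g", "gram", "kg", "mg", "ml", "l", "lb", "lbs",
  "cup", "tbsp", "tsp", "tablespoon", "teaspoon", "slice", "piece",
  "serving", "glass", "bowl", "plate", "can", "bottle", "pint", "quart",
  "gallon", "handful", "scoop", "stick", "pack", "half", "quarter"
)

# Plurals that must not be stemmed (either not plurals or lexicalised).
STEM_EXCEPTIONS <- c(
  "fries", "hummus", "couscous", "grits", "asparagus", "molasses",
  "swiss", "citrus", "octopus", "species"
)

#' Split a raw log into comma-delimited sub-logs
#'
#' @param raw_text character scalar.
#' @return character vector of trimmed non-empty segments.
#' @export
split_sublogs <- function(raw_text) {
  parts <- trimws(strsplit(raw_text, ",", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' Normalise a sub-log into cleaned tokens
#'
#' Lowercases, removes special characters, drops common English stopwords
#' and measurement tokens, removes standalone numbers (numbers adjacent to
#' letters are kept as part of their token), and reduces plural forms to
#' roots ("eggs" -> "egg").
#'
#' @param sublog character scalar.
#' @param stopwords character vector of stopwords to drop.
#' @return character vector of tokens (possibly empty).
#' @export
normalize_tokens <- function(sublog, stopwords = DEFAULT_STOPWORDS) {
  x <- tolower(sublog)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  tokens <- strsplit(trimws(gsub(" +", " ", x)), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!grepl("^[0-9]+$", tokens)]       # standalone numbers
  tokens <- tokens[!(tokens %in% stopwords)]
  tokens <- tokens[!(tokens %in% MEASUREMENT_TOKENS)]
  stem_plural(tokens)
}

# Simple plural stemming: -ies -> -y, -(s|x|z|ch|sh)es -> base, -s -> base,
# guarded by an exception list and by not touching -ss/-us/-is endings.
stem_plural <- function(tokens) {
  vapply(tokens, function(w) {
    if (w %in% STEM_EXCEPTIONS || nchar(w) < 3) return(w)
    if (grepl("ies$", w) && nchar(w) > 4) return(sub("ies$", "y", w))
    if (grepl("(ches|shes|sses|xes|zes)$", w)) return(sub("es$", "", w))
    if (grepl("(ss|us|is)$", w)) return(w)
    if (grepl("s$", w)) return(sub("s$", "", w))
    w
  }, character(1), USE.NAMES = FALSE)
}

#' Correct spelling against the typo map
#'
#' @param tokens character vector of normalised tokens.
#' @param typo_dict named character vector from [load_typo_dictionary()].
#' @return tokens with known misspellings/abbreviations replaced.
#' @export
correct_spelling <- function(tokens, typo_dict) {
  if (length(tokens) == 0) return(tokens)
  hit <- tokens %in% names(typo_dict)
  tokens[hit] <- unname(typo_dict[tokens[hit]])
  tokens
}

#' Split incorrectly joined words
#'
#' A token absent from the dictionary vocabulary is split into two
#' vocabulary words when an exact two-word decomposition exists
#' ("blueberrymuffin" -> "blueberry muffin"). Among multiple
#' decompositions the one with the longest first word wins
#' (leftmost-longest). Unsplittable tokens pass through unchanged.
#'
#' @param tokens character vector.
#' @param dict a `food_dictionary` (its unigram vocabulary is used).
#' @return character vector, possibly longer than the input.
#' @export
split_joined <- function(tokens, dict) {
  if (length(tokens) == 0) return(tokens)
  out <- lapply(tokens, function(w) {
    if (exists(w, envir = dict$vocab, inherits = FALSE) || nchar(w) < 4) return(w)
    for (i in seq(nchar(w) - 1L, 1L)) {   # longest first word wins
      left <- substr(w, 1, i); right <- substr(w, i + 1, nchar(w))
      if (exists(left, envir = dict$vocab, inherits = FALSE) &&
          exists(right, envir = dict$vocab, inherits = FALSE)) {
        return(c(left, right))
      }
    }
    w
  })
  unlist(out, use.names = FALSE)
}

#' Match cleaned tokens against the typed dictionary
#'
#' Greedy longest-first matching: scanning left to right, at each position
#' the longest dictionary phrase (up to five words) starting there is
#' matched and its tokens consumed. Matched modifiers and dictionary
#' stopwords are discarded; food/beverage/water/medication/selfcare
#' matches are emitted as items under their canonical names. Tokens
#' matching nothing are reported as unmatched.
#'
#' @param tokens character vector of cleaned tokens.
#' @param dict a `food_dictionary`.
#' @return list with `items` (tibble: `name`, `item_type`, `caloric`) and
#'   `unmatched` (character vector).
#' @export
match_phrases <- function(tokens, dict) {
  n <- length(tokens)
  items_name <- character(0); items_type <- character(0)
  unmatched <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (L in seq(min(dict$max_len, n - i + 1L), 1L)) {
      phrase <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      entry <- if (exists(phrase, envir = dict$lookup, inherits = FALSE)) {
        get(phrase, envir = dict$lookup, inherits = FALSE)
      } else NULL
      if (!is.null(entry)) {
        if (!(entry$type %in% c("modifier", "stopword"))) {
          items_name <- c(items_name, entry$canonical)
          items_type <- c(items_type, entry$type)
        }
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      unmatched <- c(unmatched, tokens[i])
      i <- i + 1L
    }
  }
  list(items = tibble::tibble(name = items_name, item_type = items_type,
                              caloric = items_type %in% c("food", "beverage")),
       unmatched = unmatched)
}

#' Parse one free-text log into typed items
#'
#' Composition of [split_sublogs()], [normalize_tokens()],
#' [correct_spelling()], [split_joined()] and [match_phrases()] applied per
#' sub-log. Deterministic: identical text and dictionaries always yield the
#' identical result.
#'
#' @param raw_text character scalar (one log).
#' @param dict a `food_dictionary`.
#' @param typo_dict named character vector (may be empty).
#' @param stopwords English stopwords removed during normalisation.
#' @return list with `items` tibble (`name`, `item_type`, `caloric`),
#'   `unmatched` tokens, and `sublog_count`.
#' @export
parse_log <- function(raw_text, dict, typo_dict = character(0),
                      stopwords = DEFAULT_STOPWORDS) {
  subs <- split_sublogs(raw_text)
  items <- list(); unmatched <- character(0)
  for (s in subs) {
    tokens <- normalize_tokens(s, stopwords)
    tokens <- correct_spelling(tokens, typo_dict)
    tokens <- split_joined(tokens, dict)
    res <- match_phrases(tokens, dict)
    items[[length(items) + 1L]] <- res$items
    unmatched <- c(unmatched, res$unmatched)
  }
  items <- if (length(items) > 0) dplyr::bind_rows(items) else
    tibble::tibble(name = character(), item_type = character(), caloric = logical())
  list(items = items, unmatched = unmatched, sublog_count = length(subs))
}

#' Parse a whole log table
#'
#' Applies [parse_log()] to every row of a log table and returns one row
#' per extracted item, joined back to the log's identifiers and timing.
#' Also reports the match coverage (fraction of logs with at least one
#' matched item).
#'
#' @param logs a log table from [read_log_table()] or
#'   [generate_cohort()].
#' @param dict,typo_dict,stopwords see [parse_log()].
#' @return list with `items` (tibble: one row per parsed item, columns
#'   `participant_id`, `log_id`, `log_time`, `logical_date`,
#'   `minute_of_day`, `name`, `item_type`, `caloric`) and `coverage`
#'   (scalar in `[0, 1]`).
#' @export
parse_logs <- function(logs, dict = default_food_dictionary(),
                       typo_dict = default_typo_dictionary(),
                       stopwords = DEFAULT_STOPWORDS) {
  n <- nrow(logs)
  per_log <- vector("list", n)
  matched <- logical(n)
  for (i in seq_len(n)) {
    res <- parse_log(logs$raw_text[i], dict, typo_dict, stopwords)
    matched[i] <- nrow(res$items) > 0
    if (matched[i]) {
      per_log[[i]] <- dplyr::mutate(res$items, .log_row = i)
    }
  }
  items <- dplyr::bind_rows(per_log)
  if (nrow(items) == 0) {
    items <- tibble::tibble(.log_row = integer(), name = character(),
                            item_type = character(), caloric = logical())
  }
  keep <- c("participant_id", "log_time", "logical_date", "minute_of_day")
  keep <- intersect(keep, names(logs))
  out <- dplyr::bind_cols(
    logs[items$.log_row, keep, drop = FALSE],
    tibble::tibble(log_id = items$.log_row, name = items$name,
                   item_type = items$item_type, caloric = items$caloric)
  )
  list(items = tibble::as_tibble(out),
       coverage = if (n > 0) mean(matched) else NA_real_)
}
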