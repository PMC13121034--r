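# Shared fixtures. Expensive cohorts are generated once per test run and
# memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Mid-size cohort under default study conditions (500 users, 14 days).
default_cohort <- function() {
  cached("default_cohort", generate_cohort(synthetic_config(), seed = 101))
}

# Small noise-free-text cohort for structural/round-trip tests.
small_cohort <- function() {
  cached("small_cohort",
         generate_cohort(synthetic_config(n_users = 60, typo_rate = 0,
                                          nondescriptive_rate = 0), seed = 7))
}

# A tiny in-code dictionary for parser oracle tests.
toy_dictionary <- function() {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "phrase,type,canonical_name",
    "orange,food,",
    "juice,beverage,",
    "orange juice,beverage,",
    "muffin,food,",
    "blueberry,food,",
    "butternut,food,",
    "squash,food,",
    "butter,food,",
    "nut,food,",
    "peanut,food,",
    "egg,food,",
    "warm,modifier,",
    "nothing,stopword,",
    "tap water,water,",
    "vitamin,medication,"
  ), path)
  load_food_dictionary(path)
}

# Build a minimal log table from participant/time/text/type vectors.
make_logs <- function(participant_id, log_time, raw_text,
                      log_type = "food", server_time = log_time) {
  lt <- as.POSIXct(log_time, tz = "UTC")
  out <- tibble::tibble(participant_id = participant_id, log_time = lt,
                        server_time = as.POSIXct(server_time, tz = "UTC"),
                        raw_text = raw_text, log_type = log_type)
  dplyr::bind_cols(out, to_logical_day(out$log_time))
}

# Parsed-item-shaped rows straight from day minutes, for metric tests.
make_items <- function(participant_id, logical_date, minute_of_day,
                       name = "item", item_type = "food") {
  tibble::tibble(participant_id = participant_id,
                 logical_date = as.Date(logical_date),
                 minute_of_day = as.integer(minute_of_day),
                 log_id = seq_along(minute_of_day),
                 name = name, item_type = item_type,
                 caloric = item_type %in% c("food", "beverage"))
}
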