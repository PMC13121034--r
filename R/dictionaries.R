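#' Load a typed food dictionary
#'
#' The dictionary maps canonical phrases of one to five lowercase,
#' punctuation-free words to one of seven types: `food`, `beverage`,
#' `modifier`, `stopword`, `water`, `medication`, `selfcare`. An optional
#' third column `canonical_name` groups synonymous phrases under one
#' emitted name (e.g. "whole wheat bread" -> "bread"); when absent the
#' phrase is its own canonical name. The package ships a reduced open
#' lexicon (see [default_food_dictionary()]); the format is documented so
#' users can substitute a larger one.
#'
#' @param path CSV with columns `phrase,type[,canonical_name]`.
#' @return a `food_dictionary` object: a list with the phrase table
#'   (`tibble`), a hashed phrase lookup, the unigram vocabulary, and the
#'   maximum phrase length.
#' @export
load_food_dictionary <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  stopifnot(all(c("phrase", "type") %in% names(raw)))
  types <- c("food", "beverage", "modifier", "stopword", "water", "medication", "selfcare")
  bad <- setdiff(unique(raw$type), types)
  if (length(bad) > 0) stop("unknown dictionary type(s): ", paste(bad, collapse = ", "))
  phrase <- tolower(trimws(raw$phrase))
  nwords <- lengths(strsplit(phrase, " ", fixed = TRUE))
  if (any(nwords < 1 | nwords > 5)) stop("dictionary phrases must be 1-5 words")
  canonical <- if ("canonical_name" %in% names(raw)) {
    ifelse(is.na(raw$canonical_name) | !nzchar(trimws(raw$canonical_name)),
           phrase, tolower(trimws(raw$canonical_name)))
  } else phrase
  tab <- tibble::tibble(phrase = phrase, type = raw$type, canonical = canonical,
                        n_words = nwords)
  lookup <- new.env(parent = emptyenv(), size = nrow(tab) * 2L)
  for (i in seq_len(nrow(tab))) {
    assign(tab$phrase[i], list(type = tab$type[i], canonical = tab$canonical[i]),
           envir = lookup)
  }
  vocab <- unique(unlist(strsplit(phrase, " ", fixed = TRUE)))
  vocab_env <- new.env(parent = emptyenv(), size = length(vocab) * 2L)
  for (w in vocab) assign(w, TRUE, envir = vocab_env)
  structure(list(table = tab, lookup = lookup, vocab = vocab_env,
                 vocab_words = vocab, max_len = max(nwords)),
            class = "food_dictionary")
}

#' @export
print.food_dictionary <- function(x, ...) {
  counts <- table(x$table$type)
  cat("<food_dictionary> ", nrow(x$table), " phrases (",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Load a typo/abbreviation map
#'
#' Two-column CSV `typo,correct` mapping misspellings and abbreviations to
#' dictionary tokens. Lookup is case-insensitive; canonical tokens are
#' fixed points (applying the map twice equals applying it once).
#'
#' @param path CSV path.
#' @return a named character vector (names = typos, values = corrections).
#' @export
load_typo_dictionary <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  stopifnot(all(c("typo", "correct") %in% names(raw)))
  stats::setNames(tolower(trimws(raw$correct)), tolower(trimws(raw$typo)))
}

#' Shipped reduced dictionaries and exclusion lists
#'
#' The package ships a reduced open lexicon (a few hundred foods and
#' beverages plus modifier/stopword/water/medication/selfcare lists), a
#' small typo map, the 16 non-descriptive phrases excluded from diversity
#' analyses, and a reduced ingredient-style exclusion list (condiments,
#' sauces, cooking ingredients). These are sufficient for synthetic
#' cohorts and testing; production use at the scale of thousands of
#' phrases only requires larger files in the same format.
#'
#' @return `default_food_dictionary()` a `food_dictionary`;
#'   `default_typo_dictionary()` a named character vector;
#'   `default_nondescriptive()` and `default_ingredients()` character
#'   vectors of excluded item names.
#' @export
default_food_dictionary <- function() {
  load_food_dictionary(system.file("extdata", "food_dictionary.csv",
                                   package = "chronoeat", mustWork = TRUE))
}

#' @rdname default_food_dictionary
#' @export
default_typo_dictionary <- function() {
  load_typo_dictionary(system.file("extdata", "typo_dictionary.csv",
                                   package = "chronoeat", mustWork = TRUE))
}

#' @rdname default_food_dictionary
#' @export
default_nondescriptive <- function() {
  readLines(system.file("extdata", "nondescriptive.txt",
                        package = "chronoeat", mustWork = TRUE))
}

#' @rdname default_food_dictionary
#' @export
default_ingredients <- function() {
  readLines(system.file("extdata", "ingredients.txt",
                        package = "chronoeat", mustWork = TRUE))
}
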