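#' Read a category scheme file
#'
#' A scheme file assigns one or more category labels to each allowable
#' response. It is a two-column, headerless CSV in the format
#' `category-label,member` (e.g. `Pets,dog`). A response may appear under
#' several labels. Schemes serve two purposes: they define cluster
#' membership for switch/size scoring, and they define the set of allowable
#' responses for intrusion detection.
#'
#' Labels and members are lowercased and whitespace-trimmed so that matching
#' against cleaned fluency responses is case-insensitive.
#'
#' @param path Path to a two-column CSV file (no header).
#' @return A `fluency_scheme` object with fields `kind` (`"semantic"`),
#'   `categories` (named list label -> character vector of members) and
#'   `inverted` (named list member -> character vector of labels).
#' @seealso [letter_scheme()] for letter-fluency prefix schemes,
#'   [segment_clusters()], [intrusions()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("scheme file not found: ", path))
  }
  raw <- readr::read_csv(path, col_names = c("label", "member"),
                         col_types = "cc", progress = FALSE)
  if (nrow(raw) == 0) abort("scheme file is empty")
  if (anyNA(raw$label) || anyNA(raw$member)) {
    abort("scheme file has rows without exactly two fields")
  }
  label <- clean_token(raw$label)
  member <- clean_token(raw$member)
  categories <- split(member, label)
  categories <- lapply(categories, unique)
  inverted <- split(rep(names(categories), lengths(categories)),
                    unlist(categories, use.names = FALSE))
  inverted <- lapply(inverted, unique)
  structure(
    list(kind = "semantic", categories = categories, inverted = inverted),
    class = "fluency_scheme"
  )
}

#' Create a letter-prefix scheme
#'
#' For letter fluency data, responses are clustered by shared leading
#' letters: a prefix length of 2 labels the response `cartoon` with the
#' category `ca`. Every word belongs to exactly one category, its own
#' prefix, so any word is an allowable response under this scheme.
#'
#' @param prefix_length Positive integer, number of leading characters that
#'   form the category label.
#' @return A `fluency_scheme` object of kind `"letter-prefix"`.
#' @export
letter_scheme <- function(prefix_length) {
  if (!is.numeric(prefix_length) || length(prefix_length) != 1 ||
      is.na(prefix_length) || prefix_length < 1) {
    abort("`prefix_length` must be a positive integer")
  }
  structure(
    list(kind = "letter-prefix", prefix_length = as.integer(prefix_length)),
    class = "fluency_scheme"
  )
}

#' Coerce to a scheme
#'
#' Accepts an existing scheme, a path to a scheme CSV, or a positive integer
#' (interpreted as a letter-prefix length).
#'
#' @param x A `fluency_scheme`, file path, or positive integer.
#' @return A `fluency_scheme`.
#' @export
as_scheme <- function(x) {
  if (inherits(x, "fluency_scheme")) return(x)
  if (is.numeric(x) && length(x) == 1) return(letter_scheme(x))
  if (is.character(x) && length(x) == 1) return(read_scheme(x))
  abort("cannot interpret `x` as a scheme: supply a fluency_scheme, a file path, or a prefix length")
}

#' @export
print.fluency_scheme <- function(x, ...) {
  if (x$kind == "semantic") {
    cat("<fluency_scheme: semantic>", length(x$categories), "categories,",
        length(x$inverted), "members\n")
  } else {
    cat("<fluency_scheme: letter-prefix>", "prefix length", x$prefix_length, "\n")
  }
  invisible(x)
}

# label sets for a token vector; unknown semantic tokens get character(0)
scheme_labels <- function(tokens, scheme) {
  if (scheme$kind == "letter-prefix") {
    as.list(substr(tokens, 1L, scheme$prefix_length))
  } else {
    lapply(tokens, function(t) scheme$inverted[[t]] %||% character(0))
  }
}

# membership test used for intrusion detection
scheme_member <- function(tokens, scheme) {
  if (scheme$kind == "letter-prefix") rep(TRUE, length(tokens))
  else tokens %in% names(scheme$inverted)
}

#' Read a spelling-correction dictionary
#'
#' A spell file is a two-column, headerless CSV in the format
#' `correct-spelling,incorrect-spelling` (e.g. `zebra,zebru`). Besides
#' misspellings, entries may canonicalize variants to a single token
#' (`elephant,african elephant`), which in turn lets verbatim-repetition
#' scoring catch semantic perseverations.
#'
#' Chained entries (a corrected form that is itself listed as an incorrect
#' form elsewhere) and self-maps are rejected at load: silent transitive
#' rewriting hides coding errors in the dictionary.
#'
#' @param path Path to a two-column CSV file (no header).
#' @return A named character vector mapping incorrect -> correct spellings,
#'   with class `spell_map`.
#' @export
read_spell_map <- function(path) {
  if (!file.exists(path)) abort(paste0("spell file not found: ", path))
  raw <- readr::read_csv(path, col_names = c("correct", "incorrect"),
                         col_types = "cc", progress = FALSE)
  if (anyNA(raw$correct) || anyNA(raw$incorrect)) {
    abort("spell file has rows without exactly two fields")
  }
  correct <- clean_token(raw$correct)
  incorrect <- clean_token(raw$incorrect)
  self <- incorrect == correct
  if (any(self)) {
    abort(paste0("spell map entries map a word to itself: ",
                 paste(unique(incorrect[self]), collapse = ", ")))
  }
  chained <- intersect(correct, incorrect)
  if (length(chained) > 0) {
    abort(paste0("spell map contains chained corrections (corrected forms that are also keys): ",
                 paste(unique(chained), collapse = ", ")))
  }
  dup <- duplicated(incorrect)
  if (any(dup)) {
    abort(paste0("spell map lists the same incorrect spelling twice: ",
                 paste(unique(incorrect[dup]), collapse = ", ")))
  }
  structure(setNames(correct, incorrect), class = "spell_map")
}

apply_spell_map <- function(tokens, spell) {
  if (is.null(spell)) return(tokens)
  hit <- tokens %in% names(spell)
  tokens[hit] <- unname(unclass(spell)[tokens[hit]])
  tokens
}

#' Read a word-norm table
#'
#' A norm file maps words to a numeric value — corpus frequency, age of
#' acquisition, valence, or any other per-word rating — one `word,value`
#' row per word, no header.
#'
#' The `missing` argument fixes the policy for words absent from the table:
#' a finite number substitutes that value (0.5 is the conventional default
#' for word frequency), while `NULL` (the default) excludes missing words
#' from list means entirely.
#'
#' @param path Path to a two-column `word,value` CSV file (no header).
#' @param missing Either `NULL` (ignore words not in the table) or a single
#'   finite numeric substitute value.
#' @return A `norm_table` object.
#' @seealso [word_stat()]
#' @export
read_norms <- function(path, missing = NULL) {
  if (!file.exists(path)) abort(paste0("norm file not found: ", path))
  raw <- readr::read_csv(path, col_names = c("word", "value"),
                         col_types = "cd", progress = FALSE)
  if (anyNA(raw$value)) abort("norm file has non-numeric or missing values")
  norm_table(setNames(raw$value, clean_token(raw$word)), missing = missing)
}

#' Construct a norm table from a named numeric vector
#'
#' @param values Named numeric vector, word -> value.
#' @param missing `NULL` (ignore missing words) or a finite substitute value.
#' @return A `norm_table` object.
#' @export
norm_table <- function(values, missing = NULL) {
  if (!is.numeric(values) || is.null(names(values))) {
    abort("`values` must be a named numeric vector")
  }
  if (!is.null(missing)) {
    if (!is.numeric(missing) || length(missing) != 1 || !is.finite(missing)) {
      abort("`missing` must be NULL or a single finite number")
    }
  }
  structure(list(values = values, missing = missing), class = "norm_table")
}

#' @export
print.norm_table <- function(x, ...) {
  cat("<norm_table>", length(x$values), "words; missing policy:",
      if (is.null(x$missing)) "ignore" else paste("substitute", x$missing), "\n")
  invisible(x)
}
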