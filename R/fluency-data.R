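# lowercase + trim; the canonical token form used throughout
clean_token <- function(x) stringr::str_squish(stringr::str_to_lower(x))

#' Load a fluency dataset from CSV
#'
#' Reads a fluency data file, applies optional cleaning, and returns a
#' tidy `fluency_tbl` (a tibble with one row per response, in chronological
#' order within each list).
#'
#' The file must have a header row with at least the columns `id` (subject
#' identifier), `listnum` (list identifier, unique within subject) and
#' `item` (the response). Optional columns `category`, `group` and `rt`
#' (inter-item response time) are kept; any other columns are ignored.
#' Responses within a list must be in chronological order.
#'
#' Cleaning is applied in a fixed order: tokens are lowercased and trimmed,
#' non-alphabetic characters are stripped if requested, spelling corrections
#' are applied, then verbatim perseverations are removed, then intrusions.
#' Removing perseverations only after spelling corrections means that
#' canonicalized variants (e.g. two elephant subspecies both corrected to
#' `elephant`) are caught as repeats.
#'
#' @param path Path to the fluency CSV file.
#' @param subject,group,category Optional character vectors; when supplied,
#'   only matching rows are kept (filters are applied before any cleaning).
#' @param spell Optional [read_spell_map()] object or path to a spell CSV.
#' @param remove_perseverations If `TRUE`, drop verbatim repeats within a
#'   list (after spelling corrections).
#' @param remove_intrusions If `TRUE`, drop responses that are not allowable
#'   under `scheme` / `target_letter`; one of those must then be supplied.
#' @param scheme Optional scheme (object, path, or prefix length; see
#'   [as_scheme()]) defining allowable responses for intrusion removal.
#' @param target_letter Optional single character for letter fluency:
#'   responses not starting with it are intrusions.
#' @param remove_nonalpha If `TRUE`, strip all non-alphabetic characters
#'   (including spaces) from responses before matching.
#' @param hierarchical If `TRUE`, downstream measures aggregate lists within
#'   each subject (one value per subject); if `FALSE` (default) each list is
#'   scored separately.
#' @return A `fluency_tbl`: tibble with columns `id`, `listnum`, `item` and
#'   any of `category`, `group`, `rt` present in the file. Attributes record
#'   the hierarchy flag, spelling corrections applied, and any removed
#'   perseverations/intrusions.
#' @examples
#' path <- system.file("extdata", "example_fluency.csv", package = "fluencynet")
#' fl <- load_fluency_data(path)
#' fl
#' @export
load_fluency_data <- function(path,
                              subject = NULL,
                              group = NULL,
                              category = NULL,
                              spell = NULL,
                              remove_perseverations = FALSE,
                              remove_intrusions = FALSE,
                              scheme = NULL,
                              target_letter = NULL,
                              remove_nonalpha = FALSE,
                              hierarchical = FALSE) {
  if (!file.exists(path)) abort(paste0("fluency data file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("id", "listnum", "item")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("fluency data file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- intersect(c("id", "listnum", "item", "category", "group", "rt"),
                    names(raw))
  df <- tibble::as_tibble(raw[keep])
  df$listnum <- as.integer(df$listnum)
  if (anyNA(df$listnum)) abort("column `listnum` must be integer-valued")
  if ("rt" %in% names(df)) df$rt <- as.numeric(df$rt)

  # filters are applied before any cleaning or construction
  df <- filter_fluency(df, subject, group, category)

  clean_and_build(df,
                  spell = spell,
                  remove_perseverations = remove_perseverations,
                  remove_intrusions = remove_intrusions,
                  scheme = scheme,
                  target_letter = target_letter,
                  remove_nonalpha = remove_nonalpha,
                  hierarchical = hierarchical)
}

filter_fluency <- function(df, subject, group, category) {
  apply_one <- function(df, col, values) {
    if (is.null(values)) return(df)
    if (!col %in% names(df)) {
      abort(paste0("cannot filter on `", col, "`: column not present in data"))
    }
    out <- df[df[[col]] %in% values, , drop = FALSE]
    unknown <- setdiff(values, unique(df[[col]]))
    if (length(unknown) > 0) {
      warn(paste0("filter value(s) not present in `", col, "`: ",
                  paste(unknown, collapse = ", ")))
    }
    if (nrow(out) == 0) warn(paste0("filter on `", col, "` selected no rows"))
    out
  }
  df <- apply_one(df, "id", subject)
  df <- apply_one(df, "group", group)
  apply_one(df, "category", category)
}

clean_and_build <- function(df, spell = NULL,
                            remove_perseverations = FALSE,
                            remove_intrusions = FALSE,
                            scheme = NULL, target_letter = NULL,
                            remove_nonalpha = FALSE,
                            hierarchical = FALSE) {
  if (remove_intrusions && is.null(scheme) && is.null(target_letter)) {
    abort("`remove_intrusions = TRUE` requires a `scheme` or `target_letter`: a list of allowable responses must be provided")
  }
  if (!is.null(spell) && !inherits(spell, "spell_map")) {
    spell <- read_spell_map(spell)
  }
  if (!is.null(scheme)) scheme <- as_scheme(scheme)

  df$item <- clean_token(df$item)
  if (remove_nonalpha) {
    df$item <- stringr::str_remove_all(df$item, "[^a-z]")
  }

  before <- df$item
  df$item <- apply_spell_map(df$item, spell)
  corrected <- before != df$item
  corrections <- tibble::tibble(id = df$id[corrected],
                                listnum = df$listnum[corrected],
                                from = before[corrected],
                                to = df$item[corrected])

  removed_pers <- empty_removed()
  if (remove_perseverations) {
    dup <- as.logical(stats::ave(seq_along(df$item), df$id, df$listnum,
                                 FUN = function(i) duplicated(df$item[i])))
    removed_pers <- removed_rows(df, dup)
    df <- df[!dup, , drop = FALSE]
  }

  removed_intr <- empty_removed()
  if (remove_intrusions) {
    ok <- allowable(df$item, scheme, target_letter)
    removed_intr <- removed_rows(df, !ok)
    df <- df[ok, , drop = FALSE]
  }

  out <- as_fluency_data(df, hierarchical = hierarchical)
  attr(out, "corrections") <- corrections
  attr(out, "removed_perseverations") <- removed_pers
  attr(out, "removed_intrusions") <- removed_intr
  out
}

allowable <- function(tokens, scheme, target_letter) {
  if (!is.null(target_letter)) {
    if (!is.character(target_letter) || nchar(target_letter) != 1) {
      abort("`target_letter` must be a single character")
    }
    startsWith(tokens, stringr::str_to_lower(target_letter))
  } else {
    scheme_member(tokens, scheme)
  }
}

empty_removed <- function() {
  tibble::tibble(id = character(), listnum = integer(),
                 position = integer(), item = character())
}

removed_rows <- function(df, flag) {
  pos <- as.integer(stats::ave(seq_along(df$item), df$id, df$listnum,
                               FUN = seq_along))
  tibble::tibble(id = df$id[flag], listnum = df$listnum[flag],
                 position = pos[flag], item = df$item[flag])
}

#' Coerce a data frame to a fluency dataset
#'
#' Validates the required columns, sorts lists first by subject
#' (lexicographically) then by list number (numerically) while preserving
#' chronological response order within each list, and attaches the
#' hierarchy flag.
#'
#' @param x Data frame with columns `id`, `listnum`, `item` (and optionally
#'   `category`, `group`, `rt`), responses in chronological order within
#'   each list.
#' @param hierarchical Logical hierarchy flag; see [load_fluency_data()].
#' @return A `fluency_tbl`.
#' @export
as_fluency_data <- function(x, hierarchical = FALSE) {
  required <- c("id", "listnum", "item")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  x$id <- as.character(x$id)
  x$listnum <- as.integer(x$listnum)
  # stable sort: subjects lexicographic, lists numeric, responses in file order
  ord <- order(match(x$id, str_sort_c(unique(x$id))), x$listnum)
  x <- x[ord, , drop = FALSE]
  structure(x,
            hierarchical = isTRUE(hierarchical),
            class = c("fluency_tbl", class(tibble::tibble())))
}

#' Toggle hierarchical aggregation
#'
#' A hierarchical dataset groups multiple lists per subject: measures return
#' one value per subject, the unweighted mean across that subject's lists.
#' A flat (non-hierarchical) dataset treats every list as independent:
#' measures return one value per list. Toggling does not alter the data.
#'
#' @param data A `fluency_tbl`.
#' @param hierarchical Logical.
#' @return The same dataset with the aggregation mode set.
#' @export
set_hierarchy <- function(data, hierarchical) {
  check_fluency_tbl(data)
  attr(data, "hierarchical") <- isTRUE(hierarchical)
  data
}

#' @rdname set_hierarchy
#' @export
is_hierarchical <- function(data) {
  check_fluency_tbl(data)
  isTRUE(attr(data, "hierarchical"))
}

check_fluency_tbl <- function(data) {
  if (!inherits(data, "fluency_tbl")) {
    abort("`data` must be a fluency_tbl (see load_fluency_data() / as_fluency_data())")
  }
  invisible(data)
}

#' Nest a fluency dataset into one row per list
#'
#' @param data A `fluency_tbl`.
#' @return A tibble with columns `id`, `listnum`, optionally `category` and
#'   `group` (first value per list), and list-columns `tokens` and (if
#'   present) `rts`.
#' @export
fluency_lists <- function(data) {
  check_fluency_tbl(data)
  key <- paste(data$id, data$listnum, sep = "\r")
  idx <- unname(split(seq_len(nrow(data)), factor(key, levels = unique(key))))
  out <- tibble::tibble(
    id = vapply(idx, function(i) data$id[i[1]], character(1)),
    listnum = vapply(idx, function(i) data$listnum[i[1]], integer(1)),
    tokens = lapply(idx, function(i) data$item[i])
  )
  for (col in intersect(c("category", "group"), names(data))) {
    out[[col]] <- vapply(idx, function(i) data[[col]][i[1]], character(1))
  }
  if ("rt" %in% names(data)) {
    out$rts <- lapply(idx, function(i) data$rt[i])
  }
  out
}

#' Item index of a fluency dataset
#'
#' Bijection between the distinct response strings of the dataset and the
#' integers `1..n`. The number of rows is the total number of unique
#' responses across all lists (the group node count).
#'
#' @param data A `fluency_tbl`.
#' @return Tibble with columns `item` and `index`.
#' @export
item_index <- function(data) {
  check_fluency_tbl(data)
  items <- str_sort_c(unique(data$item))
  tibble::tibble(item = items, index = seq_along(items))
}

#' Unique-response counts
#'
#' For a flat dataset, the total number of distinct responses; for a
#' hierarchical dataset, additionally the per-subject distinct counts.
#'
#' @param data A `fluency_tbl`.
#' @return A tibble with columns `id` and `n_nodes`, plus an attribute
#'   `group_n_nodes` with the dataset-wide count. For flat data a single
#'   row with `id = NA`.
#' @export
n_nodes <- function(data) {
  check_fluency_tbl(data)
  total <- length(unique(data$item))
  if (is_hierarchical(data)) {
    per <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(data), .data$id),
                            n_nodes = dplyr::n_distinct(.data$item),
                            .groups = "drop")
  } else {
    per <- tibble::tibble(id = NA_character_, n_nodes = total)
  }
  attr(per, "group_n_nodes") <- total
  per
}

#' Remove intrusions from a single token list
#'
#' Splits a token sequence into responses allowable under the scheme (or
#' target letter) and intrusions, preserving order.
#'
#' @param tokens Character vector of responses.
#' @param scheme Optional scheme (see [as_scheme()]).
#' @param target_letter Optional single character (letter fluency).
#' @return List with elements `kept` and `removed`.
#' @export
remove_intrusions_from_list <- function(tokens, scheme = NULL,
                                        target_letter = NULL) {
  if (is.null(scheme) && is.null(target_letter)) {
    abort("supply a `scheme` or a `target_letter`")
  }
  if (!is.null(scheme)) scheme <- as_scheme(scheme)
  ok <- allowable(tokens, scheme, target_letter)
  list(kept = tokens[ok], removed = tokens[!ok])
}

#' Write a fluency dataset back to CSV
#'
#' Writes the standard fluency CSV (header `id,listnum,item` plus any
#' optional columns present) so that reloading with [load_fluency_data()]
#' and the same options reproduces the dataset.
#'
#' @param data A `fluency_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fluency_csv <- function(data, path) {
  check_fluency_tbl(data)
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' @export
print.fluency_tbl <- function(x, ...) {
  nl <- nrow(unique(tibble::as_tibble(x)[c("id", "listnum")]))
  cat("<fluency_tbl> ", nrow(x), " responses, ", nl, " lists, ",
      length(unique(x$id)), " subjects; ",
      if (is_hierarchical(x)) "hierarchical" else "flat", "\n", sep = "")
  NextMethod()
}
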