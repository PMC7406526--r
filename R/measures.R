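#' Segment a fluency list into clusters
#'
#' Partitions a token sequence into contiguous clusters of semantically
#' related responses, under one of two boundary rules:
#'
#' * `fluid`: a new cluster begins at token *t* whenever *t* shares no
#'   category label with the immediately preceding token.
#' * `static`: a running intersection of label sets is maintained over the
#'   current cluster; a new cluster begins whenever the next token shares no
#'   label with that intersection (a label common to the whole run so far).
#'   The token that breaks the cluster starts the next one.
#'
#' Multi-label membership counts: continuity requires a non-empty label-set
#' intersection, not label equality. Tokens absent from a semantic scheme
#' carry a unique singleton label, so they always stand as their own
#' one-token cluster and trigger a switch on both sides; a warning lists
#' such tokens so unknown words are visible rather than silently fused.
#'
#' @param tokens Character vector of responses (one list).
#' @param scheme Scheme object, path, or prefix length; see [as_scheme()].
#' @param mode `"fluid"` (default) or `"static"`.
#' @return A `cluster_segmentation` object: list with `tokens`, `clusters`
#'   (list of character vectors concatenating to `tokens`), `sizes`,
#'   `boundaries` (start index of each cluster), `switches`
#'   (`length(clusters) - 1`, 0 for empty input), and `mode`.
#' @examples
#' sch <- as_scheme(system.file("extdata", "example_scheme.csv",
#'                              package = "fluencynet"))
#' segment_clusters(c("hamster", "cat", "dog", "wolf", "coyote", "zebra"),
#'                  sch, mode = "static")
#' @export
segment_clusters <- function(tokens, scheme, mode = c("fluid", "static")) {
  mode <- match.arg(mode)
  scheme <- as_scheme(scheme)
  n <- length(tokens)
  if (n == 0) {
    return(structure(list(tokens = character(0), clusters = list(),
                          sizes = integer(0), boundaries = integer(0),
                          switches = 0L, mode = mode),
                     class = "cluster_segmentation"))
  }
  labels <- scheme_labels(tokens, scheme)
  unknown <- lengths(labels) == 0
  if (any(unknown)) {
    warn(paste0("token(s) not in scheme, treated as singleton clusters: ",
                paste(unique(tokens[unknown]), collapse = ", ")))
    labels[unknown] <- paste0("..unknown..", which(unknown))
  }
  starts <- 1L
  running <- labels[[1]]
  if (n > 1) {
    for (t in 2:n) {
      ref <- if (mode == "fluid") labels[[t - 1]] else running
      shared <- intersect(labels[[t]], ref)
      if (length(shared) == 0) {
        starts <- c(starts, t)
        running <- labels[[t]]
      } else {
        running <- if (mode == "static") shared else labels[[t]]
      }
    }
  }
  ends <- c(starts[-1] - 1L, n)
  clusters <- Map(function(s, e) tokens[s:e], starts, ends)
  structure(list(tokens = tokens, clusters = clusters,
                 sizes = lengths(clusters), boundaries = starts,
                 switches = length(clusters) - 1L, mode = mode),
            class = "cluster_segmentation")
}

#' @export
print.cluster_segmentation <- function(x, ...) {
  cat("<cluster_segmentation: ", x$mode, "> ", length(x$clusters),
      " clusters, ", x$switches, " switches\n", sep = "")
  for (cl in x$clusters) cat("  [", paste(cl, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_segmentation <- function(x, ...) {
  tibble::tibble(cluster = seq_along(x$clusters),
                 start = x$boundaries,
                 size = as.integer(x$sizes),
                 tokens = x$clusters)
}

#' @exportS3Method generics::glance
glance.cluster_segmentation <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$clusters),
                 switches = x$switches,
                 mean_size = if (length(x$sizes)) mean(x$sizes) else NA_real_,
                 mode = x$mode)
}

# shared per-list -> per-subject machinery; f maps tokens -> scalar
measure_over_lists <- function(data, name, f) {
  check_fluency_tbl(data)
  lists <- fluency_lists(data)
  lists$value <- vapply(lists$tokens, f, numeric(1))
  per_list <- tibble::tibble(id = lists$id, listnum = lists$listnum,
                             measure = name, value = lists$value)
  if (is_hierarchical(data)) {
    dplyr::summarise(dplyr::group_by(per_list, .data$id),
                     measure = name, value = mean(.data$value),
                     .groups = "drop")
  } else {
    per_list
  }
}

#' Cluster switches per list or subject
#'
#' Number of transitions between clusters in each fluency list (number of
#' clusters minus one), or the switch rate — switches divided by the number
#' of scored responses in the list — when `switch_rate = TRUE`. The rate
#' removes the confound with generative capacity: a 30-item list can have up
#' to 29 switches while a 10-item list is capped at 9.
#'
#' Perseverations and intrusions are included in the scoring unless they
#' were removed when the data were loaded. Hierarchical datasets return the
#' unweighted mean across each subject's lists.
#'
#' @param data A `fluency_tbl`.
#' @param scheme Scheme object, path, or letter-prefix length
#'   (see [as_scheme()]).
#' @param mode `"fluid"` (default) or `"static"`.
#' @param switch_rate If `TRUE`, return switches per item.
#' @return Tibble with columns `id`, `listnum` (flat data only), `measure`,
#'   `value`.
#' @export
cluster_switches <- function(data, scheme, mode = c("fluid", "static"),
                             switch_rate = FALSE) {
  mode <- match.arg(mode)
  scheme <- as_scheme(scheme)
  name <- if (switch_rate) "switch_rate" else "cluster_switches"
  measure_over_lists(data, name, function(tokens) {
    s <- segment_clusters(tokens, scheme, mode)$switches
    if (switch_rate) {
      if (length(tokens) == 0) return(NA_real_)
      s / length(tokens)
    } else {
      as.numeric(s)
    }
  })
}

#' Mean cluster size per list or subject
#'
#' Mean number of responses per cluster in each list (see
#' [segment_clusters()] for the clustering rules); hierarchical datasets
#' return the mean of list means per subject.
#'
#' @inheritParams cluster_switches
#' @return Tibble with columns `id`, `listnum` (flat data only), `measure`,
#'   `value`.
#' @export
cluster_sizes <- function(data, scheme, mode = c("fluid", "static")) {
  mode <- match.arg(mode)
  scheme <- as_scheme(scheme)
  measure_over_lists(data, "cluster_size", function(tokens) {
    if (length(tokens) == 0) return(NA_real_)
    mean(segment_clusters(tokens, scheme, mode)$sizes)
  })
}

#' Count or list perseverations
#'
#' A perseveration is a response repeated verbatim within the same list:
#' every occurrence beyond the first counts. Because spelling corrections
#' are applied at load time, canonicalized variants (subspecies, word forms)
#' mapped to the same token are detected as repeats.
#'
#' @param data A `fluency_tbl`.
#' @param as_list If `TRUE`, return the perseverated tokens themselves (one
#'   row per occurrence, with its position) instead of counts.
#' @return Counts: tibble `id`, `listnum` (flat only), `measure`, `value`
#'   (hierarchical: mean count per subject). Token form: tibble `id`,
#'   `listnum`, `position`, `item`.
#' @export
perseverations <- function(data, as_list = FALSE) {
  check_fluency_tbl(data)
  if (as_list) {
    lists <- fluency_lists(data)
    rows <- purrr::pmap(lists[c("id", "listnum", "tokens")],
      function(id, listnum, tokens) {
        rep_at <- which(duplicated(tokens))
        tibble::tibble(id = id, listnum = listnum,
                       position = rep_at, item = tokens[rep_at])
      })
    return(dplyr::bind_rows(rows))
  }
  measure_over_lists(data, "perseverations",
                     function(tokens) sum(duplicated(tokens)))
}

#' Count or list intrusions
#'
#' An intrusion is a response outside the allowed set: for semantic fluency,
#' a token that is not a member of any category in the scheme; for letter
#' fluency, a token that does not begin with the target letter.
#'
#' @param data A `fluency_tbl`.
#' @param scheme Optional scheme (see [as_scheme()]).
#' @param target_letter Optional single character (letter fluency).
#' @param as_list If `TRUE`, return the intruding tokens with positions.
#' @return As [perseverations()].
#' @export
intrusions <- function(data, scheme = NULL, target_letter = NULL,
                       as_list = FALSE) {
  check_fluency_tbl(data)
  if (is.null(scheme) && is.null(target_letter)) {
    abort("intrusion detection requires a `scheme` or `target_letter`")
  }
  if (!is.null(scheme)) scheme <- as_scheme(scheme)
  if (as_list) {
    lists <- fluency_lists(data)
    rows <- purrr::pmap(lists[c("id", "listnum", "tokens")],
      function(id, listnum, tokens) {
        bad <- which(!allowable(tokens, scheme, target_letter))
        tibble::tibble(id = id, listnum = listnum,
                       position = bad, item = tokens[bad])
      })
    return(dplyr::bind_rows(rows))
  }
  measure_over_lists(data, "intrusions",
                     function(tokens) sum(!allowable(tokens, scheme, target_letter)))
}

#' Number of responses per list or subject
#'
#' Total responses given in each list, including perseverations and
#' intrusions unless removed at load.
#'
#' @param data A `fluency_tbl`.
#' @return Tibble with columns `id`, `listnum` (flat only), `measure`,
#'   `value`.
#' @export
n_responses <- function(data) {
  measure_over_lists(data, "n_responses", length)
}

#' Mean word-norm value per list or subject
#'
#' Looks every response up in a norm table (word frequency, age of
#' acquisition, or any word -> value rating) and averages over the list.
#' Words absent from the table either contribute the table's substitute
#' value or are excluded from the mean, per the table's missing policy
#' (see [read_norms()]). A list whose tokens are all missing under the
#' ignore policy yields `NA` with a warning, never a silent zero.
#'
#' @param data A `fluency_tbl`.
#' @param norms A `norm_table` (see [read_norms()], [norm_table()]).
#' @param name Measure name used in the output (default `"word_stat"`).
#' @return Tibble with columns `id`, `listnum` (flat only), `measure`,
#'   `value`.
#' @export
word_stat <- function(data, norms, name = "word_stat") {
  check_fluency_tbl(data)
  if (!inherits(norms, "norm_table")) {
    abort("`norms` must be a norm_table (see read_norms())")
  }
  any_undefined <- FALSE
  out <- measure_over_lists(data, name, function(tokens) {
    if (length(tokens) == 0) return(NA_real_)
    v <- unname(norms$values[tokens])
    if (is.null(norms$missing)) {
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        any_undefined <<- TRUE
        return(NA_real_)
      }
    } else {
      v[is.na(v)] <- norms$missing
    }
    mean(v)
  })
  if (any_undefined) {
    warn("some lists have no tokens in the norm table; their value is NA")
  }
  out
}
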