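# First-passage probability for the censored walk.
#
# Given the set of already-visited nodes, a walk currently at `from` moves
# uniformly over neighbors; visited nodes are transient, unvisited neighbors
# of the visited set absorb. Returns the probability that `target` (an
# unvisited node) is the first absorption point, by solving the linear
# system of the absorbing chain. Transient states that cannot reach any
# absorbing state are dropped (their absorption probability is zero), which
# keeps the reduced system nonsingular.
first_passage_prob <- function(adj, deg, visited_idx, from_idx, target_idx) {
  if (deg[from_idx] == 0) return(0)
  # absorbing set: unvisited neighbors of the visited set
  nbr_any <- colSums(adj[visited_idx, , drop = FALSE]) > 0
  nbr_any[visited_idx] <- FALSE
  if (!nbr_any[target_idx]) return(0)

  # restrict transients to those connected (within the visited-induced
  # subgraph) to a node holding an unvisited neighbor
  has_exit <- rowSums(adj[visited_idx, nbr_any, drop = FALSE]) > 0
  sub <- adj[visited_idx, visited_idx, drop = FALSE]
  reach <- has_exit
  repeat {
    grown <- reach | (sub %*% reach > 0)
    if (all(grown == reach)) break
    reach <- grown
  }
  if (!reach[match(from_idx, visited_idx)]) return(0)
  live <- visited_idx[reach]

  q <- adj[live, live, drop = FALSE] / deg[live]
  r <- adj[live, target_idx] / deg[live]
  h <- tryCatch(solve(diag(length(live)) - q, r, tol = 1e-10),
                error = function(e) NULL)
  if (is.null(h)) return(0)
  max(0, h[match(from_idx, live)])
}

#' Exact censored-random-walk log-likelihood of one list
#'
#' The generative model is an uncensored random walk on the network that
#' moves uniformly at random over neighbors, with only first visits
#' emitted. The first response is conditioned on (it contributes
#' log-probability zero), which keeps the objective comparable across
#' networks. Each subsequent response contributes the probability that a
#' walk started at the previous response — free to revisit any
#' already-emitted node — first leaves the visited set at exactly that
#' response. These first-passage probabilities are computed exactly by
#' solving the linear system of the absorbing chain whose transient states
#' are the visited responses and whose absorbing states are their unvisited
#' neighbors.
#'
#' @param net A [semantic_network()].
#' @param tokens Character vector of distinct responses (perseverations are
#'   not allowed under this model), all of which must be nodes of `net`.
#' @return A `walk_likelihood` object: list with `log_likelihood` (real or
#'   `-Inf`) and `per_transition` (ordered log-probabilities, one per
#'   emitted transition, summing to `log_likelihood`).
#' @examples
#' net <- semantic_network(rbind(c("a", "b"), c("b", "c")))
#' list_log_likelihood(net, c("a", "b", "c"))
#' @export
list_log_likelihood <- function(net, tokens) {
  check_network(net)
  if (length(tokens) == 0) abort("`tokens` must be non-empty")
  if (anyDuplicated(tokens)) {
    abort("`tokens` contains repeated responses; the censored-walk likelihood requires perseveration-free lists")
  }
  unknown <- setdiff(tokens, net$nodes)
  if (length(unknown) > 0) {
    abort(paste0("token(s) not in network: ", paste(unknown, collapse = ", ")))
  }
  idx <- match(tokens, net$nodes)
  adj <- net$adj
  deg <- rowSums(adj)
  m <- length(tokens)
  per <- numeric(max(0, m - 1))
  for (k in seq_len(m)[-1]) {
    p <- first_passage_prob(adj, deg, idx[seq_len(k - 1)], idx[k - 1], idx[k])
    per[k - 1] <- log(p)
    if (p == 0) {
      per[seq_len(m - 1) > (k - 1)] <- NA_real_
      break
    }
  }
  structure(list(log_likelihood = if (anyNA(per)) -Inf else sum(per),
                 per_transition = per),
            class = "walk_likelihood")
}

#' @export
print.walk_likelihood <- function(x, ...) {
  cat("<walk_likelihood> log-likelihood:", x$log_likelihood, "over",
      length(x$per_transition), "transitions\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.walk_likelihood <- function(x, ...) {
  tibble::tibble(transition = seq_along(x$per_transition),
                 log_prob = x$per_transition)
}

#' @exportS3Method generics::glance
glance.walk_likelihood <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood,
                 n_transitions = length(x$per_transition),
                 finite = is.finite(x$log_likelihood))
}

#' Censored-random-walk log-likelihood of a dataset
#'
#' Sum of [list_log_likelihood()] over the (independent) lists of the
#' dataset; `-Inf` if any list is impossible under the network.
#'
#' @param net A [semantic_network()].
#' @param data A `fluency_tbl` whose lists are perseveration-free.
#' @return A single real value (possibly `-Inf`).
#' @export
dataset_log_likelihood <- function(net, data) {
  lists <- estimator_lists(data)
  sum(vapply(lists, function(tok) list_log_likelihood(net, tok)$log_likelihood,
             numeric(1)))
}

#' Simulate one censored random walk
#'
#' Runs an unrestricted uniform random walk on the network from a start
#' node, emitting each node on first visit, and stops once `emit_target`
#' unique nodes have been emitted or the step budget is exhausted (the
#' truncated list is returned as-is, flagged via attribute `truncated`).
#'
#' @param net A [semantic_network()].
#' @param emit_target Number of unique responses to emit (at least 1).
#' @param start Start rule: `"uniform"` (uniform over nodes), a node label
#'   (fixed start), or a named numeric vector of node weights
#'   (frequency-weighted start).
#' @param max_steps Walk-step budget (default `100 * emit_target`); must be
#'   at least `emit_target`.
#' @param seed Optional integer; when given, the simulation is a
#'   deterministic function of it and the caller's RNG state is left
#'   untouched.
#' @param n Number of independent walks to simulate (default 1).
#' @return For `n = 1`, a character vector of emitted responses in emission
#'   order with attribute `truncated` (logical); for `n > 1`, a list of
#'   such vectors.
#' @export
simulate_censored_walk <- function(net, emit_target, start = "uniform",
                                   max_steps = 100 * emit_target,
                                   seed = NULL, n = 1) {
  check_network(net)
  if (!is.numeric(emit_target) || emit_target < 1) {
    abort("`emit_target` must be at least 1")
  }
  emit_target <- as.integer(emit_target)
  if (max_steps < emit_target) abort("`max_steps` must be >= `emit_target`")
  comp <- igraph::components(as_igraph(net))
  run <- function() {
    start_idx <- pick_start(net, start)
    comp_size <- comp$csize[comp$membership[start_idx]]
    if (comp_size < emit_target) {
      abort(paste0("start node lies in a component of ", comp_size,
                   " node(s); cannot emit ", emit_target, " unique responses"))
    }
    walk_once(net$adj, start_idx, emit_target, max_steps, net$nodes)
  }
  run_all <- function() {
    if (n == 1) run() else replicate(n, run(), simplify = FALSE)
  }
  if (is.null(seed)) run_all() else with_seed(seed, run_all())
}

pick_start <- function(net, start) {
  n <- length(net$nodes)
  if (is.numeric(start)) {
    if (is.null(names(start))) abort("weighted `start` must be a named vector")
    w <- rep(0, n)
    w[match(names(start), net$nodes)] <- start
    if (any(is.na(match(names(start), net$nodes)))) {
      abort("weighted `start` names must be network nodes")
    }
    sample.int(n, 1, prob = w)
  } else if (identical(start, "uniform")) {
    sample.int(n, 1)
  } else {
    i <- match(start, net$nodes)
    if (is.na(i)) abort(paste0("start node not in network: ", start))
    i
  }
}

walk_once <- function(adj, start_idx, emit_target, max_steps, nodes) {
  emitted <- integer(emit_target)
  emitted[1] <- start_idx
  n_emit <- 1L
  cur <- start_idx
  seen <- logical(nrow(adj))
  seen[start_idx] <- TRUE
  steps <- 0L
  while (n_emit < emit_target && steps < max_steps) {
    nb <- which(adj[cur, ])
    if (length(nb) == 0) break
    cur <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
    steps <- steps + 1L
    if (!seen[cur]) {
      seen[cur] <- TRUE
      n_emit <- n_emit + 1L
      emitted[n_emit] <- cur
    }
  }
  out <- nodes[emitted[seq_len(n_emit)]]
  attr(out, "truncated") <- n_emit < emit_target
  out
}

#' Generate a synthetic fluency dataset with a ground-truth ledger
#'
#' Simulates censored-random-walk fluency lists from a known network, and
#' optionally plants verbatim perseverations and out-of-lexicon intrusions
#' at given rates, recording every insertion in a machine-readable ledger.
#' The ledger makes the dataset usable as a measure-recovery fixture: the
#' perseveration and intrusion counts reported by the measures module must
#' equal the planted counts exactly.
#'
#' Planting works on each simulated list independently: after each emitted
#' response beyond the first, a verbatim copy of a uniformly chosen earlier
#' response is inserted with probability `perseveration_rate`, and a fresh
#' token from `intrusion_lexicon` (sampled without replacement within the
#' list, so planted intrusions never double as perseverations) is inserted
#' with probability `intrusion_rate`.
#'
#' @param net A [semantic_network()] (the planted ground-truth network).
#' @param n_subjects,lists_per_subject Dataset dimensions.
#' @param emit_target Unique responses per list before planting (default:
#'   all nodes of `net`).
#' @param start,max_steps Passed to [simulate_censored_walk()].
#' @param perseveration_rate,intrusion_rate Per-gap insertion probabilities
#'   in `[0, 1)`.
#' @param intrusion_lexicon Character vector of out-of-network tokens drawn
#'   from when planting intrusions; defaults to a built-in nonsense lexicon.
#' @param seed Integer seed; the dataset is a deterministic function of it.
#' @param category Category label stamped on every list (default
#'   `"synthetic"`).
#' @return A flat `fluency_tbl`. Attribute `ledger` (see
#'   [synthetic_ledger()]) records planted perseverations and intrusions
#'   (with positions), plus any truncated lists.
#' @export
generate_synthetic_dataset <- function(net, n_subjects, lists_per_subject,
                                       emit_target = length(net$nodes),
                                       start = "uniform",
                                       max_steps = 100 * emit_target,
                                       perseveration_rate = 0,
                                       intrusion_rate = 0,
                                       intrusion_lexicon = NULL,
                                       seed = 1,
                                       category = "synthetic") {
  check_network(net)
  for (rate in c(perseveration_rate, intrusion_rate)) {
    if (!is.numeric(rate) || rate < 0 || rate >= 1) {
      abort("planting rates must lie in [0, 1)")
    }
  }
  if (is.null(intrusion_lexicon)) {
    intrusion_lexicon <- sprintf("xq%03d", 1:999)
  }
  overlap <- intersect(intrusion_lexicon, net$nodes)
  if (length(overlap) > 0) {
    abort(paste0("intrusion lexicon overlaps network nodes: ",
                 paste(head(overlap, 5), collapse = ", ")))
  }
  ids <- sprintf("S%03d", seq_len(n_subjects))
  with_seed(seed, {
    rows <- list()
    pers_ledger <- list()
    intr_ledger <- list()
    trunc_ledger <- list()
    for (s in ids) {
      for (l in seq_len(lists_per_subject)) {
        walk <- simulate_censored_walk(net, emit_target, start = start,
                                       max_steps = max_steps)
        if (isTRUE(attr(walk, "truncated"))) {
          trunc_ledger[[length(trunc_ledger) + 1]] <-
            tibble::tibble(id = s, listnum = l)
        }
        tokens <- walk[1]
        kind <- "walk"
        avail_intr <- intrusion_lexicon
        for (j in seq_along(walk)[-1]) {
          tokens <- c(tokens, walk[j]); kind <- c(kind, "walk")
          if (perseveration_rate > 0 &&
              stats::runif(1) < perseveration_rate) {
            earlier <- walk[seq_len(j)]
            tokens <- c(tokens, earlier[sample.int(length(earlier), 1)])
            kind <- c(kind, "pers")
          }
          if (intrusion_rate > 0 && length(avail_intr) > 0 &&
              stats::runif(1) < intrusion_rate) {
            pick <- sample.int(length(avail_intr), 1)
            tokens <- c(tokens, avail_intr[pick])
            kind <- c(kind, "intr")
            avail_intr <- avail_intr[-pick]
          }
        }
        rows[[length(rows) + 1]] <-
          tibble::tibble(id = s, listnum = l, item = tokens,
                         category = category)
        at <- which(kind == "pers")
        if (length(at)) {
          pers_ledger[[length(pers_ledger) + 1]] <-
            tibble::tibble(id = s, listnum = l, position = at,
                           item = tokens[at])
        }
        at <- which(kind == "intr")
        if (length(at)) {
          intr_ledger[[length(intr_ledger) + 1]] <-
            tibble::tibble(id = s, listnum = l, position = at,
                           item = tokens[at])
        }
      }
    }
    out <- as_fluency_data(dplyr::bind_rows(rows), hierarchical = FALSE)
    bind_or_empty <- function(x) {
      if (length(x) == 0) empty_removed() else dplyr::bind_rows(x)
    }
    attr(out, "ledger") <- list(
      perseverations = bind_or_empty(pers_ledger),
      intrusions = bind_or_empty(intr_ledger),
      truncated = if (length(trunc_ledger) == 0) {
        tibble::tibble(id = character(), listnum = integer())
      } else {
        dplyr::bind_rows(trunc_ledger)
      },
      seed = seed
    )
    out
  })
}

#' Ground-truth ledger of a synthetic dataset
#'
#' @param data A dataset from [generate_synthetic_dataset()].
#' @return List with tibbles `perseverations`, `intrusions` (planted
#'   insertions with positions), `truncated` (lists cut off by the step
#'   budget), and the generating `seed`.
#' @export
synthetic_ledger <- function(data) {
  check_fluency_tbl(data)
  ledger <- attr(data, "ledger")
  if (is.null(ledger)) abort("`data` carries no synthetic ground-truth ledger")
  ledger
}

#' Write a synthetic dataset with its ledger sidecar
#'
#' Writes the standard fluency CSV plus a JSON sidecar holding the planted
#' ground truth, so the full pipeline can be exercised end-to-end from
#' files.
#'
#' @param data A dataset from [generate_synthetic_dataset()].
#' @param csv_path Output path for the fluency CSV.
#' @param ledger_path Output path for the ledger JSON (default: `csv_path`
#'   with extension `.ledger.json`).
#' @return `csv_path`, invisibly.
#' @export
write_synthetic_dataset <- function(data, csv_path,
                                    ledger_path = paste0(csv_path, ".ledger.json")) {
  ledger <- synthetic_ledger(data)
  write_fluency_csv(data, csv_path)
  jsonlite::write_json(ledger, ledger_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
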