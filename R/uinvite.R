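#' Maximum-likelihood network under the censored-random-walk model
#'
#' Estimates the network that maximizes the probability of the observed
#' fluency lists under the censored-random-walk generative model (see
#' [list_log_likelihood()]), combined with an independent Bernoulli(theta)
#' prior over edges. With the default flat prior (theta = 0.5) the result
#' is a pure maximum-likelihood fit.
#'
#' The search is greedy coordinate ascent over edge toggles: starting from
#' the naive random-walk network (which always assigns the data positive
#' likelihood, since every observed transition then runs along an edge),
#' candidate node pairs are swept in seeded random order and an edge is
#' added or removed whenever the toggle strictly increases the posterior
#' score. Sweeps repeat until a full pass accepts no toggle or `max_passes`
#' is reached. The result is a local maximum a posteriori network and is a
#' deterministic function of (dataset, seed).
#'
#' Perseverations are not allowed in the data: remove them at load time
#' (`remove_perseverations = TRUE`) before estimating.
#'
#' @param data A `fluency_tbl` with non-empty, repeat-free lists.
#' @param prior_edge_probability Edge prior theta in (0, 1); default 0.5
#'   (flat).
#' @param max_passes Maximum number of full sweeps (default 20).
#' @param seed Integer seed controlling the sweep order.
#' @return A [semantic_network()] with attributes `score` (final
#'   log-posterior up to the prior's additive constant) and `score_trace`
#'   (objective after the initial network and after each accepted toggle;
#'   non-decreasing by construction).
#' @export
estimate_uinvite <- function(data, prior_edge_probability = 0.5,
                             max_passes = 20, seed = 1) {
  lists <- estimator_lists(data)
  if (length(lists) == 0) abort("`data` contains no lists")
  if (any(lengths(lists) == 0)) abort("`data` contains an empty list")
  has_repeat <- vapply(lists, anyDuplicated, integer(1)) > 0
  if (any(has_repeat)) {
    abort("perseverations are not allowed in the data for censored-walk estimation; remove them at load time")
  }
  theta <- prior_edge_probability
  if (!is.numeric(theta) || theta <= 0 || theta >= 1) {
    abort("`prior_edge_probability` must lie in (0, 1)")
  }
  # log-prior change for adding one edge (removal is the negation)
  prior_delta <- log(theta) - log(1 - theta)

  net <- estimate_naive_random_walk(data)
  nodes <- net$nodes
  adj <- net$adj
  deg <- rowSums(adj)
  idx_lists <- lapply(lists, match, nodes)

  list_ll <- function(adj, deg, idx) {
    total <- 0
    for (k in seq_along(idx)[-1]) {
      p <- first_passage_prob(adj, deg, idx[seq_len(k - 1)], idx[k - 1], idx[k])
      if (p == 0) return(-Inf)
      total <- total + log(p)
    }
    total
  }

  per_list <- vapply(idx_lists, function(idx) list_ll(adj, deg, idx),
                     numeric(1))
  score <- sum(per_list) + sum(adj[upper.tri(adj)]) * prior_delta
  trace <- score
  # which lists mention each node: only those can change when an edge at
  # that node is toggled
  touches <- lapply(seq_along(nodes),
                    function(i) which(vapply(idx_lists, function(idx) i %in% idx,
                                             logical(1))))
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  tol <- 1e-9

  with_seed(seed, {
    for (pass in seq_len(max_passes)) {
      accepted <- FALSE
      for (p in sample.int(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        adding <- !adj[i, j]
        affected <- union(touches[[i]], touches[[j]])
        if (length(affected) == 0 && !adding) next
        new_adj <- adj
        new_adj[i, j] <- adding
        new_adj[j, i] <- adding
        new_deg <- deg
        delta_deg <- if (adding) 1 else -1
        new_deg[c(i, j)] <- new_deg[c(i, j)] + delta_deg
        new_ll <- vapply(affected,
                         function(l) list_ll(new_adj, new_deg, idx_lists[[l]]),
                         numeric(1))
        delta <- sum(new_ll) - sum(per_list[affected]) +
          (if (adding) prior_delta else -prior_delta)
        if (is.finite(delta) && delta > tol) {
          adj <- new_adj
          deg <- new_deg
          per_list[affected] <- new_ll
          score <- score + delta
          trace <- c(trace, score)
          accepted <- TRUE
        }
      }
      if (!accepted) break
    }
  })
  out <- new_semantic_network(nodes, adj)
  attr(out, "score") <- score
  attr(out, "score_trace") <- trace
  out
}
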