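# token lists used by the estimators; estimation treats lists as units,
# regardless of the dataset's hierarchy flag
estimator_lists <- function(data) {
  check_fluency_tbl(data)
  fluency_lists(data)$tokens
}

#' First-edge network
#'
#' Connects the first two responses of every fluency list by an edge. All
#' distinct responses in the dataset become nodes; lists with fewer than
#' two responses contribute nodes only.
#'
#' @param data A `fluency_tbl`.
#' @return A [semantic_network()].
#' @export
estimate_first_edge <- function(data) {
  lists <- estimator_lists(data)
  pairs <- purrr::map(lists, function(tok) {
    if (length(tok) >= 2 && tok[1] != tok[2]) c(tok[1], tok[2]) else NULL
  })
  pairs <- purrr::compact(pairs)
  edges <- if (length(pairs)) do.call(rbind, pairs) else NULL
  semantic_network(edges = edges, nodes = unique(unlist(lists)))
}

#' Naive random-walk network
#'
#' Connects every pair of adjacent responses within each fluency list by an
#' edge; duplicate pairs across lists collapse to a single edge.
#'
#' @param data A `fluency_tbl`.
#' @return A [semantic_network()].
#' @export
estimate_naive_random_walk <- function(data) {
  lists <- estimator_lists(data)
  edges <- purrr::map(lists, function(tok) {
    if (length(tok) < 2) return(NULL)
    e <- cbind(tok[-length(tok)], tok[-1])
    e[e[, 1] != e[, 2], , drop = FALSE]
  })
  edges <- purrr::compact(edges)
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  semantic_network(edges = edges, nodes = unique(unlist(lists)))
}

#' Positional proximity distances between items
#'
#' Distance between two items is the mean, over lists containing both, of
#' the absolute difference of their (first-occurrence) positions; infinite
#' when the pair never co-occurs in a list. This positional-lag proximity is
#' one conventional choice for fluency data; it is isolated here so other
#' distances can be swapped in ahead of [estimate_pathfinder()].
#'
#' @param data A `fluency_tbl`.
#' @return Symmetric numeric matrix (items x items) of distances with a
#'   zero diagonal; `Inf` marks never-co-listed pairs.
#' @export
pathfinder_distances <- function(data) {
  lists <- estimator_lists(data)
  nodes <- str_sort_c(unique(unlist(lists)))
  n <- length(nodes)
  total <- matrix(0, n, n, dimnames = list(nodes, nodes))
  count <- matrix(0L, n, n)
  for (tok in lists) {
    pos <- match(nodes, tok)  # first occurrence
    present <- which(!is.na(pos))
    if (length(present) < 2) next
    p <- pos[present]
    lag <- abs(outer(p, p, "-"))
    total[present, present] <- total[present, present] + lag
    count[present, present] <- count[present, present] + 1L
  }
  d <- total / count  # 0/0 -> NaN for never co-listed
  d[count == 0] <- Inf
  diag(d) <- 0
  d
}

#' Pathfinder network (union of all minimum spanning trees)
#'
#' Builds the sparsest classical pathfinder network: within each connected
#' component of the finite-distance graph, an edge is kept if and only if
#' it belongs to at least one minimum spanning tree. By the cycle property,
#' edge (u, v) of weight w is in some MST exactly when u and v are
#' disconnected in the subgraph restricted to edges of weight strictly less
#' than w; [mst_union()] applies that rule directly with a Kruskal-style
#' sweep that unions equal-weight batches after testing them.
#'
#' @param data A `fluency_tbl`.
#' @return A [semantic_network()].
#' @export
estimate_pathfinder <- function(data) {
  mst_union(pathfinder_distances(data))
}

#' @rdname estimate_pathfinder
#' @param d Symmetric distance matrix with labelled dimnames (see
#'   [pathfinder_distances()]); `Inf` entries mean no direct dissimilarity.
#' @export
mst_union <- function(d) {
  nodes <- rownames(d)
  if (is.null(nodes)) abort("`d` must have dimnames")
  n <- length(nodes)
  idx <- which(upper.tri(d) & is.finite(d), arr.ind = TRUE)
  if (nrow(idx) == 0) return(semantic_network(nodes = nodes))
  w <- d[idx]
  ord <- order(w)
  idx <- idx[ord, , drop = FALSE]
  w <- w[ord]

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(idx))
  k <- 1
  while (k <= nrow(idx)) {
    # batch of equal-weight edges: test all against the strictly-lighter
    # forest, then merge the batch
    batch <- k
    while (batch < nrow(idx) && w[batch + 1] == w[k]) batch <- batch + 1
    rows <- k:batch
    roots <- cbind(vapply(idx[rows, 1], find, integer(1)),
                   vapply(idx[rows, 2], find, integer(1)))
    keep[rows] <- roots[, 1] != roots[, 2]
    for (r in rows[keep[rows]]) {
      a <- find(idx[r, 1]); b <- find(idx[r, 2])
      if (a != b) parent[a] <- b
    }
    k <- batch + 1
  }
  edges <- cbind(nodes[idx[keep, 1]], nodes[idx[keep, 2]])
  semantic_network(edges = edges, nodes = nodes)
}

#' Correlation-based network
#'
#' Computes, for every item, its presence/absence vector across lists, and
#' connects two items when the product-moment correlation of their vectors
#' reaches the threshold. Items present in every list or in none have zero
#' variance, so their correlation is undefined; they are excluded from
#' correlation (kept as isolated nodes) with a warning.
#'
#' @param data A `fluency_tbl` with at least two lists.
#' @param threshold Correlation threshold in (-1, 1); an edge is placed when
#'   r >= threshold. Default 0.5.
#' @return A [semantic_network()].
#' @export
estimate_correlation_network <- function(data, threshold = 0.5) {
  lists <- estimator_lists(data)
  if (length(lists) < 2) {
    abort("correlation-based estimation requires at least 2 lists")
  }
  if (!is.numeric(threshold) || threshold <= -1 || threshold >= 1) {
    abort("`threshold` must lie in (-1, 1)")
  }
  nodes <- str_sort_c(unique(unlist(lists)))
  presence <- vapply(lists, function(tok) nodes %in% tok,
                     logical(length(nodes)))
  presence <- matrix(presence, nrow = length(nodes),
                     dimnames = list(nodes, NULL))
  varying <- rowSums(presence) > 0 & rowSums(presence) < ncol(presence)
  if (any(!varying)) {
    warn(paste0("zero-variance item(s) excluded from correlation: ",
                paste(nodes[!varying], collapse = ", ")))
  }
  keep <- nodes[varying]
  edges <- NULL
  if (length(keep) >= 2) {
    r <- stats::cor(t(presence[keep, , drop = FALSE]))
    hit <- which(r >= threshold & upper.tri(r), arr.ind = TRUE)
    if (nrow(hit) > 0) edges <- cbind(keep[hit[, 1]], keep[hit[, 2]])
  }
  semantic_network(edges = edges, nodes = nodes)
}

#' Windowed co-occurrence significance network
#'
#' Places an edge between two items when they co-occur within a positional
#' window across lists significantly more often than expected if responses
#' were ordered at random within each list.
#'
#' For each unordered item pair, the observed statistic is the number of
#' lists in which the two items appear within `window` positions of each
#' other (counted at most once per list). Under the null of uniformly
#' random within-list order, a list of length m containing both items
#' co-locates them within window w with probability
#' p = w(2m - w - 1) / (m(m - 1)). The co-occurrence count across
#' qualifying lists is then a sum of independent Bernoulli trials with
#' list-specific p (a Poisson-binomial variable, computed by exact
#' convolution); an edge is drawn when the upper-tail probability
#' P(C >= observed) falls below `alpha`. No multiple-comparison correction
#' is applied.
#'
#' @param data A `fluency_tbl`.
#' @param window Positive integer positional window (default 2).
#' @param alpha Significance level in (0, 1) (default 0.05). Edge sets are
#'   nested in `alpha`.
#' @return A [semantic_network()].
#' @export
estimate_conceptual_network <- function(data, window = 2, alpha = 0.05) {
  lists <- estimator_lists(data)
  if (!is.numeric(window) || length(window) != 1 || window < 1) {
    abort("`window` must be a positive integer")
  }
  window <- as.integer(window)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)")
  }
  nodes <- str_sort_c(unique(unlist(lists)))
  if (length(lists) > 0 && window >= max(lengths(lists)) - 1) {
    warn("`window` spans the longest list; all its co-listed pairs trivially co-occur and contribute no evidence")
  }
  # per-pair: observed co-occurrence count and null probabilities per list
  pair_key <- function(i, j) paste0(i, "\r", j)
  obs <- new.env(parent = emptyenv())
  probs <- new.env(parent = emptyenv())
  for (tok in lists) {
    m <- length(tok)
    items <- unique(tok)
    if (length(items) < 2 || m < 2) next
    p_l <- min(1, window * (2 * m - window - 1) / (m * (m - 1)))
    cmb <- combn(str_sort_c(items), 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      key <- pair_key(a, b)
      co <- min(abs(outer(which(tok == a), which(tok == b), "-"))) <= window
      obs[[key]] <- (obs[[key]] %||% 0L) + as.integer(co)
      probs[[key]] <- c(probs[[key]], p_l)
    }
  }
  edges <- NULL
  for (key in ls(obs)) {
    c_obs <- obs[[key]]
    if (c_obs == 0L) next
    tail_p <- poisson_binomial_tail(probs[[key]], c_obs)
    if (tail_p < alpha) {
      edges <- rbind(edges, strsplit(key, "\r", fixed = TRUE)[[1]])
    }
  }
  semantic_network(edges = edges, nodes = nodes)
}

# exact P(C >= c) for C a sum of independent Bernoulli(p) trials
poisson_binomial_tail <- function(p, c_obs) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  sum(pmf[(c_obs + 1):length(pmf)])
}
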