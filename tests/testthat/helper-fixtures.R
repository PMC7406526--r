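# Fixtures and independent oracles, all built in code.

# ---- worked-example list and scheme (three categories) ----

fig_tokens <- function() c("hamster", "cat", "dog", "wolf", "coyote", "zebra")

fig_scheme <- function() {
  tmp <- withr::local_tempfile(fileext = ".csv",
                               .local_envir = parent.frame())
  writeLines(c("Pets,hamster", "Pets,cat", "Pets,dog",
               "Canines,dog", "Canines,wolf", "Canines,coyote",
               "ZooAnimals,zebra"), tmp)
  read_scheme(tmp)
}

# scheme directly from a label -> members list, via a temp file
scheme_from_list <- function(categories) {
  tmp <- withr::local_tempfile(fileext = ".csv",
                               .local_envir = parent.frame())
  rows <- unlist(lapply(names(categories), function(lab) {
    paste0(lab, ",", categories[[lab]])
  }))
  writeLines(rows, tmp)
  read_scheme(tmp)
}

fluency_from_lists <- function(lists, hierarchical = FALSE) {
  rows <- purrr::imap(lists, function(tok, i) {
    tibble::tibble(id = sprintf("S%02d", i), listnum = 1L, item = tok)
  })
  as_fluency_data(dplyr::bind_rows(rows), hierarchical = hierarchical)
}

# ---- random generators ----

random_tokens <- function(n_tokens, vocab = letters[1:8]) {
  sample(vocab, n_tokens, replace = TRUE)
}

random_scheme <- function(vocab = letters[1:8], n_categories = 4) {
  labs <- paste0("C", seq_len(n_categories))
  categories <- lapply(labs, function(l) {
    sample(vocab, sample(2:length(vocab), 1))
  })
  names(categories) <- labs
  scheme_from_list(categories)
}

# connected labelled graph on n nodes, extra edges beyond a random tree
random_connected_network <- function(n, extra = 2, nodes = letters[1:n]) {
  edges <- NULL
  for (i in 2:n) {
    edges <- rbind(edges, c(nodes[i], nodes[sample.int(i - 1, 1)]))
  }
  all_pairs <- t(combn(nodes, 2))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  remaining <- all_pairs[!(key(all_pairs) %in% key(edges)), , drop = FALSE]
  extra <- min(extra, nrow(remaining))
  if (extra > 0) {
    pick <- remaining[sample.int(nrow(remaining), extra), , drop = FALSE]
    edges <- rbind(edges, pick)
  }
  semantic_network(edges)
}

# random symmetric weighted distance matrix; missing entries are Inf
random_distance_matrix <- function(n, p_edge = 0.7, weights = 1:6) {
  nodes <- letters[seq_len(n)]
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        w <- sample(weights, 1)
        d[i, j] <- w
        d[j, i] <- w
      }
    }
  }
  diag(d) <- 0
  d
}

# ---- oracle: union of all minimum spanning trees by enumeration ----

# enumerate every minimum spanning tree of each finite-weight component and
# take the union of their edges
brute_force_mst_union <- function(d) {
  nodes <- rownames(d)
  n <- length(nodes)
  fin <- is.finite(d) & upper.tri(d)
  eidx <- which(fin, arr.ind = TRUE)
  # components over finite edges
  comp <- seq_len(n)
  for (r in seq_len(nrow(eidx))) {
    a <- comp[eidx[r, 1]]; b <- comp[eidx[r, 2]]
    if (a != b) comp[comp == b] <- a
  }
  kept <- NULL
  for (c_id in unique(comp)) {
    members <- which(comp == c_id)
    if (length(members) < 2) next
    rows <- which(eidx[, 1] %in% members & eidx[, 2] %in% members)
    k <- length(members) - 1
    best <- Inf
    best_sets <- list()
    for (subset in combn(length(rows), k, simplify = FALSE)) {
      sel <- eidx[rows[subset], , drop = FALSE]
      # spanning tree test: k edges connecting all members
      cc <- members
      for (r in seq_len(nrow(sel))) {
        a <- cc[match(sel[r, 1], members)]
        b <- cc[match(sel[r, 2], members)]
        if (a != b) cc[cc == b] <- a
      }
      if (length(unique(cc)) != 1) next
      w <- sum(d[sel])
      if (w < best - 1e-12) {
        best <- w
        best_sets <- list(sel)
      } else if (abs(w - best) <= 1e-12) {
        best_sets <- c(best_sets, list(sel))
      }
    }
    for (sel in best_sets) kept <- rbind(kept, sel)
  }
  if (is.null(kept)) return(semantic_network(nodes = nodes))
  semantic_network(cbind(nodes[kept[, 1]], nodes[kept[, 2]]), nodes = nodes)
}

# ---- oracle: emission-sequence probability by bounded mass propagation ----

# Probability that a censored walk starting at seq[1] emits exactly the
# given sequence: iterate one walk step at a time, tracking the probability
# mass over current positions within the visited set; mass reaching the next
# target is banked, mass reaching any other unvisited node is discarded.
# Independent of the package's linear-system solution.
emission_prob_oracle <- function(net, tokens, max_steps = 5000, tol = 1e-13) {
  adj <- unclass(as.matrix(net))
  n <- nrow(adj)
  deg <- rowSums(adj)
  idx <- match(tokens, network_nodes(net))
  stopifnot(!anyNA(idx))
  prob <- 1
  visited <- rep(FALSE, n)
  visited[idx[1]] <- TRUE
  for (k in seq_along(idx)[-1]) {
    target <- idx[k]
    mass <- numeric(n)
    mass[idx[k - 1]] <- 1
    banked <- 0
    for (step in seq_len(max_steps)) {
      new_mass <- numeric(n)
      for (v in which(mass > 0)) {
        if (deg[v] == 0) next
        new_mass <- new_mass + mass[v] / deg[v] * adj[v, ]
      }
      banked <- banked + new_mass[target] * !visited[target]
      # unvisited non-target mass is absorbed elsewhere: discard
      new_mass[!visited] <- 0
      mass <- new_mass
      if (sum(mass) < tol) break
    }
    prob <- prob * unname(banked)
    if (prob == 0) return(0)
    visited[target] <- TRUE
  }
  prob
}

# all connected labelled graphs on the given nodes
all_connected_graphs <- function(nodes) {
  pairs <- t(combn(nodes, 2))
  out <- list()
  for (mask in seq_len(2^nrow(pairs)) - 1) {
    sel <- bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0
    net <- semantic_network(pairs[sel, , drop = FALSE], nodes = nodes)
    g <- igraph::graph_from_adjacency_matrix(as.matrix(net),
                                             mode = "undirected")
    if (igraph::components(g)$no == 1) out[[length(out) + 1]] <- net
  }
  out
}

# ---- oracle: cluster segmentation from first principles ----

# recompute the partition by scanning all candidate boundaries, deciding
# each from the raw definition (fluid: previous token; static: label
# intersection over the whole current run, recomputed from scratch)
brute_force_segments <- function(tokens, scheme, mode) {
  labelset <- function(t, i) {
    l <- if (scheme$kind == "letter-prefix") {
      substr(t, 1, scheme$prefix_length)
    } else {
      scheme$inverted[[t]]
    }
    if (is.null(l) || length(l) == 0) paste0("<unk>", i) else l
  }
  labs <- Map(labelset, tokens, seq_along(tokens))
  starts <- 1
  for (t in seq_along(tokens)[-1]) {
    if (mode == "fluid") {
      ok <- length(intersect(labs[[t]], labs[[t - 1]])) > 0
    } else {
      run <- labs[seq(from = tail(starts, 1), to = t)]
      ok <- length(Reduce(intersect, run)) > 0
    }
    if (!ok) starts <- c(starts, t)
  }
  ends <- c(starts[-1] - 1, length(tokens))
  Map(function(s, e) tokens[s:e], starts, ends)
}

edge_keys <- function(net) {
  e <- network_edges(net)
  paste(e$from, e$to)
}

planted_network_10 <- function(seed = 7) {
  withr::with_seed(seed, random_connected_network(10, extra = 6))
}
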