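test_that("first-edge and naive-random-walk networks follow their definitions", {
  fl <- fluency_from_lists(list(c("a", "b", "c"), c("c", "d", "a")))
  fe <- estimate_first_edge(fl)
  expect_setequal(edge_keys(fe), c("a b", "c d"))
  expect_setequal(network_nodes(fe), c("a", "b", "c", "d"))

  nrw <- estimate_naive_random_walk(fl)
  expect_setequal(edge_keys(nrw), c("a b", "b c", "c d", "a d"))

  # union across lists collapses duplicates
  fl2 <- fluency_from_lists(list(c("a", "b"), c("b", "c"), c("a", "b")))
  expect_setequal(edge_keys(estimate_naive_random_walk(fl2)),
                  c("a b", "b c"))

  # single-token list contributes its node only
  fl3 <- fluency_from_lists(list("a"))
  expect_equal(network_nodes(estimate_first_edge(fl3)), "a")
  expect_equal(nrow(network_edges(estimate_first_edge(fl3))), 0)

  # first-edge edges are always a subset of naive-random-walk edges
  withr::with_seed(4, {
    for (rep in 1:10) {
      lists <- replicate(4, unique(random_tokens(6)), simplify = FALSE)
      fl4 <- fluency_from_lists(lists)
      expect_true(all(edge_keys(estimate_first_edge(fl4)) %in%
                        edge_keys(estimate_naive_random_walk(fl4))))
    }
  })
})

test_that("positional distances average lags and mark never-co-listed pairs", {
  fl <- fluency_from_lists(list(c("a", "b", "c")))
  d <- pathfinder_distances(fl)
  expect_equal(d["a", "b"], 1)
  expect_equal(d["b", "c"], 1)
  expect_equal(d["a", "c"], 2)
  d2 <- pathfinder_distances(fluency_from_lists(list(c("a", "b"),
                                                     c("b", "a"))))
  expect_equal(d2["a", "b"], 1)
  d3 <- pathfinder_distances(fluency_from_lists(list(c("a", "b"),
                                                     c("c", "d"))))
  expect_true(is.infinite(d3["a", "c"]))
  expect_equal(diag(d3), setNames(rep(0, 4), rownames(d3)))
})

test_that("pathfinder keeps exactly the edges lying in some MST", {
  tri <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_setequal(edge_keys(mst_union(tri)), c("a b", "b c"))
  eq <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(eq) <- 0
  expect_setequal(edge_keys(mst_union(eq)), c("a b", "a c", "b c"))
  # tree-structured distances reproduce the tree
  tree <- matrix(Inf, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(tree) <- 0
  tree["a", "b"] <- tree["b", "a"] <- 1
  tree["b", "c"] <- tree["c", "b"] <- 2
  tree["b", "d"] <- tree["d", "b"] <- 5
  expect_setequal(edge_keys(mst_union(tree)), c("a b", "b c", "b d"))
})

test_that("pathfinder agrees with spanning-tree enumeration and ignores list order", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      d <- random_distance_matrix(sample(3:6, 1))
      expect_setequal(edge_keys(mst_union(d)),
                      edge_keys(brute_force_mst_union(d)))
    }
    lists <- replicate(5, unique(random_tokens(6)), simplify = FALSE)
    a <- estimate_pathfinder(fluency_from_lists(lists))
    b <- estimate_pathfinder(fluency_from_lists(rev(lists)))
    expect_setequal(edge_keys(a), edge_keys(b))
  })
})

test_that("correlation network thresholds presence-vector correlations", {
  # a and b present in exactly the same 2 of 4 lists: r = 1
  fl <- fluency_from_lists(list(c("a", "b", "x"), c("a", "b", "y"),
                                c("x", "y"), c("x", "y", "z")))
  suppressWarnings(net <- estimate_correlation_network(fl, threshold = 0.9))
  expect_true(has_edge(net, "a", "b"))
  # anti-aligned presence: r = -1, never an edge at positive thresholds
  expect_false(has_edge(net, "a", "z"))
  # zero-variance items are excluded with a warning but kept as nodes
  fl2 <- fluency_from_lists(list(c("a", "b"), c("a", "c")))
  expect_warning(net2 <- estimate_correlation_network(fl2), "zero-variance")
  expect_true("a" %in% network_nodes(net2))
  expect_equal(sum(as.matrix(net2)["a", ]), 0)
  expect_error(estimate_correlation_network(fluency_from_lists(list(c("a")))),
               "2 lists")
})

test_that("co-occurrence network matches the exact binomial tail", {
  # rotate 6 items through 10 lists of length 5 with a,b always adjacent:
  # per-list null probability 0.4, so P(C >= 10) = 0.4^10 < 0.05
  others <- c("u", "v", "w", "x")
  lists <- lapply(1:10, function(i) {
    fill <- rep(others, length.out = 3 + i)[(i):(i + 2)]
    c(fill[1], "a", "b", fill[2:3])
  })
  fl <- fluency_from_lists(lists)
  net <- estimate_conceptual_network(fl, window = 1, alpha = 0.05)
  expect_true(has_edge(net, "a", "b"))
  # a single adjacent co-listing: tail equals the per-list null, no edge
  fl2 <- fluency_from_lists(list(c("a", "b", "u", "v", "w"),
                                 c("u", "v", "w", "x", "y")))
  net2 <- estimate_conceptual_network(fl2, window = 1, alpha = 0.05)
  expect_false(has_edge(net2, "a", "b"))
  # window spanning the whole list: degenerate null, warned, no edges
  fl3 <- fluency_from_lists(list(c("a", "b", "c"), c("a", "c", "b")))
  expect_warning(net3 <- estimate_conceptual_network(fl3, window = 2), "window")
  expect_equal(nrow(network_edges(net3)), 0)
})

test_that("co-occurrence edge sets are nested in alpha", {
  withr::with_seed(13, {
    net0 <- random_connected_network(8, extra = 4)
    syn <- generate_synthetic_dataset(net0, 12, 1, emit_target = 8, seed = 5)
    alphas <- c(0.001, 0.01, 0.05, 0.2, 0.5)
    nets <- lapply(alphas, function(a)
      estimate_conceptual_network(syn, window = 2, alpha = a))
    for (i in seq_along(alphas)[-1]) {
      expect_true(all(edge_keys(nets[[i - 1]]) %in% edge_keys(nets[[i]])))
    }
  })
})

test_that("poisson binomial tail matches closed forms", {
  expect_equal(poisson_binomial_tail(rep(0.4, 10), 10), 0.4^10)
  expect_equal(poisson_binomial_tail(0.3, 1), 0.3)
  expect_equal(poisson_binomial_tail(c(0.2, 0.5), 0), 1)
  # binomial cross-check
  expect_equal(poisson_binomial_tail(rep(0.25, 8), 3),
               stats::pbinom(2, 8, 0.25, lower.tail = FALSE))
})

test_that("network statistics match enumeration on small graphs", {
  tri <- semantic_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  s <- network_statistics(tri)
  expect_equal(s$clustering_coefficient, 1)
  expect_equal(s$mean_degree, 2)
  expect_equal(s$mean_shortest_path, 1)
  expect_equal(s$n_components, 1L)

  path3 <- semantic_network(rbind(c("a", "b"), c("b", "c")))
  s2 <- network_statistics(path3)
  expect_equal(s2$clustering_coefficient, 0)
  expect_equal(s2$mean_degree, 4 / 3)
  expect_equal(s2$mean_shortest_path, 4 / 3)

  two <- semantic_network(rbind(c("a", "b"), c("c", "d")))
  s3 <- network_statistics(two)
  expect_equal(s3$n_components, 2L)
  expect_equal(s3$component_sizes[[1]], c(2L, 2L))

  expect_warning(empty <- network_statistics(semantic_network()), "empty")
  expect_equal(empty$n_nodes, 0L)
})

test_that("network statistics agree with hand computation on all 4-node graphs", {
  nodes <- letters[1:4]
  pairs <- t(combn(nodes, 2))
  hand_stats <- function(adj) {
    n <- nrow(adj)
    deg <- rowSums(adj)
    cc <- vapply(seq_len(n), function(v) {
      if (deg[v] < 2) return(0)
      nb <- which(adj[v, ] > 0)
      links <- sum(adj[nb, nb]) / 2
      links / choose(deg[v], 2)
    }, numeric(1))
    # Floyd-Warshall shortest paths
    dmat <- ifelse(adj > 0, 1, Inf)
    diag(dmat) <- 0
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
      dmat[i, j] <- min(dmat[i, j], dmat[i, k] + dmat[k, j])
    }
    list(mean_cc = mean(cc), dmat = dmat)
  }
  for (mask in seq_len(2^6) - 1) {
    sel <- bitwAnd(mask, 2^(0:5)) > 0
    net <- semantic_network(pairs[sel, , drop = FALSE], nodes = nodes)
    s <- network_statistics(net)
    adj <- unclass(as.matrix(net))
    h <- hand_stats(adj)
    expect_equal(s$clustering_coefficient, h$mean_cc)
    expect_equal(s$mean_degree, mean(rowSums(adj)))
    # largest-component mean path from the hand distance matrix
    comp_id <- apply(is.finite(h$dmat), 1, paste, collapse = "")
    comp_sizes <- table(comp_id)[unique(comp_id)]
    expect_equal(s$largest_component_size, max(as.integer(comp_sizes)))
    big <- names(which.max(table(comp_id)))
    members <- which(comp_id == big)
    if (length(members) > 1) {
      dd <- h$dmat[members, members]
      expect_equal(s$mean_shortest_path, mean(dd[upper.tri(dd)]))
    }
  }
})

test_that("category edge proportions sum to one and expose the intra fraction", {
  net <- semantic_network(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  labs <- c(a = "X", b = "X", c = "X", d = "Y")
  m <- category_edge_matrix(net, labs)
  expect_equal(attr(m, "intra_fraction"), 2 / 3)
  expect_equal(m["X", "X"] + m["X", "Y"], 1)
  # all edges intra
  m2 <- category_edge_matrix(net, c(a = "X", b = "X", c = "X", d = "X"))
  expect_equal(attr(m2, "intra_fraction"), 1)
  # perfect bipartite
  bip <- semantic_network(rbind(c("a", "c"), c("a", "d"),
                                c("b", "c"), c("b", "d")))
  m3 <- category_edge_matrix(bip, c(a = "X", b = "X", c = "Y", d = "Y"))
  expect_equal(attr(m3, "intra_fraction"), 0)
  expect_error(category_edge_matrix(net, c(a = "X", b = "X", c = "X")), "d")
})

test_that("edge-list export is canonical and import inverts it", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  net <- semantic_network(rbind(c("b", "a")))
  export_edge_list(net, tmp)
  expect_equal(readLines(tmp), "a,b")
  # isolated nodes survive the round trip via single-field rows
  net2 <- semantic_network(nodes = c("a", "b", "c"))
  export_edge_list(net2, tmp)
  expect_equal(import_edge_list(tmp)$nodes, c("a", "b", "c"))
  writeLines(c("a,b", "c,d,e"), tmp)
  expect_error(import_edge_list(tmp), "line 2")
  # identity on random graphs
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(3:8, 1)
      rnet <- random_connected_network(n, extra = sample(0:3, 1),
                                       nodes = sample(letters, n))
      export_edge_list(rnet, tmp)
      back <- import_edge_list(tmp)
      expect_identical(back$nodes, rnet$nodes)
      expect_identical(back$adj, rnet$adj)
    }
  })
})

test_that("all estimators return symmetric, self-loop-free networks", {
  withr::with_seed(17, {
    net0 <- random_connected_network(7, extra = 4)
    syn <- generate_synthetic_dataset(net0, 10, 1, emit_target = 6, seed = 2)
    nets <- list(
      estimate_first_edge(syn),
      estimate_naive_random_walk(syn),
      estimate_pathfinder(syn),
      suppressWarnings(estimate_correlation_network(syn, 0.3)),
      estimate_conceptual_network(syn),
      estimate_uinvite(syn, max_passes = 3, seed = 1)
    )
    for (net in nets) {
      a <- as.matrix(net)
      expect_true(isSymmetric(a))
      expect_equal(sum(diag(a)), 0)
      expect_equal(anyDuplicated(network_nodes(net)), 0)
    }
  })
})

test_that("tidy, glance and plots work on networks", {
  net <- semantic_network(rbind(c("a", "b"), c("b", "c")))
  td <- tidy(net)
  expect_equal(names(td), c("from", "to"))
  gl <- glance(net)
  expect_equal(gl$n_edges, 2L)
  expect_s3_class(autoplot(net), "ggplot")
  m <- category_edge_matrix(net, c(a = "X", b = "X", c = "Y"))
  expect_s3_class(plot_category_heatmap(m), "ggplot")
})
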