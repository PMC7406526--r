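#' Construct a semantic network
#'
#' A semantic network is an undirected, unweighted graph over item labels:
#' a symmetric binary adjacency relation with no self-edges. Node order is
#' canonical (radix-sorted labels) so that equal networks compare equal.
#'
#' @param edges Two-column character matrix / data frame of endpoint labels,
#'   or `NULL` for an edgeless network.
#' @param nodes Character vector of node labels; defaults to the labels
#'   occurring in `edges`. Extra labels become isolated nodes.
#' @return A `semantic_network` object with fields `nodes` (character) and
#'   `adj` (logical symmetric adjacency matrix with zero diagonal).
#' @examples
#' net <- semantic_network(rbind(c("dog", "cat"), c("cat", "fish")))
#' net
#' tidy(net)
#' @export
semantic_network <- function(edges = NULL, nodes = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (length(edges) == 0) {
      edges <- NULL
    } else if (ncol(edges) != 2) {
      abort("`edges` must have two columns")
    } else {
      mode(edges) <- "character"
    }
  }
  nodes <- str_sort_c(unique(c(nodes, as.character(edges))))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (!is.null(edges) && nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) abort("self-edges are not allowed")
    i <- match(edges[, 1], nodes)
    j <- match(edges[, 2], nodes)
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }
  new_semantic_network(nodes, adj)
}

new_semantic_network <- function(nodes, adj) {
  structure(list(nodes = nodes, adj = adj), class = "semantic_network")
}

check_network <- function(net) {
  if (!inherits(net, "semantic_network")) {
    abort("`net` must be a semantic_network")
  }
  invisible(net)
}

#' @export
print.semantic_network <- function(x, ...) {
  cat("<semantic_network> ", length(x$nodes), " nodes, ",
      n_network_edges(x), " edges\n", sep = "")
  invisible(x)
}

#' Nodes and edges of a semantic network
#'
#' @param net A `semantic_network`.
#' @return `network_nodes()`: character vector of labels.
#'   `network_edges()`: tibble with columns `from`, `to`, endpoints ordered
#'   alphabetically within each row, rows sorted.
#' @export
network_nodes <- function(net) {
  check_network(net)
  net$nodes
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  check_network(net)
  idx <- which(net$adj & upper.tri(net$adj), arr.ind = TRUE)
  out <- tibble::tibble(from = net$nodes[idx[, 1]], to = net$nodes[idx[, 2]])
  out[order(out$from, out$to, method = "radix"), , drop = FALSE]
}

n_network_edges <- function(net) sum(net$adj) / 2

#' Test for an edge
#'
#' @param net A `semantic_network`.
#' @param a,b Node labels.
#' @return Logical.
#' @export
has_edge <- function(net, a, b) {
  check_network(net)
  a %in% net$nodes && b %in% net$nodes && net$adj[a, b]
}

#' @export
as.matrix.semantic_network <- function(x, ...) {
  m <- x$adj
  mode(m) <- "integer"
  m
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(as.matrix(net), mode = "undirected")
}

#' @exportS3Method generics::tidy
tidy.semantic_network <- function(x, ...) network_edges(x)

#' @exportS3Method generics::glance
glance.semantic_network <- function(x, ...) {
  s <- network_statistics(x)
  s$component_sizes <- NULL
  s
}

#' Descriptive statistics of a semantic network
#'
#' Node and edge counts, mean degree, mean local clustering coefficient
#' (nodes of degree below two contribute zero), number and sizes of
#' connected components, and the mean shortest-path length over unordered
#' connected pairs within the largest component.
#'
#' @param net A `semantic_network`.
#' @return One-row tibble with columns `n_nodes`, `n_edges`, `mean_degree`,
#'   `clustering_coefficient`, `mean_shortest_path`, `n_components`,
#'   `largest_component_size`, and a list-column `component_sizes`.
#' @export
network_statistics <- function(net) {
  check_network(net)
  n <- length(net$nodes)
  if (n == 0) {
    warn("empty network: statistics are zero")
    return(tibble::tibble(n_nodes = 0L, n_edges = 0L, mean_degree = NA_real_,
                          clustering_coefficient = NA_real_,
                          mean_shortest_path = NA_real_, n_components = 0L,
                          largest_component_size = 0L,
                          component_sizes = list(integer(0))))
  }
  g <- as_igraph(net)
  m <- n_network_edges(net)
  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  comps <- igraph::components(g)
  sizes <- sort(as.integer(comps$csize), decreasing = TRUE)
  largest <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(g, which(comps$membership == largest))
  msp <- if (igraph::vcount(sub) > 1) {
    igraph::mean_distance(sub, directed = FALSE)
  } else {
    NA_real_
  }
  tibble::tibble(n_nodes = n, n_edges = as.integer(m),
                 mean_degree = 2 * m / n,
                 clustering_coefficient = mean(cc_local),
                 mean_shortest_path = msp,
                 n_components = as.integer(comps$no),
                 largest_component_size = max(sizes),
                 component_sizes = list(sizes))
}

#' Category-pair edge proportions
#'
#' Given one primary category per node, tabulates the proportion of edges
#' falling between each unordered pair of categories. The diagonal holds
#' intra-category proportions; their sum — the intra-category edge fraction
#' — is attached as attribute `intra_fraction`. Proportions over unordered
#' category pairs sum to one (the matrix is symmetric, with each
#' between-category proportion shown in both cells).
#'
#' @param net A `semantic_network`.
#' @param categories Named character vector mapping every node label to its
#'   primary category, or a data frame with columns `item` and `category`.
#' @return Symmetric numeric matrix (categories x categories) of edge
#'   proportions, with attribute `intra_fraction`.
#' @seealso [plot_category_heatmap()]
#' @export
category_edge_matrix <- function(net, categories) {
  check_network(net)
  if (is.data.frame(categories)) {
    categories <- setNames(as.character(categories$category),
                           as.character(categories$item))
  }
  missing_nodes <- setdiff(net$nodes, names(categories))
  if (length(missing_nodes) > 0) {
    abort(paste0("node(s) without a primary category: ",
                 paste(missing_nodes, collapse = ", ")))
  }
  cats <- str_sort_c(unique(unname(categories[net$nodes])))
  m <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  e <- network_edges(net)
  if (nrow(e) == 0) {
    warn("network has no edges; proportions are zero")
    attr(m, "intra_fraction") <- NA_real_
    return(m)
  }
  ca <- unname(categories[e$from])
  cb <- unname(categories[e$to])
  for (k in seq_along(ca)) {
    m[ca[k], cb[k]] <- m[ca[k], cb[k]] + 1
    if (ca[k] != cb[k]) m[cb[k], ca[k]] <- m[cb[k], ca[k]] + 1
  }
  m <- m / nrow(e)
  attr(m, "intra_fraction") <- sum(diag(m))
  m
}

#' Export a network as a canonical edge list
#'
#' One undirected edge per row (`a,b`, endpoints alphabetically ordered
#' within the row, rows sorted), followed by one single-field row per
#' isolated node so the node manifest survives a round trip.
#' [import_edge_list()] inverts the format exactly.
#'
#' @param net A `semantic_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(net, path) {
  check_network(net)
  e <- network_edges(net)
  deg <- rowSums(net$adj)
  isolated <- net$nodes[deg == 0]
  writeLines(c(paste(e$from, e$to, sep = ","), isolated), path)
  invisible(path)
}

#' @rdname export_edge_list
#' @return `import_edge_list()`: a `semantic_network`.
#' @export
import_edge_list <- function(path) {
  if (!file.exists(path)) abort(paste0("edge list file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) > 2)
  if (length(bad) > 0) {
    abort(paste0("malformed edge list row at line ", bad[1], ": ", lines[bad[1]]))
  }
  is_edge <- lengths(parts) == 2
  edges <- if (any(is_edge)) do.call(rbind, parts[is_edge]) else NULL
  nodes <- unlist(parts[!is_edge])
  semantic_network(edges = edges, nodes = nodes)
}

#' Export a network as a 0/1 adjacency matrix CSV
#'
#' Square matrix with node labels as header row and first column.
#'
#' @param net A `semantic_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_adjacency <- function(net, path) {
  check_network(net)
  m <- as.matrix(net)
  df <- tibble::as_tibble(m)
  df <- dplyr::bind_cols(tibble::tibble(node = rownames(m)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.semantic_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(name = object$nodes, x = xy[, 1], y = xy[, 2])
  e <- network_edges(object)
  e$x <- nodes$x[match(e$from, nodes$name)]
  e$y <- nodes$y[match(e$from, nodes$name)]
  e$xend <- nodes$x[match(e$to, nodes$name)]
  e$yend <- nodes$y[match(e$to, nodes$name)]
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -0.8,
                       size = 3) +
    ggplot2::theme_void()
}

#' Heatmap of category-pair edge proportions
#'
#' @param m Matrix from [category_edge_matrix()].
#' @return A ggplot object.
#' @export
plot_category_heatmap <- function(m) {
  df <- tibble::as_tibble(as.table(m), .name_repair = ~ c("from", "to", "prop"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "edge\nproportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
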