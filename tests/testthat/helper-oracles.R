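# Brute-force oracles and small graph builders shared across the suite.
# The oracles use matrix-power shortest-path counting and explicit double
# loops, independent of the package's (igraph-backed) implementations.

graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  nodes <- unique(as.vector(t(el)))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  igraph::add_edges(g, as.vector(t(el)))
}

# two triangles joined through a degree-2 bridge node x
k3_x_k3 <- function() {
  graph_from_pairs("a1","a2", "a1","a3", "a2","a3",
                   "b1","b2", "b1","b3", "b2","b3",
                   "x","a1", "x","b1")
}

path_abc <- function() graph_from_pairs("a","b", "b","c")

# Erdos-Renyi G(n, p) with character labels, no isolates guaranteed
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  nodes <- paste0("v", seq_len(n))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = nodes)
  if (nrow(keep) > 0) {
    g <- igraph::add_edges(g, as.vector(t(matrix(nodes[keep], ncol = 2))))
  }
  g
}

# shortest-path distance and count matrices via adjacency-matrix powers
sp_counts <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  dist <- matrix(Inf, n, n, dimnames = dimnames(A))
  sigma <- matrix(0, n, n, dimnames = dimnames(A))
  diag(dist) <- 0
  diag(sigma) <- 1
  Ak <- diag(n)
  for (k in seq_len(n)) {
    Ak <- Ak %*% A
    newly <- is.infinite(dist) & Ak > 0
    dist[newly] <- k
    sigma[newly] <- Ak[newly]
  }
  list(dist = dist, sigma = sigma)
}

bf_betweenness <- function(g, normalized = TRUE) {
  sp <- sp_counts(g)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  out <- setNames(numeric(n), nodes)
  for (v in nodes) {
    acc <- 0
    for (si in seq_len(n - 1)) for (ti in (si + 1):n) {
      s <- nodes[si]; t <- nodes[ti]
      if (s == v || t == v) next
      if (!is.finite(sp$dist[s, t])) next
      if (sp$dist[s, v] + sp$dist[v, t] == sp$dist[s, t]) {
        acc <- acc + sp$sigma[s, v] * sp$sigma[v, t] / sp$sigma[s, t]
      }
    }
    out[v] <- acc
  }
  if (normalized && n > 2) out <- out / ((n - 1) * (n - 2) / 2)
  out
}

bf_edge_betweenness <- function(g, normalized = TRUE) {
  sp <- sp_counts(g)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  el <- igraph::as_edgelist(g)
  flip <- el[, 1] > el[, 2]
  tmp <- el[flip, 1]; el[flip, 1] <- el[flip, 2]; el[flip, 2] <- tmp
  vals <- numeric(nrow(el))
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1]; w <- el[e, 2]
    acc <- 0
    for (si in seq_len(n)) for (ti in seq_len(n)) {
      if (ti <= si) next
      s <- nodes[si]; t <- nodes[ti]
      if (!is.finite(sp$dist[s, t])) next
      cnt <- 0
      if (sp$dist[s, u] + 1 + sp$dist[w, t] == sp$dist[s, t]) {
        cnt <- cnt + sp$sigma[s, u] * sp$sigma[w, t]
      }
      if (sp$dist[s, w] + 1 + sp$dist[u, t] == sp$dist[s, t]) {
        cnt <- cnt + sp$sigma[s, w] * sp$sigma[u, t]
      }
      acc <- acc + cnt / sp$sigma[s, t]
    }
    vals[e] <- acc
  }
  if (normalized && n > 1) vals <- vals / (n * (n - 1) / 2)
  data.frame(from = el[, 1], to = el[, 2], betweenness = vals,
             stringsAsFactors = FALSE)
}

# explicit double-loop modularity, independent of modularity_terms()
bf_modularity <- function(g, p) {
  m <- igraph::ecount(g)
  el <- igraph::as_edgelist(g)
  d <- igraph::degree(g)
  q <- 0
  for (ci in unique(unname(p))) {
    members <- names(p)[p == ci]
    e_in <- 0
    for (r in seq_len(nrow(el))) {
      if (el[r, 1] %in% members && el[r, 2] %in% members) e_in <- e_in + 1
    }
    dsum <- 0
    for (v in members) dsum <- dsum + d[[v]]
    q <- q + e_in / m - (dsum / (2 * m))^2
  }
  q
}

# random partition of a graph's nodes into up to k groups (all non-empty ids kept)
random_partition <- function(g, k, seed) {
  set.seed(seed)
  nodes <- igraph::V(g)$name
  as_partition(setNames(as.character(sample.int(k, length(nodes), replace = TRUE)),
                        nodes))
}

expect_valid_graph <- function(g) {
  testthat::expect_silent(validate_graph(g))
  nms <- igraph::V(g)$name
  deg <- igraph::degree(g)
  testthat::expect_equal(igraph::ecount(g), sum(deg) / 2)
}

karate_graph <- function() {
  read_edgelist(system.file("extdata", "karate.edgelist", package = "bridgecomm"))
}
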