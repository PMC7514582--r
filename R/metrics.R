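# Per-node, per-edge and per-partition quantities: Jaccard node similarity,
# betweenness and edge betweenness, bridging coefficient and centrality,
# clustering coefficient, Newman-Girvan modularity.

#' Jaccard similarity of two nodes' open neighbourhoods
#'
#' \deqn{sim(u,v) = |N(u) \cap N(v)| / |N(u) \cup N(v)|}
#'
#' Open neighbourhoods: the endpoints are not added to their own neighbour
#' sets, so for adjacent `u`, `v` each endpoint appears in the union through
#' the other's neighbourhood. Returns 0 when both neighbourhoods are empty.
#' A bridge-node whose neighbours share nothing with it scores 0 against each
#' of them — the signature of a disjunct node.
#'
#' @param g a graph.
#' @param u,v distinct node labels.
#' @return a number in \[0, 1\].
#' @export
jaccard_similarity <- function(g, u, v) {
  check_node(g, u); check_node(g, v)
  if (u == v) stop("u and v must be distinct", call. = FALSE)
  nu <- igraph::neighbors(g, u)$name
  nv <- igraph::neighbors(g, v)$name
  n_union <- length(union(nu, nv))
  if (n_union == 0) return(0)
  length(intersect(nu, nv)) / n_union
}

#' Betweenness centrality of all nodes
#'
#' Fraction of shortest paths between every other pair of nodes that pass
#' through each node, accumulated exactly (Brandes' algorithm). Pairs with no
#' connecting path contribute zero. When `normalized`, values are divided by
#' `(n-1)(n-2)/2`, the number of unordered pairs excluding the node itself.
#'
#' @param g a graph.
#' @param normalized divide by `(n-1)(n-2)/2`? Default `TRUE`.
#' @return named numeric vector over all nodes.
#' @export
node_betweenness <- function(g, normalized = TRUE) {
  validate_graph(g)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (normalized) {
    n <- igraph::vcount(g)
    if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  }
  b
}

#' Edge betweenness of all edges
#'
#' Fraction of shortest paths traversing each edge. When `normalized`, raw
#' path counts are divided by `n(n-1)/2`, the number of unordered node pairs.
#'
#' @param g a graph.
#' @param normalized divide by `n(n-1)/2`? Default `TRUE`.
#' @return data frame with columns `from`, `to` (with `from < to`
#'   lexicographically) and `betweenness`.
#' @export
edge_betweenness <- function(g, normalized = TRUE) {
  validate_graph(g)
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0) {
    flip <- el[, 1] > el[, 2]
    tmp <- el[flip, 1]
    el[flip, 1] <- el[flip, 2]
    el[flip, 2] <- tmp
  }
  if (normalized) {
    n <- igraph::vcount(g)
    if (n > 1) eb <- eb / (n * (n - 1) / 2)
  }
  data.frame(from = el[, 1], to = el[, 2], betweenness = eb,
             stringsAsFactors = FALSE)
}

#' Bridging coefficient
#'
#' \deqn{BC(v) = \frac{1/d(v)}{\sum_{i \in N(v)} 1/d(i)}}
#'
#' the ratio of a node's inverse degree to the sum of its neighbours' inverse
#' degrees. High values mark low-degree nodes surrounded by high-degree
#' neighbours — the local signature of a bridge. Defined as 0 for isolated
#' nodes. In a d-regular graph every node scores `1/d`.
#'
#' @param g a graph.
#' @param v optional single node label; when omitted all nodes are scored.
#' @return a number (single node) or named numeric vector (all nodes).
#' @export
bridging_coefficient <- function(g, v = NULL) {
  validate_graph(g)
  d <- igraph::degree(g)
  score_one <- function(u) {
    du <- d[[u]]
    if (du == 0) return(0)
    nb <- igraph::neighbors(g, u)$name
    (1 / du) / sum(1 / d[nb])
  }
  if (!is.null(v)) {
    check_node(g, v)
    return(score_one(v))
  }
  vapply(setNames(igraph::V(g)$name, igraph::V(g)$name), score_one, numeric(1))
}

#' Bridging centrality of all nodes
#'
#' The product of betweenness centrality and the bridging coefficient,
#' \eqn{CR(v) = CB(v) \times BC(v)}. Nodes with high bridging centrality sit
#' on many shortest paths *and* at local degree troughs: the bridge-nodes
#' joining modules. Because normalization rescales betweenness by a global
#' positive constant, the ranking (and therefore bridge-node selection) does
#' not depend on `normalized`; reported magnitudes do, so the convention is
#' recorded on the result.
#'
#' @param g a graph.
#' @param normalized normalize the betweenness factor? Default `TRUE`.
#' @return a data frame of class `centrality_scores` with columns `node`,
#'   `degree`, `betweenness`, `bridging_coefficient`, `bridging_centrality`,
#'   and attribute `normalized`.
#' @export
bridging_centrality <- function(g, normalized = TRUE) {
  cb <- node_betweenness(g, normalized = normalized)
  bc <- bridging_coefficient(g)
  nodes <- igraph::V(g)$name
  out <- data.frame(node = nodes,
                    degree = as.numeric(igraph::degree(g)[nodes]),
                    betweenness = as.numeric(cb[nodes]),
                    bridging_coefficient = as.numeric(bc[nodes]),
                    bridging_centrality = as.numeric(cb[nodes] * bc[nodes]),
                    stringsAsFactors = FALSE)
  attr(out, "normalized") <- normalized
  class(out) <- c("centrality_scores", "data.frame")
  out
}

#' Local clustering coefficient
#'
#' \deqn{Cl(v) = \frac{2L}{d_v (d_v - 1)}}
#'
#' where `L` is the number of edges among the `d_v` neighbours of `v`.
#' Defined as 0 for nodes of degree 0 or 1. The detector classifies a
#' single-node partition as disjunct when its clustering coefficient in the
#' original graph is 0 and as overlapping otherwise.
#'
#' @param g a graph.
#' @param v optional single node label; when omitted all nodes are scored.
#' @return a number in \[0, 1\] or a named numeric vector.
#' @export
clustering_coefficient <- function(g, v = NULL) {
  validate_graph(g)
  vids <- if (is.null(v)) igraph::V(g) else check_node(g, v)
  cl <- igraph::transitivity(g, type = "local", vids = vids, isolates = "zero")
  cl[is.nan(cl)] <- 0
  if (is.null(v)) setNames(cl, igraph::V(g)$name) else unname(cl)[1]
}

#' Newman-Girvan modularity with per-community terms
#'
#' For a partition into communities \eqn{C_i},
#' \deqn{Q = \sum_i (e_{ii} - a_i^2)}
#' where \eqn{e_{ii} = E_i / m} is the fraction of edges with both endpoints
#' inside \eqn{C_i} and \eqn{a_i = \sum_{v \in C_i} d_v / (2m)} is the
#' fraction of edge endpoints in \eqn{C_i}. Singleton communities contribute
#' \eqn{-a_i^2}.
#'
#' @param g a graph with at least one edge.
#' @param p a partition covering exactly `g`'s node set.
#' @return list of class `modularity_terms` with elements `terms` (data frame:
#'   `community`, `internal_edges`, `edge_fraction`, `degree_fraction`) and
#'   `modularity` (the scalar Q).
#' @examples
#' g <- bridge_fixture(3, 3)$graph
#' p <- as_partition(connected_components(remove_edge(remove_edge(g,
#'   "x", "a1"), "x", "b1")))
#' modularity_terms(g, p)$modularity
#' @export
modularity_terms <- function(g, p) {
  validate_graph(g)
  p <- as_partition(p)
  check_partition_covers(p, g)
  m <- igraph::ecount(g)
  if (m == 0) stop("modularity is undefined for an edgeless graph", call. = FALSE)
  d <- igraph::degree(g)
  el <- igraph::as_edgelist(g)
  comm_ids <- sort(unique(unname(p)))
  internal <- setNames(numeric(length(comm_ids)), comm_ids)
  intra <- p[el[, 1]] == p[el[, 2]]
  if (any(intra)) {
    cnt <- table(p[el[intra, 1]])
    internal[names(cnt)] <- as.numeric(cnt)
  }
  deg_sum <- vapply(comm_ids, function(ci) sum(d[names(p)[p == ci]]), numeric(1))
  e_ii <- internal / m
  a_i <- deg_sum / (2 * m)
  terms <- data.frame(community = comm_ids,
                      internal_edges = as.numeric(internal),
                      edge_fraction = as.numeric(e_ii),
                      degree_fraction = as.numeric(a_i),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, modularity = sum(e_ii - a_i^2)),
            class = "modularity_terms")
}

#' @export
print.modularity_terms <- function(x, ...) {
  cat(sprintf("Modularity Q = %.4f over %d communities\n",
              x$modularity, nrow(x$terms)))
  print(x$terms, row.names = FALSE)
  invisible(x)
}
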