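# Synthetic benchmark generators: planted bridge and overlap fixtures with
# known ground truth, and a planted-partition family with a tunable
# mixing parameter for detection-quality experiments.

make_clique <- function(labels) {
  if (length(labels) < 2) return(matrix(character(0), ncol = 2))
  t(combn(labels, 2))
}

graph_from_edge_matrix <- function(el, extra_nodes = character(0)) {
  nodes <- unique(c(as.vector(t(el)), extra_nodes))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  igraph::add_edges(g, as.vector(t(el)))
}

#' Planted bridge fixture: two cliques joined through a disjunct node
#'
#' Builds `K_k1 - x - K_k2`: two cliques (labels `a1..a<k1>`, `b1..b<k2>`)
#' and a bridge node `x` joined by one edge to `a1` and one to `b1`. The
#' planted node has degree 2, shares no neighbours with either neighbour
#' (zero Jaccard similarity on both edges), and has clustering coefficient 0:
#' the textbook disjunct node. `detect_multitype(graph, 3)` recovers the two
#' cliques as clusters and `x` as the sole neutral node.
#'
#' @param k1,k2 clique sizes, both >= 3.
#' @return list with `graph`, `truth` (partition of the clique nodes into
#'   communities `"A"` and `"B"`; the bridge is deliberately unassigned) and
#'   `planted_bridge` (`"x"`).
#' @export
bridge_fixture <- function(k1, k2) {
  if (k1 < 3 || k2 < 3) stop("clique sizes must be >= 3", call. = FALSE)
  a <- paste0("a", seq_len(k1))
  b <- paste0("b", seq_len(k2))
  el <- rbind(make_clique(a), make_clique(b), c("x", a[1]), c("x", b[1]))
  g <- validate_graph(graph_from_edge_matrix(el))
  truth <- as_partition(setNames(c(rep("A", k1), rep("B", k2)), c(a, b)))
  list(graph = g, truth = truth, planted_bridge = "x")
}

#' Planted overlap fixture: a node binding two cliques
#'
#' Two k-cliques `A` and `B` plus a node `v` adjacent to two *adjacent*
#' members of each clique (`a1`,`a2` and `b1`,`b2`). By construction `v` has
#' degree 4 with exactly two edges among its neighbours, so its clustering
#' coefficient is 1/3: when the detector isolates it, it is classified
#' overlapping, and [overlapped_communities()] recovers both cliques.
#'
#' @param k clique size, >= 4.
#' @return list with `graph`, `truth` (clique nodes in communities `"A"`,
#'   `"B"`; `v` unassigned) and `planted_overlap` (`"v"`).
#' @export
overlap_fixture <- function(k) {
  if (k < 4) stop("clique size must be >= 4", call. = FALSE)
  a <- paste0("a", seq_len(k))
  b <- paste0("b", seq_len(k))
  el <- rbind(make_clique(a), make_clique(b),
              c("v", a[1]), c("v", a[2]), c("v", b[1]), c("v", b[2]))
  g <- validate_graph(graph_from_edge_matrix(el))
  truth <- as_partition(setNames(c(rep("A", k), rep("B", k)), c(a, b)))
  list(graph = g, truth = truth, planted_overlap = "v")
}

# Draw community sizes from p(s) ~ s^-exponent truncated to
# [min_size, max_size]; any remainder smaller than min_size is distributed
# round-robin over the drawn communities (so a size may exceed max_size by a
# few nodes rather than a degenerate small community being created).
draw_power_law_sizes <- function(n_nodes, exponent, min_size, max_size) {
  if (min_size > n_nodes) stop("min_size exceeds n_nodes", call. = FALSE)
  support <- min_size:max_size
  probs <- support^(-exponent)
  sizes <- integer(0)
  while (sum(sizes) + min_size <= n_nodes) {
    s <- sample(support, 1, prob = probs)
    sizes <- c(sizes, min(s, n_nodes - sum(sizes)))
  }
  gap <- n_nodes - sum(sizes)
  if (gap > 0) {
    idx <- rep_len(seq_along(sizes), gap)
    for (i in idx) sizes[i] <- sizes[i] + 1L
  }
  sizes
}

#' Planted-partition benchmark graph with a mixing parameter
#'
#' Generates a graph of `n_nodes` nodes split into communities, with
#' `round(n_nodes * mean_degree / 2)` edges of which a fraction `mixing`
#' (the mixing parameter mu) run between communities and the rest inside
#' them. Each edge is placed by sampling a random node and then a random
#' partner inside (intra) or outside (inter) its community; self-edges and
#' duplicates are rejected and resampled. Community structure weakens as
#' `mixing` grows: detection quality against the returned ground truth is
#' essentially perfect for small mu and degrades beyond mu of roughly 0.3.
#'
#' All randomness flows from `seed`; repeated calls with the same arguments
#' return an identical graph. Node labels are `"1" .. "<n_nodes>"`.
#'
#' @param n_nodes total number of nodes.
#' @param mean_degree target average degree `<k>`.
#' @param mixing mu in \[0, 1): fraction of edges running between
#'   communities.
#' @param community_sizes explicit community sizes summing to `n_nodes`;
#'   overrides `n_communities`.
#' @param n_communities number of equal-sized communities (used when
#'   `community_sizes` is `NULL`; `n_nodes` must be divisible by it).
#' @param size_exponent optional power-law exponent: community sizes are
#'   drawn from `p(s) ~ s^-size_exponent` on `[min_size, max_size]` instead
#'   of being equal.
#' @param min_size,max_size size bounds for the power-law draw.
#' @param seed integer seed; the only source of randomness.
#' @return list with `graph` (all `n_nodes` present, including any that end
#'   up isolated), `truth` (the planted partition) and `spec` (the echoed
#'   parameters).
#' @export
planted_partition <- function(n_nodes, mean_degree, mixing,
                              community_sizes = NULL, n_communities = NULL,
                              size_exponent = NULL, min_size = NULL,
                              max_size = NULL, seed = 1L) {
  if (mixing < 0 || mixing >= 1) stop("mixing must be in [0, 1)", call. = FALSE)
  if ((1 - mixing) * mean_degree < 1) {
    stop("expected intra-community degree (1 - mixing) * mean_degree must be >= 1",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    if (is.null(community_sizes)) {
      if (!is.null(size_exponent)) {
        if (is.null(min_size) || is.null(max_size)) {
          stop("min_size and max_size are required with size_exponent", call. = FALSE)
        }
        community_sizes <- draw_power_law_sizes(n_nodes, size_exponent,
                                                min_size, max_size)
      } else {
        if (is.null(n_communities)) stop("give community_sizes or n_communities",
                                         call. = FALSE)
        if (n_nodes %% n_communities != 0) {
          stop("n_nodes must be divisible by n_communities", call. = FALSE)
        }
        community_sizes <- rep(n_nodes %/% n_communities, n_communities)
      }
    }
    if (sum(community_sizes) != n_nodes) {
      stop("community sizes must sum to n_nodes", call. = FALSE)
    }
    if (min(community_sizes) <= (1 - mixing) * mean_degree) {
      stop("infeasible: a community is not larger than the required intra-degree",
           call. = FALSE)
    }
    comm <- rep(seq_along(community_sizes), community_sizes)
    nodes <- as.character(seq_len(n_nodes))
    truth <- as_partition(setNames(as.character(comm), nodes))

    m <- round(n_nodes * mean_degree / 2)
    m_inter <- round(mixing * m)
    m_intra <- m - m_inter
    by_comm <- split(seq_len(n_nodes), comm)
    seen <- new.env(hash = TRUE, size = 2L * m)
    el <- matrix(0L, nrow = m, ncol = 2)
    draw <- function(intra) {
      repeat {
        u <- sample.int(n_nodes, 1)
        pool <- if (intra) by_comm[[comm[u]]] else seq_len(n_nodes)[comm != comm[u]]
        v <- pool[sample.int(length(pool), 1)]
        if (u == v) next
        key <- paste0(min(u, v), "_", max(u, v))
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        return(c(u, v))
      }
    }
    for (i in seq_len(m_intra)) el[i, ] <- draw(TRUE)
    for (i in seq_len(m_inter)) el[m_intra + i, ] <- draw(FALSE)

    el_chr <- matrix(as.character(el), ncol = 2)
    g <- validate_graph(graph_from_edge_matrix(el_chr, extra_nodes = nodes))
    list(graph = g, truth = truth,
         spec = list(n_nodes = n_nodes, mean_degree = mean_degree,
                     mixing = mixing, community_sizes = community_sizes,
                     size_exponent = size_exponent, seed = as.integer(seed)))
  })
}
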