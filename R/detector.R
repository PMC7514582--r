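# The divisive detection loop: iterative bridge-node selection by maximal
# bridging centrality, minimum-Jaccard edge cuts on the working graph, early
# stop at exactly P connected components, and classification of single-node
# partitions into disjunct (neutral) vs overlapping nodes.

# Eligibility: a neighbour is cut-eligible iff its degree in the working
# graph is >= 2 (degree-1 nodes are never cut off, so they cannot be mistaken
# for disjunct nodes); a candidate bridge-node needs >= 2 eligible
# neighbours, otherwise it is disqualified from selection.
eligible_neighbours <- function(g, v, deg = igraph::degree(g)) {
  nb <- igraph::neighbors(g, v)$name
  nb[deg[nb] >= 2]
}

#' Select the current bridge-node
#'
#' Returns the node with the maximal bridging centrality among nodes that
#' have at least two cut-eligible neighbours (neighbours of degree >= 2) in
#' the working graph. Ties are broken by the smallest node label, making the
#' whole detection loop deterministic. Returns `NULL` when no node qualifies.
#'
#' @param working the (possibly pruned) working graph.
#' @param normalized normalization flag forwarded to [bridging_centrality()];
#'   the selected node does not depend on it.
#' @return a node label, or `NULL`.
#' @export
select_bridge_node <- function(working, normalized = TRUE) {
  validate_graph(working)
  if (igraph::vcount(working) == 0) stop("empty graph", call. = FALSE)
  scores <- bridging_centrality(working, normalized = normalized)
  deg <- igraph::degree(working)
  n_elig <- vapply(scores$node,
                   function(v) length(eligible_neighbours(working, v, deg)),
                   integer(1))
  cand <- scores[n_elig >= 2, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  best <- cand$node[cand$bridging_centrality == max(cand$bridging_centrality)]
  sort(best)[1]
}

#' Minimum-similarity edge cut for a bridge-node
#'
#' Computes the Jaccard similarity between `bridge` and each of its
#' cut-eligible neighbours on the current working graph and returns the edges
#' attaining the minimum; all tied edges are returned, ordered by ascending
#' neighbour label. The caller removes them one at a time so that the
#' component count can be re-checked after every single removal.
#'
#' @param working the working graph.
#' @param bridge a node with at least one eligible neighbour.
#' @return data frame with columns `from` (the bridge), `to` (the neighbour)
#'   and `similarity`.
#' @export
min_similarity_cut <- function(working, bridge) {
  check_node(working, bridge)
  elig <- eligible_neighbours(working, bridge)
  if (length(elig) == 0) {
    stop(sprintf("node '%s' has no cut-eligible neighbour", bridge), call. = FALSE)
  }
  sims <- vapply(elig, function(x) jaccard_similarity(working, bridge, x),
                 numeric(1))
  keep <- sort(elig[sims == min(sims)])
  data.frame(from = bridge, to = keep, similarity = as.numeric(sims[keep]),
             stringsAsFactors = FALSE)
}

#' Classify single-node partitions
#'
#' A single-node partition is **neutral (disjunct)** when its clustering
#' coefficient in the original graph is 0 — none of its neighbours are
#' adjacent to each other, so it shares no nodes with any neighbour and
#' cannot join a community. It is **overlapping** when the coefficient is
#' positive — it has edges linking back to it through adjacent neighbours and
#' binds the communities those neighbours belong to.
#'
#' @param original the original (unpruned) graph.
#' @param singletons character vector of single-node partition labels.
#' @return list with sorted character vectors `neutral` and `overlapping`.
#' @export
classify_singletons <- function(original, singletons) {
  validate_graph(original)
  if (length(singletons) == 0) {
    return(list(neutral = character(0), overlapping = character(0)))
  }
  for (v in singletons) check_node(original, v)
  cl <- vapply(singletons, function(v) clustering_coefficient(original, v),
               numeric(1))
  list(neutral = sort(singletons[cl == 0]),
       overlapping = sort(singletons[cl > 0]))
}

#' Communities overlapped by an overlapping node
#'
#' The communities an overlapping node binds together: the final communities
#' (other than the node's own singleton) of the original-graph neighbours
#' with which the node *shares common nodes*, i.e. neighbours whose Jaccard
#' similarity with `v` in the original graph is positive. A neighbour that
#' shares nothing with `v` is a pure bridge attachment and does not make its
#' community an overlapped one — only the neighbours through which `v` could
#' form a community (those closing a triangle with it) count.
#'
#' @param original the original graph.
#' @param v an overlapping (single-node-partition) node.
#' @param p the final partition, covering all nodes.
#' @return sorted character vector of community ids.
#' @export
overlapped_communities <- function(original, v, p) {
  validate_graph(original)
  check_node(original, v)
  p <- as_partition(p)
  check_partition_covers(p, original)
  own <- p[[v]]
  if (sum(p == own) != 1) {
    stop(sprintf("node '%s' is not a single-node community", v), call. = FALSE)
  }
  nb <- igraph::neighbors(original, v)$name
  sharing <- nb[vapply(nb, function(u) jaccard_similarity(original, v, u) > 0,
                       logical(1))]
  setdiff(sort(unique(unname(p[sharing]))), own)
}

unreachable_error <- function(achieved, target) {
  stop(structure(class = c("bridgecomm_unreachable", "error", "condition"),
                 list(message = sprintf(
                   "target of %d partitions unreachable: no selectable bridge-node left at %d components",
                   target, achieved),
                   call = NULL, achieved = achieved, target = target)))
}

#' Detect multi-type nodes by divisive bridge-node cutting
#'
#' Runs the full detection loop on a working copy of `g`:
#'
#' 1. compute bridging centrality for all nodes of the working graph;
#' 2. select the bridge-node: maximal bridging centrality among nodes with
#'    at least two cut-eligible (degree >= 2) neighbours, smallest label on
#'    ties;
#' 3. compute the Jaccard similarity between the bridge-node and each
#'    eligible neighbour on the working graph, and remove the edges attaining
#'    the minimum similarity — one edge at a time in ascending neighbour
#'    order, re-counting connected components after every removal and
#'    stopping the loop the moment the count reaches `partitions`;
#' 4. repeat from 1.
#'
#' On termination the components of the working graph form the partition:
#' components of size > 1 are the **clusters** (disjoint nodes); single-node
#' components are classified by [classify_singletons()] on the original graph
#' into **neutral (disjunct)** and **overlapping** nodes. Modularity is
#' reported twice: `modularity` evaluates the final partition on the original
#' graph's edges and degrees, and `modularity_pruned` evaluates it on the
#' pruned working graph (whose inter-community edges have been removed), the
#' convention under which divisive methods usually print their scores.
#'
#' @param g the input graph (undirected, simple, named; at least one edge).
#' @param partitions target number of connected components P, counting
#'   singleton partitions; must be between the initial component count and
#'   the node count.
#' @param normalized betweenness normalization flag, recorded in the result;
#'   the detected partition does not depend on it.
#' @return an object of class `multitype_result`: list with elements
#'   `clusters` (list of sorted label vectors, size > 1), `neutral_nodes`,
#'   `overlapping_nodes`, `partition` (named community-id vector over all
#'   nodes), `modularity`, `modularity_pruned`, `steps` (data frame removal
#'   log: `iteration`, `bridge_node`, `bridge_score`, `neighbour`,
#'   `similarity`, `components_after`), `normalized`, `target_partitions`.
#' @examples
#' fx <- bridge_fixture(3, 3)
#' res <- detect_multitype(fx$graph, partitions = 3)
#' res$neutral_nodes # the planted bridge "x"
#' @export
detect_multitype <- function(g, partitions, normalized = TRUE) {
  validate_graph(g)
  n <- igraph::vcount(g)
  if (igraph::ecount(g) < 1) stop("graph has no edges", call. = FALSE)
  partitions <- as.integer(partitions)
  n0 <- igraph::count_components(g)
  if (partitions < n0) {
    stop(sprintf("partitions (%d) is below the initial component count (%d)",
                 partitions, n0), call. = FALSE)
  }
  if (partitions > n) {
    stop(sprintf("partitions (%d) exceeds the node count (%d)", partitions, n),
         call. = FALSE)
  }

  gw <- g
  steps <- list()
  iter <- 0L
  nc <- n0
  while (nc != partitions) {
    iter <- iter + 1L
    scores <- bridging_centrality(gw, normalized = normalized)
    deg <- igraph::degree(gw)
    n_elig <- vapply(scores$node,
                     function(v) length(eligible_neighbours(gw, v, deg)),
                     integer(1))
    cand <- scores[n_elig >= 2, , drop = FALSE]
    if (nrow(cand) == 0) unreachable_error(nc, partitions)
    best <- cand$node[cand$bridging_centrality == max(cand$bridging_centrality)]
    bri <- sort(best)[1]
    bri_score <- cand$bridging_centrality[cand$node == bri]
    cut <- min_similarity_cut(gw, bri)
    for (k in seq_len(nrow(cut))) {
      gw <- remove_edge(gw, bri, cut$to[k])
      nc <- igraph::count_components(gw)
      steps[[length(steps) + 1L]] <- data.frame(
        iteration = iter, bridge_node = bri, bridge_score = bri_score,
        neighbour = cut$to[k], similarity = cut$similarity[k],
        components_after = nc, stringsAsFactors = FALSE)
      if (nc == partitions) break
    }
  }

  comps <- connected_components(gw)
  partition <- as_partition(comps)
  singles <- unlist(comps[lengths(comps) == 1], use.names = FALSE)
  if (is.null(singles)) singles <- character(0)
  cls <- classify_singletons(g, singles)
  steps_df <- if (length(steps) > 0) do.call(rbind, steps) else
    data.frame(iteration = integer(0), bridge_node = character(0),
               bridge_score = numeric(0), neighbour = character(0),
               similarity = numeric(0), components_after = integer(0),
               stringsAsFactors = FALSE)

  structure(list(
    clusters = comps[lengths(comps) > 1],
    neutral_nodes = cls$neutral,
    overlapping_nodes = cls$overlapping,
    partition = partition,
    modularity = modularity_terms(g, partition)$modularity,
    modularity_pruned = if (igraph::ecount(gw) > 0)
      modularity_terms(gw, partition)$modularity else NA_real_,
    steps = steps_df,
    normalized = normalized,
    target_partitions = partitions
  ), class = "multitype_result")
}

#' @export
print.multitype_result <- function(x, ...) {
  cat(sprintf("Multi-type node detection: %d partitions (%d clusters, %d neutral, %d overlapping)\n",
              x$target_partitions, length(x$clusters),
              length(x$neutral_nodes), length(x$overlapping_nodes)))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  cluster %d (%d nodes): %s%s\n", i, length(x$clusters[[i]]),
                paste(head(x$clusters[[i]], 10), collapse = " "),
                if (length(x$clusters[[i]]) > 10) " ..." else ""))
  }
  if (length(x$neutral_nodes) > 0)
    cat("  neutral (disjunct):", paste(x$neutral_nodes, collapse = " "), "\n")
  if (length(x$overlapping_nodes) > 0)
    cat("  overlapping:", paste(x$overlapping_nodes, collapse = " "), "\n")
  cat(sprintf("  Q = %.4f on the original graph; %.4f on the pruned graph\n",
              x$modularity, x$modularity_pruned))
  cat(sprintf("  %d edges removed in %d iterations\n",
              nrow(x$steps), if (nrow(x$steps)) max(x$steps$iteration) else 0L))
  invisible(x)
}
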