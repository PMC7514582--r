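# Graph data type, invariant checks, component analysis, file I/O.
# Graphs are undirected simple igraph objects whose vertices carry character
# names; node labels from input files are preserved verbatim and never
# renumbered.

#' Validate the package's graph invariants
#'
#' Checks that `g` is an undirected, simple (no self-loops, no multi-edges)
#' igraph object with unique character vertex names. Every graph produced or
#' consumed by this package satisfies these invariants; the validator is run
#' by the test suite after each mutating operation.
#'
#' @param g an igraph object.
#' @return `g`, invisibly. Errors if an invariant is violated.
#' @export
validate_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("not an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("graph must be undirected", call. = FALSE)
  if (any(igraph::which_loop(g))) stop("graph contains self-loops", call. = FALSE)
  if (any(igraph::which_multiple(g))) stop("graph contains multi-edges", call. = FALSE)
  nms <- igraph::V(g)$name
  if (is.null(nms) || !is.character(nms)) {
    stop("graph vertices must carry character names", call. = FALSE)
  }
  if (anyDuplicated(nms)) stop("duplicate vertex names", call. = FALSE)
  invisible(g)
}

check_node <- function(g, v) {
  if (!v %in% igraph::V(g)$name) {
    stop(sprintf("unknown node '%s'", v), call. = FALSE)
  }
  invisible(v)
}

#' Read an undirected graph from a two-column edge list
#'
#' Each non-comment line holds at least two whitespace-separated tokens, the
#' endpoints of one undirected edge; extra tokens are ignored with a warning.
#' Duplicate edges (in either orientation) are collapsed. Node labels are kept
#' verbatim as strings. Isolated nodes can be declared on a header line of the
#' form `#nodes: a b c` (recognised only when the comment character is `#`).
#'
#' @param path path to the edge-list file.
#' @param comment_char single character starting comment lines (default `#`).
#' @return an undirected simple igraph object with named vertices.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c"), f)
#' g <- read_edgelist(f)
#' igraph::vcount(g) # 3
#' @export
read_edgelist <- function(path, comment_char = "#") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  declared <- character(0)
  edges <- matrix(character(0), ncol = 2)
  extra_seen <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (nchar(ln) == 0) next
    if (startsWith(ln, paste0(comment_char, "nodes:"))) {
      declared <- c(declared, strsplit(trimws(sub("^.nodes:", "", ln)), "\\s+")[[1]])
      next
    }
    if (startsWith(ln, comment_char)) next
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) < 2) {
      stop(sprintf("malformed line %d in %s: '%s'", i, path, ln), call. = FALSE)
    }
    if (length(toks) > 2) extra_seen <- TRUE
    if (toks[1] == toks[2]) {
      stop(sprintf("self-loop on line %d in %s: '%s'", i, path, ln), call. = FALSE)
    }
    edges <- rbind(edges, sort(toks[1:2]))
  }
  if (extra_seen) warning("extra tokens beyond the first two were ignored")
  edges <- unique(edges)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  nodes <- unique(c(as.vector(t(edges)), declared))
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  validate_graph(g)
}

#' Write a graph as a two-column edge list
#'
#' Inverse of [read_edgelist()]: emits one `u v` line per edge and a
#' `#nodes:` header naming isolated vertices so that reading the file back
#' reproduces the graph up to label ordering.
#'
#' @param g a validated graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  validate_graph(g)
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  el <- igraph::as_edgelist(g)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(iso) > 0) {
    writeLines(paste("#nodes:", paste(iso, collapse = " ")), con)
  }
  if (nrow(el) > 0) {
    writeLines(paste(el[, 1], el[, 2]), con)
  }
  invisible(path)
}

#' Read a graph from a GML file
#'
#' Minimal GML dialect: node `id`/`label` and edge `source`/`target` are
#' honoured; node labels become vertex names (falling back to the numeric id
#' when no label is present).
#'
#' @param path path to a GML file.
#' @return an undirected simple igraph object with named vertices.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  g <- igraph::read_graph(path, format = "gml")
  g <- igraph::as_undirected(g, mode = "collapse")
  nms <- igraph::vertex_attr(g, "label")
  if (is.null(nms)) nms <- igraph::vertex_attr(g, "id")
  if (is.null(nms)) nms <- seq_len(igraph::vcount(g)) - 1
  igraph::V(g)$name <- as.character(nms)
  g <- igraph::simplify(g)
  validate_graph(g)
}

#' Connected components, deterministically ordered
#'
#' Returns the connected components as a list of character vectors, sorted by
#' decreasing size, ties broken by the smallest contained label; nodes within
#' each component are sorted.
#'
#' @param g a graph.
#' @return a list of character vectors (possibly empty).
#' @export
connected_components <- function(g) {
  validate_graph(g)
  if (igraph::vcount(g) == 0) return(list())
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, function(x) sort(x))
  ord <- order(-lengths(comps), vapply(comps, `[`, "", 1))
  unname(comps[ord])
}

#' Remove one edge, keeping both endpoints
#'
#' The endpoints persist even if the removal leaves them with degree zero;
#' a fully cut node becomes its own single-node component.
#'
#' @param g a graph.
#' @param u,v endpoint labels of an existing edge.
#' @return the graph with the edge removed.
#' @export
remove_edge <- function(g, u, v) {
  check_node(g, u); check_node(g, v)
  eid <- igraph::get_edge_ids(g, c(u, v))
  if (eid == 0) stop(sprintf("no edge between '%s' and '%s'", u, v), call. = FALSE)
  igraph::delete_edges(g, eid)
}

# ---- partitions ------------------------------------------------------------

#' Construct a partition
#'
#' A partition is a named vector mapping node label to community id. This
#' helper canonicalises input given either as a named vector or as a list of
#' disjoint node sets (communities get ids `1, 2, ...` in list order).
#'
#' @param x named vector (node -> community id) or list of character vectors.
#' @return named character vector of community ids.
#' @export
as_partition <- function(x) {
  if (is.list(x)) {
    nodes <- unlist(x, use.names = FALSE)
    if (anyDuplicated(nodes)) stop("communities are not disjoint", call. = FALSE)
    ids <- rep(seq_along(x), lengths(x))
    x <- setNames(as.character(ids), nodes)
  }
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("partition must be a uniquely named vector", call. = FALSE)
  }
  setNames(as.character(x), names(x))
}

#' Community member sets of a partition
#'
#' @param p a partition ([as_partition()]).
#' @return named list: community id -> sorted character vector of members.
#' @export
partition_communities <- function(p) {
  p <- as_partition(p)
  lapply(split(names(p), p), sort)
}

check_partition_covers <- function(p, g) {
  nodes <- igraph::V(g)$name
  if (!setequal(names(p), nodes)) {
    stop("partition does not cover the graph's node set exactly", call. = FALSE)
  }
  invisible(p)
}

#' Read a node-to-community partition from TSV
#'
#' Expects two tab- (or whitespace-) separated columns: node label and
#' community id. Lines starting with `#` are skipped.
#'
#' @param path path to the partition file.
#' @return a partition (named character vector).
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2) stop("partition file needs two columns", call. = FALSE)
  as_partition(setNames(tab[[2]], tab[[1]]))
}

#' Write a partition as TSV
#'
#' @param p a partition.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  p <- as_partition(p)
  ord <- order(names(p))
  utils::write.table(data.frame(node = names(p)[ord], community = unname(p)[ord]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
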