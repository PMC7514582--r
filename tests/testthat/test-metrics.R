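test_that("jaccard similarity matches hand-derived neighbourhood overlaps", {
  # bridge node of K3-x-K3 shares no neighbours with either neighbour
  g <- k3_x_k3()
  expect_equal(jaccard_similarity(g, "x", "a1"), 0)
  expect_equal(jaccard_similarity(g, "x", "b1"), 0)

  # adjacent nodes of a triangle: N(a)={b,c}, N(b)={a,c} -> 1/3
  tri <- graph_from_pairs("a","b", "b","c", "c","a")
  expect_equal(jaccard_similarity(tri, "a", "b"), 1 / 3)

  # opposite corners of a 4-cycle have identical open neighbourhoods
  c4 <- graph_from_pairs("a","b", "b","c", "c","d", "d","a")
  expect_equal(jaccard_similarity(c4, "a", "c"), 1)

  expect_error(jaccard_similarity(tri, "a", "zz"), "unknown node")
  expect_error(jaccard_similarity(tri, "a", "a"), "distinct")
})

test_that("jaccard similarity is symmetric, bounded, and zero iff disjoint", {
  for (seed in 1:5) {
    g <- random_test_graph(9, 0.35, seed = seed)
    nodes <- igraph::V(g)$name
    for (pair in list(c(1, 2), c(3, 7), c(5, 9))) {
      u <- nodes[pair[1]]; v <- nodes[pair[2]]
      s <- jaccard_similarity(g, u, v)
      expect_identical(s, jaccard_similarity(g, v, u))
      expect_gte(s, 0); expect_lte(s, 1)
      nu <- igraph::neighbors(g, u)$name
      nv <- igraph::neighbors(g, v)$name
      expect_identical(s == 0, length(intersect(nu, nv)) == 0)
      expect_identical(s == 1,
                       setequal(nu, nv) && length(nu) > 0)
    }
  }
})

test_that("node betweenness matches hand examples and the path-count oracle", {
  p <- path_abc()
  expect_equal(node_betweenness(p)[["b"]], 1)
  star <- graph_from_pairs("c","l1", "c","l2", "c","l3", "c","l4")
  b <- node_betweenness(star)
  expect_equal(b[["c"]], 1)
  expect_equal(unname(b[c("l1", "l2", "l3", "l4")]), rep(0, 4))

  for (seed in 1:12) {
    g <- random_test_graph(sample(6:12, 1), stats::runif(1, 0.25, 0.5), seed = seed)
    for (norm in c(TRUE, FALSE)) {
      expect_equal(node_betweenness(g, normalized = norm),
                   bf_betweenness(g, normalized = norm), tolerance = 1e-10)
    }
  }
})

test_that("edge betweenness matches hand examples and the path-count oracle", {
  p <- path_abc()
  eb <- edge_betweenness(p)
  # edge (a,b) carries pairs (a,b) and (a,c), of 3 unordered pairs
  expect_equal(eb$betweenness[eb$from == "a" & eb$to == "b"], 2 / 3)

  # a bridge between two cliques ranks strictly highest
  g <- graph_from_pairs("a1","a2","a1","a3","a2","a3",
                        "b1","b2","b1","b3","b2","b3", "a1","b1")
  eb2 <- edge_betweenness(g)
  top <- eb2[which.max(eb2$betweenness), ]
  expect_equal(sort(c(top$from, top$to)), c("a1", "b1"))
  expect_true(max(eb2$betweenness[-which.max(eb2$betweenness)]) < top$betweenness)

  for (seed in 1:10) {
    g <- random_test_graph(sample(6:12, 1), stats::runif(1, 0.25, 0.5), seed = 100 + seed)
    got <- edge_betweenness(g)
    want <- bf_edge_betweenness(g)
    key <- function(df) df[order(df$from, df$to), ]
    expect_equal(key(got)$betweenness, key(want)$betweenness, tolerance = 1e-10)
  }
})

test_that("bridging coefficient matches hand-derived values", {
  p <- path_abc()
  expect_equal(bridging_coefficient(p, "b"), 0.25)  # (1/2)/(1+1)
  expect_equal(bridging_coefficient(p, "a"), 2.0)   # (1/1)/(1/2)

  # d-regular graphs: every node scores 1/d
  c5 <- graph_from_pairs("a","b","b","c","c","d","d","e","e","a")
  expect_equal(unname(bridging_coefficient(c5)), rep(0.5, 5))
  k4 <- graph_from_pairs("a","b","a","c","a","d","b","c","b","d","c","d")
  expect_equal(unname(bridging_coefficient(k4)), rep(1 / 3, 4))

  iso <- igraph::add_vertices(p, 1, name = "z")
  expect_equal(bridging_coefficient(iso, "z"), 0)
  expect_error(bridging_coefficient(p, "zz"), "unknown node")
})

test_that("bridging centrality is the product of its factors and flags the bridge", {
  g <- k3_x_k3()
  for (norm in c(TRUE, FALSE)) {
    sc <- bridging_centrality(g, normalized = norm)
    expect_equal(sc$bridging_centrality, sc$betweenness * sc$bridging_coefficient)
    expect_true(all(sc$bridging_centrality >= 0))
    expect_identical(attr(sc, "normalized"), norm)
    # argmax must not depend on the normalization convention
    expect_equal(sc$node[which.max(sc$bridging_centrality)], "x")
  }
  sc <- bridging_centrality(g)
  expect_true(all(sc$betweenness <= 1))
  # degree-1 leaves have zero betweenness hence zero bridging centrality
  p <- path_abc()
  scp <- bridging_centrality(p)
  expect_equal(scp$bridging_centrality[scp$node == "a"], 0)
  expect_equal(scp$bridging_centrality[scp$node == "b"], 0.25) # 1 * 0.25
})

test_that("clustering coefficient counts edges among neighbours", {
  tri <- graph_from_pairs("a","b", "b","c", "c","a")
  expect_equal(clustering_coefficient(tri, "a"), 1)
  expect_equal(clustering_coefficient(path_abc(), "b"), 0)
  expect_equal(clustering_coefficient(path_abc(), "a"), 0)  # degree 1 -> 0

  # v of the overlap fixture: degree 4, exactly 2 edges among neighbours
  of <- overlap_fixture(4)
  expect_equal(clustering_coefficient(of$graph, "v"), 1 / 3)
})

test_that("modularity matches hand counts, the double-loop oracle and igraph", {
  # a whole connected graph as one community scores 0
  g <- random_test_graph(8, 0.5, seed = 3)
  one <- as_partition(setNames(rep("c", 8), igraph::V(g)$name))
  expect_equal(modularity_terms(g, one)$modularity, 0)

  # two triangles joined by one edge, split into the triangles (m = 7)
  tt <- graph_from_pairs("a1","a2","a1","a3","a2","a3",
                         "b1","b2","b1","b3","b2","b3", "a1","b1")
  p <- as_partition(list(c("a1","a2","a3"), c("b1","b2","b3")))
  expect_equal(modularity_terms(tt, p)$modularity, 2 * (3 / 7 - (7 / 14)^2))

  # K3-x-K3 with the bridge as a singleton community (m = 8)
  kx <- k3_x_k3()
  p2 <- as_partition(list(c("a1","a2","a3"), c("b1","b2","b3"), "x"))
  mt <- modularity_terms(kx, p2)
  expect_equal(mt$modularity, 2 * (3 / 8 - (7 / 16)^2) - (2 / 16)^2)
  expect_equal(mt$modularity, 0.3515625)
  # singleton community contributes 0 internal edges
  expect_equal(mt$terms$internal_edges[mt$terms$community == "3"], 0)

  for (seed in 1:8) {
    g <- random_test_graph(9, 0.4, seed = 200 + seed)
    p <- random_partition(g, 3, seed = seed)
    mt <- modularity_terms(g, p)
    expect_equal(mt$modularity, bf_modularity(g, p), tolerance = 1e-12)
    expect_equal(mt$modularity,
                 igraph::modularity(g, as.integer(factor(p[igraph::V(g)$name]))),
                 tolerance = 1e-12)
    expect_lte(mt$modularity, 1)
    expect_equal(sum(mt$terms$degree_fraction), 1)
    expect_lte(sum(mt$terms$internal_edges), igraph::ecount(g))
  }

  expect_error(modularity_terms(g, as_partition(setNames("1", "v1"))), "cover")
})

test_that("on K3-x-K3, max edge betweenness and min similarity coincide at the bridge", {
  g <- k3_x_k3()
  sc <- bridging_centrality(g)
  bridge <- sc$node[which.max(sc$bridging_centrality)]
  expect_equal(bridge, "x")

  eb <- edge_betweenness(g)
  top_edge <- eb[which.max(eb$betweenness), ]
  expect_true(bridge %in% c(top_edge$from, top_edge$to))

  nb <- igraph::neighbors(g, bridge)$name
  sims <- vapply(nb, function(v) jaccard_similarity(g, bridge, v), numeric(1))
  bridge_edges <- eb[eb$from == bridge | eb$to == bridge, ]
  other <- ifelse(bridge_edges$from == bridge, bridge_edges$to, bridge_edges$from)
  # the node similarity of the bridge's edges orders inversely to their
  # edge betweenness: its minimum-similarity edges carry the maximum load
  expect_equal(sort(other[sims[other] == min(sims)]),
               sort(other[bridge_edges$betweenness == max(bridge_edges$betweenness)]))
})
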