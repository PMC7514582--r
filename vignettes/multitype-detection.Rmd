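---
title: "Multi-type node detection: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-type node detection: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgecomm)
```

## The problem

Most community-detection algorithms force every node of a network into some
community. Real interaction networks — protein–protein interaction graphs,
contact networks, co-occurrence networks — contain nodes that do not fit that
mould: *disjunct* (neutral) nodes that sit between modules without belonging
to any, and *overlapping* nodes that genuinely participate in two or more
modules at once. A protein that couples two complexes without being part of
either is a disjunct node; a protein shared by two complexes is an
overlapping one. `bridgecomm` detects and distinguishes all three node types
in one divisive pass.

## The model

The input is an undirected, unweighted, simple graph $G = (V, E)$ with
$n = |V|$ nodes and $m = |E|$ edges. Three per-node quantities drive the
algorithm.

**Betweenness centrality.** $C_B(v) = \sum_{s \neq v \neq t}
\rho_{st}(v) / \rho_{st}$, the fraction of shortest paths between every other
pair of nodes that pass through $v$, computed exactly (Brandes'
accumulation). When normalized — the default — it is divided by
$(n-1)(n-2)/2$, the number of unordered pairs excluding $v$.

**Bridging coefficient.** $BC(v) = \frac{1/d(v)}{\sum_{i \in N(v)} 1/d(i)}$,
the node's inverse degree relative to its neighbours' summed inverse degrees.
It is large for a low-degree node whose neighbours are high-degree — a node
sitting in a "degree trough" between dense regions. In any $d$-regular graph
it is $1/d$ everywhere.

**Bridging centrality.** $C_R(v) = C_B(v) \times BC(v)$. Betweenness alone
also ranks the *interiors* of large communities highly; the bridging
coefficient suppresses those and leaves the nodes that join modules. The node
maximising $C_R$ is the current *bridge-node*.

**Jaccard node similarity.** $sim(u, v) = |N(u) \cap N(v)| / |N(u) \cup
N(v)|$ over *open* neighbourhoods (a node is not a member of its own
neighbour set). Two nodes in the same dense module share many neighbours;
a bridge-node shares few or none with the far side. The similarity of 0 is
the signature of an edge that carries no community structure.

### The divisive loop

Given a target partition count $P$, the detector works on a pruned copy
$G'$ of the graph:

1. compute $C_R$ for every node of $G'$;
2. select the bridge-node: the maximiser of $C_R$ among nodes with at least
   two *cut-eligible* neighbours (ties: smallest label);
3. compute $sim$ between the bridge-node and each eligible neighbour on
   $G'$, and remove the edges attaining the minimum — one edge at a time,
   re-counting connected components after each removal and stopping the
   whole loop the instant the count reaches $P$;
4. repeat.

A neighbour is cut-eligible only if its degree in $G'$ is at least 2:
degree-1 nodes are never cut off, so genuine leaves cannot masquerade as
disjunct nodes. A node with fewer than two eligible neighbours is
disqualified from selection (cutting its single eligible edge could only
detach a pendant), and when no node qualifies before $P$ is reached the
detector raises a typed error stating the achieved component count — on some
networks there simply is a ceiling on how many partitions this divisive rule
can produce.

### Classification

When $G'$ has $P$ components, components of size greater than one are the
**clusters** (disjoint nodes). Each single-node component $v$ is classified
by its clustering coefficient $Cl(v) = 2L / (d_v(d_v - 1))$ in the
*original* graph ($L$ = edges among $v$'s neighbours; defined as 0 for
degree below 2):

* $Cl(v) = 0$ — **disjunct (neutral)**: none of $v$'s neighbours are
  adjacent, $v$ shares no common node with any neighbour, and every one of
  its edges had zero similarity. It bridges communities but belongs to none.
* $Cl(v) > 0$ — **overlapping**: at least two of $v$'s neighbours are
  mutually adjacent, so $v$ closes triangles into the surrounding
  communities and binds them. `overlapped_communities()` reports which:
  the final communities of the neighbours with which $v$ shares at least one
  common node (positive Jaccard similarity in the original graph). A
  neighbour that shares nothing with $v$ is a pure bridge attachment and
  does not make its community an overlapped one.

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| `partitions` (P) | `detect_multitype()` | — | target number of connected components, **counting** singleton partitions; the printed breakdown (clusters / neutral / overlapping) always sums to P |
| `normalized` | metrics, detector | `TRUE` | betweenness divisor $(n-1)(n-2)/2$ (nodes), $n(n-1)/2$ (edges); a global positive constant, so selection and the detected partition are invariant to it — only reported magnitudes change, and the flag is recorded in every result |
| `mixing` ($\mu$) | `planted_partition()` | — | fraction of edges placed *between* communities; structure weakens as $\mu$ grows |
| `mean_degree` | `planted_partition()` | — | average degree $\langle k \rangle$; feasibility requires $(1-\mu)\langle k \rangle \ge 1$ and every community larger than $(1-\mu)\langle k \rangle$ |
| `scheme` | `f1_vs_truth()` | `"arithmetic"` | how precision and recall combine into the reported F1 (see below) |

The choice of $P$ is the user's: the method deliberately exposes the
hierarchy, and different $P$ reveal sub-modular structure (an automatic
stopping rule is out of scope). Because the loop is deterministic and only
ever extends its removal sequence, the division at $P' > P$ contains the
division at $P$ as a prefix.

## Numerical and convention choices

* **Bridging-coefficient formula.** The defining ratio is read with $1/d(v)$
  in the numerator (the reciprocal, as in the bridging-centrality
  literature), not $d(v) - 1$.
* **Tie-breaks.** Equal bridging centrality: smallest node label wins. Equal
  minimum similarity: *all* tied edges are scheduled, but removed one at a
  time (ascending neighbour label) with the early stop at exactly $P$
  components — a simultaneous multi-edge cut could overshoot the component
  target, which the stopping test compares with equality. Similarities are
  not recomputed between the removals of one scheduled batch.
* **Two modularity conventions.** The result carries `modularity` — the
  Newman–Girvan $Q = \sum_i (e_{ii} - a_i^2)$ of the final partition
  (singletons included) evaluated on the **original** graph's edges and
  degrees — and `modularity_pruned`, the same partition evaluated on the
  pruned working graph. The original-graph value is comparable across
  algorithms; the pruned-graph value is the convention under which divisive
  methods often print their scores (removing inter-community edges shrinks
  $m$ and inflates the within-community edge fractions, which is why
  pruned-graph values can exceed a graph's ordinary modularity maximum).
  Reporting both, plus the full removal log, makes any published number
  diagnosable.
* **Degenerate inputs.** Pairs of nodes with no connecting path contribute 0
  to betweenness; the clustering coefficient of degree-0/1 nodes is 0; the
  Jaccard similarity of two nodes with empty neighbourhoods is 0; a node
  whose every edge is removed persists as a degree-0 single-node component.
  Modularity requires $m > 0$ and a partition covering the node set exactly.
* **NMI variant.** $2 I / (H_1 + H_2)$ (arithmetic-mean normalisation) from
  the label contingency table, natural logs; defined as 1 when both
  partitions are the trivial single community. Community ids are opaque —
  both NMI and F1 are invariant to relabeling.
* **F1 scheme.** Each detected community is matched to the truth community
  maximising set-wise F1 ($2|A \cap B|/(|A|+|B|)$); precision averages the
  best matches over detected communities, recall over truth communities. The
  reported F1 combines the two as their *arithmetic* mean by default (the
  harmonic combination is one flag away); the scheme used is recorded in the
  report, so comparisons are internally consistent either way.

## What the synthetic generators emulate — and what they do not

`bridge_fixture(k1, k2)` plants the canonical disjunct node: two cliques
joined through a degree-2 node `x` with zero similarity to both neighbours.
`overlap_fixture(k)` plants the canonical overlapping node: `v` attached to
two adjacent members of each of two cliques, giving $Cl(v) = 2 \cdot 2 /
(4 \cdot 3) = 1/3$ exactly. These fixtures have unambiguous ground truth and
are used as exhaustive recovery grids (clique sizes 3–8 and 4–8) in the
tests.

`planted_partition()` generates equal-sized (or power-law-sized) communities
and places $\text{round}(n \langle k \rangle / 2)$ edges, a fraction $\mu$
of them between communities, by rejection sampling; all randomness flows
from one seed. This is a deliberate desk-scale stand-in for full LFR
benchmarks: it reproduces the mixing-parameter semantics (detection quality
near-perfect for small $\mu$, degrading beyond $\mu \approx 0.3$) but its
degree distribution is binomial-like, not power-law, and community sizes are
controlled rather than drawn from a heavy tail. Passing the planted-partition
suite therefore demonstrates recovery under controlled mixing, not
performance on networks with hubs or strongly skewed module sizes.

The validation problem sizes are chosen to keep the whole suite exact and
fast on one CPU: oracle comparisons on random graphs of 6–12 nodes (where
brute-force shortest-path enumeration via matrix powers is feasible),
fixture grids up to 8-cliques, and planted partitions of 200 nodes in 10
communities of 20 at $\langle k \rangle = 10$ over 20 seeds per mixing
value.

## Known limitations

* Exact betweenness is recomputed on the working graph every iteration:
  $O(nm)$ per iteration and up to one iteration per removed edge. Small and
  medium networks (hundreds of nodes) run in seconds; very large networks
  are out of scope, as is approximate or sampled betweenness.
* The divisive rule can hit a ceiling: when every remaining candidate lacks
  two cut-eligible neighbours, larger $P$ values are unreachable and the
  detector says so rather than guessing.
* Overlapping nodes are reported as their own type together with the
  communities they bind; they are not multiply assigned into those
  communities (no fuzzy membership).
* Weighted, directed and multi-graphs are rejected at validation.
* Results depend on the stated tie-break conventions. Any implementation of
  this family of algorithms that breaks ties differently can produce a
  different (equally valid) removal sequence and hence different modularity
  values at the same $P$; the conventions are therefore embedded in every
  result file.

## A worked example

```{r karate}
karate <- read_edgelist(system.file("extdata", "karate.edgelist",
                                    package = "bridgecomm"))
res <- detect_multitype(karate, partitions = 3)
res
res$neutral_nodes
head(res$steps)
```

The friendship network of Zachary's karate club is the classic two-faction
benchmark. At `partitions = 3` the detector returns the two factions as
clusters plus one single-node partition — node `"9"`, whose clustering
coefficient in the original graph is 0 and whose every edge had zero
similarity: the member with neutral allegiance that hard-assignment methods
are known to misplace. Deeper in the hierarchy:

```{r karate6}
res6 <- detect_multitype(karate, partitions = 6)
res6$overlapping_nodes
overlapped_communities(karate, "28", res6$partition)
```

node `"28"` is isolated as well, but with positive clustering coefficient —
it is an overlapping node binding the two communities of its mutually
adjacent neighbours `"31"` and `"33"`.
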