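# Partition-comparison metrics: normalized mutual information and
# best-match F1 against a ground-truth partition.

#' Normalized mutual information between two partitions
#'
#' \deqn{NMI = \frac{2 I(P_1; P_2)}{H(P_1) + H(P_2)}}
#'
#' computed from the label contingency table, with natural-log entropies.
#' Identical partitions give 1; independent ones give 0. When both partitions
#' are the trivial single-community partition (both entropies 0) the value is
#' defined as 1.
#'
#' @param p1,p2 partitions ([as_partition()]) covering the same node set.
#' @return a number in \[0, 1\].
#' @export
nmi_partitions <- function(p1, p2) {
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  if (!setequal(names(p1), names(p2))) {
    stop("partitions cover different node sets", call. = FALSE)
  }
  p2 <- p2[names(p1)]
  n <- length(p1)
  joint <- table(p1, p2) / n
  r1 <- rowSums(joint); r2 <- colSums(joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h1 <- h(r1); h2 <- h(r2)
  if (h1 + h2 == 0) return(1)
  outer_p <- outer(r1, r2)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer_p[nz]))
  max(0, min(1, 2 * mi / (h1 + h2)))
}

set_f1 <- function(a, b) {
  i <- length(intersect(a, b))
  if (i == 0) return(0)
  2 * i / (length(a) + length(b))
}

#' Best-match F1 comparison against a ground-truth partition
#'
#' Each detected community is matched to the truth community maximising
#' their set-wise F1 score (`2|A intersect B| / (|A| + |B|)`); `precision` is
#' the mean best-match F1 over detected communities and `recall` the mean
#' over truth communities. The reported `f1` combines the two, by default as
#' their arithmetic mean; `scheme = "harmonic"` gives the conventional
#' harmonic combination instead. The scheme used is recorded in the report.
#' NMI between the two partitions is included for convenience.
#'
#' @param detected,truth partitions covering the same node set.
#' @param scheme how to combine precision and recall into `f1`:
#'   `"arithmetic"` (default) or `"harmonic"`.
#' @return list of class `comparison_report`: `nmi`, `f1`, `precision`,
#'   `recall`, `community_counts` (detected, truth), `f1_scheme`.
#' @export
f1_vs_truth <- function(detected, truth, scheme = c("arithmetic", "harmonic")) {
  scheme <- match.arg(scheme)
  detected <- as_partition(detected); truth <- as_partition(truth)
  if (!setequal(names(detected), names(truth))) {
    stop("partitions cover different node sets", call. = FALSE)
  }
  dc <- partition_communities(detected)
  tc <- partition_communities(truth)
  best_against <- function(a, fam) max(vapply(fam, set_f1, numeric(1), a = a))
  precision <- mean(vapply(dc, best_against, numeric(1), fam = tc))
  recall <- mean(vapply(tc, best_against, numeric(1), fam = dc))
  f1 <- if (scheme == "arithmetic") (precision + recall) / 2 else {
    if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  }
  structure(list(nmi = nmi_partitions(detected, truth), f1 = f1,
                 precision = precision, recall = recall,
                 community_counts = c(detected = length(dc), truth = length(tc)),
                 f1_scheme = scheme),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Partition comparison (%d detected vs %d truth communities)\n",
              x$community_counts[["detected"]], x$community_counts[["truth"]]))
  cat(sprintf("  NMI       %.4f\n", x$nmi))
  cat(sprintf("  precision %.4f\n  recall    %.4f\n  F1        %.4f (%s mean)\n",
              x$precision, x$recall, x$f1, x$f1_scheme))
  invisible(x)
}
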