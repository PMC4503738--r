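#' Louvain community detection
#'
#' Greedy modularity optimization implemented in this package (seeded,
#' restartable): repeated local moving of nodes followed by graph
#' aggregation. `level = "first_level"` returns the partition after the
#' first local-moving phase only — the intermediate solution that avoids
#' resolution-limit merging of small communities — while `"final"` returns
#' the fully aggregated optimum. With `restarts > 1` the node-visiting
#' order is reshuffled per restart and the best final-modularity partition
#' is kept.
#'
#' @param net A [weighted_network()] with at least one edge.
#' @param weighted If `TRUE` optimize weighted modularity; otherwise every
#'   edge counts 1.
#' @param level `"final"` or `"first_level"`.
#' @param restarts Number of seeded restarts (default 5).
#' @param seed Integer seed for the node shuffles.
#' @return An object of class `partition`: list with `membership` (integer
#'   labels 1..K for every node), `n_communities`, `modularity` (of the
#'   returned level, under the requested weighting), `level`, `weighted`.
#' @examples
#' net <- make_fixture("bridged_cliques", sizes = c(4, 4))
#' louvain_partition(net)$n_communities
#' @export
louvain_partition <- function(net, weighted = FALSE,
                              level = c("final", "first_level"),
                              restarts = 5, seed = 1) {
  level <- match.arg(level)
  if (!nrow(net$edges)) stop("cannot partition an edgeless graph",
                             call. = FALSE)
  ev <- edge_vectors(net)
  w <- if (weighted) ev$w else rep(1, length(ev$w))
  res <- cpp_louvain(net$n_nodes, ev$i, ev$j, w, as.integer(restarts), seed)
  memb <- if (level == "final") res$membership else res$first_level
  memb <- as.integer(factor(memb))   # relabel 1..K
  structure(list(membership = memb,
                 n_communities = max(memb),
                 modularity = modularity(net, memb, weighted = weighted),
                 level = level, weighted = weighted),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition (%s, %s): %d communities, Q = %.4f\n",
              x$level, if (x$weighted) "weighted" else "binary",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Newman modularity of a node partition
#'
#' `Q = sum_c [ L_c / m - (d_c / 2m)^2 ]` where, in binary mode, `L_c` is
#' the number of intra-community edges, `m` the total edge count and `d_c`
#' the total degree of community c; weighted mode replaces counts by weight
#' sums and degrees by strengths.
#'
#' @param net A [weighted_network()].
#' @param partition A `partition` object or an integer membership vector
#'   covering all nodes.
#' @param weighted Use edge weights instead of unit counts.
#' @return Modularity in `[-0.5, 1]`.
#' @export
modularity <- function(net, partition, weighted = FALSE) {
  memb <- if (inherits(partition, "partition")) partition$membership
          else as.integer(partition)
  stopifnot(length(memb) == net$n_nodes, !anyNA(memb))
  e <- net$edges
  w <- if (weighted) e$w else rep(1, nrow(e))
  m <- sum(w)
  if (m == 0) return(0)
  intra <- tapply(w[memb[e$i] == memb[e$j]],
                  memb[e$i][memb[e$i] == memb[e$j]], sum)
  d <- rowsum(c(w, w), memb[c(e$i, e$j)])   # community degree/strength
  q <- sum(intra) / m - sum((d / (2 * m))^2)
  as.numeric(q)
}

#' Intra-community weight homogeneity
#'
#' For every community with at least 2 internal edges, the relative
#' fluctuation `sigma_c / <w>_c` of its internal edge weights (population
#' standard deviation over mean). The aggregate is the unweighted mean over
#' eligible communities; it is scale-invariant under global weight
#' rescaling. A value below 1 indicates homogeneous within-community tie
#' strengths.
#'
#' @inheritParams modularity
#' @return An object of class `community_weight_stats`: data frame
#'   `per_community` (community, n_nodes, n_edges, mean_w, sd_w, rel_fluct)
#'   and scalar `aggregate`.
#' @export
intra_community_weight_fluctuation <- function(net, partition) {
  memb <- if (inherits(partition, "partition")) partition$membership
          else as.integer(partition)
  stopifnot(length(memb) == net$n_nodes)
  e <- net$edges
  intra <- memb[e$i] == memb[e$j]
  com <- memb[e$i][intra]
  w <- e$w[intra]
  if (!length(w)) stop("no community has internal edges", call. = FALSE)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  per <- do.call(rbind, lapply(split(w, com), function(v) {
    data.frame(n_edges = length(v), mean_w = mean(v), sd_w = pop_sd(v))
  }))
  per$community <- as.integer(rownames(per))
  per$n_nodes <- as.integer(table(factor(memb,
                                         levels = per$community))[
                                           as.character(per$community)])
  per$rel_fluct <- ifelse(per$n_edges >= 2, per$sd_w / per$mean_w, NA_real_)
  eligible <- per$n_edges >= 2
  if (!any(eligible))
    stop("no community has >= 2 internal edges", call. = FALSE)
  structure(list(per_community = per[, c("community", "n_nodes", "n_edges",
                                         "mean_w", "sd_w", "rel_fluct")],
                 aggregate = mean(per$rel_fluct[eligible])),
            class = "community_weight_stats")
}

#' @export
print.community_weight_stats <- function(x, ...) {
  cat(sprintf("community weight stats: %d communities, aggregate sigma/mean = %.4f\n",
              nrow(x$per_community), x$aggregate))
  invisible(x)
}

#' Mean intra-community weight versus community size
#'
#' Returns per-community pairs `(n, <w>_c)` and the through-origin
#' least-squares fit of `<w>_c` against `1/(n - 1)`, whose prefactor `a`
#' the aging model's mean-field theory predicts to be `6 delta / (1 - f)`
#' (see [clique_equilibrium_weight()]). The fit is flagged degenerate when
#' all communities have the same size.
#'
#' @inheritParams modularity
#' @return List with `per_community` data frame (community, n, mean_w),
#'   `prefactor` a, `residuals`, and logical `degenerate`.
#' @export
community_weight_vs_size <- function(net, partition) {
  memb <- if (inherits(partition, "partition")) partition$membership
          else as.integer(partition)
  e <- net$edges
  intra <- memb[e$i] == memb[e$j]
  com <- memb[e$i][intra]
  w <- e$w[intra]
  if (!length(w)) stop("no community has internal edges", call. = FALSE)
  mean_w <- tapply(w, com, mean)
  cid <- as.integer(names(mean_w))
  n <- as.integer(table(factor(memb, levels = cid))[as.character(cid)])
  keep <- n >= 2
  per <- data.frame(community = cid[keep], n = n[keep],
                    mean_w = as.numeric(mean_w)[keep])
  if (nrow(per) < 2)
    stop("need >= 2 communities with internal edges", call. = FALSE)
  x <- 1 / (per$n - 1)
  a <- sum(x * per$mean_w) / sum(x^2)
  list(per_community = per, prefactor = a,
       residuals = per$mean_w - a * x,
       degenerate = length(unique(per$n)) < 2)
}

#' Weighted link communities
#'
#' Groups edges (not nodes) into communities: the similarity of two edges
#' sharing a node is the Tanimoto coefficient of the non-shared endpoints'
#' inclusive weighted neighbour vectors (the self-entry is set to the mean
#' weight of the node's incident ties); binary mode uses the Jaccard index
#' of inclusive neighbourhoods. Edges are agglomerated by single linkage in
#' decreasing similarity order and the dendrogram is cut where the partition
#' density D is maximal (ties broken toward fewer communities). Edges with
#' no similar partner stay singleton communities.
#'
#' @param net A [weighted_network()] with at least 2 edges.
#' @param weighted Use the weighted (Tanimoto) similarity.
#' @return An object of class `link_community_result`: `edge_membership`
#'   (label per edge, aligned with `net$edges`), `node_counts` and
#'   `edge_counts` per community, `partition_density`, `cut_height`, and the
#'   scanned `(height, D)` sequence in `scan`.
#' @export
link_communities <- function(net, weighted = TRUE) {
  if (nrow(net$edges) < 2) stop("need at least 2 edges", call. = FALSE)
  ev <- edge_vectors(net)
  res <- cpp_link_communities(net$n_nodes, ev$i, ev$j, ev$w, weighted)
  structure(list(edge_membership = res$labels,
                 node_counts = res$node_counts,
                 edge_counts = res$edge_counts,
                 partition_density = res$D,
                 cut_height = res$height,
                 scan = data.frame(height = res$scan_height,
                                   D = res$scan_D),
                 weighted = weighted),
            class = "link_community_result")
}

#' @export
print.link_community_result <- function(x, ...) {
  cat(sprintf("link communities: %d communities, D = %.4f at height %.4f\n",
              length(x$node_counts), x$partition_density, x$cut_height))
  invisible(x)
}

#' Size distribution of link communities
#'
#' Distribution of the number of distinct nodes per link community.
#'
#' @param result A [link_communities()] result.
#' @return A [dist_estimate()] over community node counts.
#' @export
link_community_size_distribution <- function(result) {
  sizes <- result$node_counts
  if (!length(sizes)) stop("empty link-community result", call. = FALSE)
  ct <- tabulate(sizes, nbins = max(sizes))
  keep <- ct > 0
  dist_estimate((1:max(sizes))[keep], ct[keep] / length(sizes), ct[keep],
                mode = "discrete")
}
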