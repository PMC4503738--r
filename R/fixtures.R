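#' Deterministic fixture graphs
#'
#' Small graphs used as test oracles and worked examples:
#' * `clique`: one clique of size `sizes[1]` with uniform weight.
#' * `bridged_cliques`: two cliques of sizes `sizes[1]`, `sizes[2]` joined
#'   by a single bridge of strictly minimal weight.
#' * `star`: a hub with `sizes[1]` leaves.
#' * `ring`: a cycle of `sizes[1]` nodes.
#' * `planted_weight_cliques`: disjoint cliques of the given sizes with
#'   uniform internal weight `prefactor / (n - 1)` — an exact 1/(n-1)
#'   weight–size collapse for the community-weight fit oracle.
#'
#' @param kind Fixture kind (see above).
#' @param sizes Integer size parameter(s).
#' @param weight Uniform edge weight (clique, star, ring and the clique part
#'   of `bridged_cliques`).
#' @param bridge_weight Weight of the bridge; must be strictly below
#'   `weight`.
#' @param prefactor Prefactor of the planted `1/(n-1)` weights.
#' @return A [weighted_network()].
#' @examples
#' edge_count(make_fixture("clique", 5))         # 10
#' edge_count(make_fixture("bridged_cliques", c(5, 5)))  # 21
#' @export
make_fixture <- function(kind = c("clique", "bridged_cliques", "star",
                                  "ring", "planted_weight_cliques"),
                         sizes, weight = 1, bridge_weight = weight / 2,
                         prefactor = 60) {
  kind <- match.arg(kind)
  clique_edges <- function(nodes, w) {
    if (length(nodes) < 2) return(NULL)
    pr <- t(utils::combn(nodes, 2))
    data.frame(i = pr[, 1], j = pr[, 2], w = w)
  }
  switch(kind,
    clique = {
      stopifnot(sizes[1] >= 2)
      weighted_network(clique_edges(seq_len(sizes[1]), weight), sizes[1])
    },
    bridged_cliques = {
      stopifnot(length(sizes) >= 2, sizes[1] >= 2, sizes[2] >= 2,
                bridge_weight < weight, bridge_weight > 0)
      n1 <- sizes[1]; n2 <- sizes[2]
      e <- rbind(clique_edges(seq_len(n1), weight),
                 clique_edges(n1 + seq_len(n2), weight),
                 data.frame(i = n1, j = n1 + 1L, w = bridge_weight))
      weighted_network(e, n1 + n2)
    },
    star = {
      stopifnot(sizes[1] >= 1)
      weighted_network(data.frame(i = 1L, j = 1L + seq_len(sizes[1]),
                                  w = weight), sizes[1] + 1L)
    },
    ring = {
      n <- sizes[1]
      stopifnot(n >= 3)
      weighted_network(data.frame(i = seq_len(n), j = c(2:n, 1L), w = weight),
                       n)
    },
    planted_weight_cliques = {
      stopifnot(all(sizes >= 2))
      off <- c(0L, cumsum(sizes))
      e <- do.call(rbind, lapply(seq_along(sizes), function(t) {
        clique_edges(off[t] + seq_len(sizes[t]), prefactor / (sizes[t] - 1))
      }))
      weighted_network(e, sum(sizes))
    })
}
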