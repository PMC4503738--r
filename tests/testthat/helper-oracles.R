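# Brute-force oracles by direct set arithmetic, independent of the package's
# sparse-matrix / C++ code paths. Only meant for graphs of <= ~8 nodes.

oracle_neighbors <- function(net, i) {
  e <- net$edges
  sort(c(e$j[e$i == i], e$i[e$j == i]))
}

oracle_local_clustering <- function(net, i) {
  nb <- oracle_neighbors(net, i)
  k <- length(nb)
  if (k < 2) return(0)
  links <- 0
  for (a in seq_len(k - 1))
    for (b in (a + 1):k)
      if (nb[b] %in% oracle_neighbors(net, nb[a])) links <- links + 1
  links / (k * (k - 1) / 2)
}

oracle_overlap <- function(net, i, j) {
  ni <- oracle_neighbors(net, i)
  nj <- oracle_neighbors(net, j)
  nij <- length(intersect(ni, nj))
  den <- (length(ni) - 1) + (length(nj) - 1) - nij
  if (den <= 0) 0 else nij / den
}

oracle_knn <- function(net, i) {
  nb <- oracle_neighbors(net, i)
  mean(vapply(nb, function(j) length(oracle_neighbors(net, j)), numeric(1)))
}

oracle_modularity <- function(net, memb, weighted = FALSE) {
  n <- net$n_nodes
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(net$edges))) {
    w <- if (weighted) net$edges$w[r] else 1
    A[net$edges$i[r], net$edges$j[r]] <- w
    A[net$edges$j[r], net$edges$i[r]] <- w
  }
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  q / m2
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (lab in seq_len(maxlab + 1))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(), 0L)
  out
}

oracle_best_modularity <- function(net, weighted = FALSE) {
  best <- -Inf
  for (memb in all_partitions(net$n_nodes)) {
    q <- oracle_modularity(net, memb, weighted)
    if (q > best) best <- q
  }
  best
}

# relative LCC size after deleting `removed` edge rows, by plain BFS
oracle_rlcc <- function(net, removed) {
  e <- net$edges[setdiff(seq_len(nrow(net$edges)), removed), ]
  n <- net$n_nodes
  nb <- rep(list(integer()), n)
  for (r in seq_len(nrow(e))) {
    nb[[e$i[r]]] <- c(nb[[e$i[r]]], e$j[r])
    nb[[e$j[r]]] <- c(nb[[e$j[r]]], e$i[r])
  }
  seen <- logical(n)
  best <- 1L
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      for (u in nb[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
    }
    best <- max(best, size)
  }
  best / n
}

# small fixture set shared by the oracle-equivalence tests
small_fixtures <- function() {
  tri_pendant <- weighted_network(
    data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 3, 4), w = c(1, 2, 3, 4)), 4)
  two_triangles <- weighted_network(
    data.frame(i = c(1, 1, 2, 4, 4, 5), j = c(2, 3, 3, 5, 6, 6), w = 1), 6)
  bowtie <- weighted_network(
    data.frame(i = c(1, 1, 2, 3, 3, 4), j = c(2, 3, 3, 4, 5, 5),
               w = c(2, 1, 1, 1, 3, 1)), 5)
  set.seed(42)
  rnd <- list()
  for (t in 1:3) {
    n <- 7 + (t %% 2)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (sum(keep) < 2) keep[1:2] <- TRUE
    rnd[[t]] <- weighted_network(
      data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                 w = round(runif(sum(keep), 0.5, 4), 2)), n)
  }
  c(list(tri_pendant = tri_pendant, two_triangles = two_triangles,
         bowtie = bowtie, clique4 = make_fixture("clique", 4),
         star4 = make_fixture("star", 4), ring6 = make_fixture("ring", 6),
         bridged = make_fixture("bridged_cliques", c(4, 3))),
    setNames(rnd, paste0("random", 1:3)))
}
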