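test_that("Louvain recovers planted communities on canonical fixtures", {
  two_tri <- small_fixtures()$two_triangles
  part <- louvain_partition(two_tri, seed = 1)
  expect_equal(part$n_communities, 2L)
  expect_equal(part$modularity, 0.5)
  expect_equal(length(unique(part$membership[1:3])), 1L)
  expect_equal(length(unique(part$membership[4:6])), 1L)
  expect_equal(louvain_partition(make_fixture("clique", 6))$n_communities, 1L)
  expect_error(louvain_partition(empty_network(4)), "edgeless")
})

test_that("modularity matches the direct null-model formula", {
  nets <- small_fixtures()
  for (nm in names(nets)) {
    net <- nets[[nm]]
    memb_one <- rep(1L, net$n_nodes)
    expect_equal(modularity(net, memb_one), 0, info = nm)
    set.seed(7)
    for (t in 1:5) {
      memb <- sample(1:3, net$n_nodes, replace = TRUE)
      expect_equal(modularity(net, memb), oracle_modularity(net, memb),
                   info = nm)
      expect_equal(modularity(net, memb, weighted = TRUE),
                   oracle_modularity(net, memb, weighted = TRUE), info = nm)
    }
  }
})

test_that("Louvain attains the exhaustive-search optimum on small graphs", {
  nets <- small_fixtures()
  for (nm in c("two_triangles", "tri_pendant", "bowtie", "bridged",
               "random1", "random2")) {
    net <- nets[[nm]]
    part <- louvain_partition(net, restarts = 8, seed = 3)
    best <- oracle_best_modularity(net)
    expect_equal(part$modularity, best, tolerance = 1e-12, info = nm)
    # no label permutation can beat the optimum
    set.seed(11)
    for (t in 1:10) {
      memb <- sample(1:4, net$n_nodes, replace = TRUE)
      expect_lte(modularity(net, memb), best + 1e-12)
    }
  }
})

test_that("our Louvain agrees with igraph on a larger graph", {
  skip_if_not_installed("igraph")
  p <- model_params(300, "AGING", aging_factor = 0.9, w_th = 0.01,
                    p_r = 0.005, steps = 1500, seed = 5)
  net <- run_simulation(p)$network
  part <- louvain_partition(net, restarts = 5, seed = 1)
  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, net$n_nodes - igraph::vcount(g))
  ref <- igraph::cluster_louvain(g)
  expect_equal(part$modularity, igraph::modularity(ref), tolerance = 0.02)
})

test_that("intra-community weight fluctuation follows its definition", {
  # one community with internal weights {1, 3}: population sd 1, mean 2
  net <- weighted_network(
    data.frame(i = c(1, 1, 2, 4), j = c(2, 3, 3, 5), w = c(1, 3, 2, 9)), 5)
  memb <- c(1, 1, 1, 2, 2)
  # community 1 weights {1,3,2}: mean 2, pop sd sqrt(2/3)
  fl <- intra_community_weight_fluctuation(net, memb)
  expect_equal(nrow(fl$per_community), 2L)
  eligible <- fl$per_community[fl$per_community$n_edges >= 2, ]
  expect_equal(eligible$rel_fluct, sqrt(2 / 3) / 2)
  expect_equal(fl$aggregate, sqrt(2 / 3) / 2)  # dyad community excluded
  # equal weights: zero fluctuation
  k4 <- make_fixture("clique", 4, weight = 2.5)
  expect_equal(intra_community_weight_fluctuation(k4, rep(1, 4))$aggregate, 0)
  # scale invariance
  net2 <- small_fixtures()$random1
  memb2 <- louvain_partition(net2, seed = 1)$membership
  a1 <- intra_community_weight_fluctuation(net2, memb2)$aggregate
  net2s <- weighted_network(transform(net2$edges, w = w * 13), net2$n_nodes)
  a2 <- intra_community_weight_fluctuation(net2s, memb2)$aggregate
  expect_equal(a1, a2)
  expect_error(intra_community_weight_fluctuation(
    weighted_network(data.frame(i = 1, j = 2, w = 1), 2), c(1, 2)),
    "internal edges")
})

test_that("community weight-size fit recovers a planted 1/(n-1) collapse", {
  pw <- make_fixture("planted_weight_cliques", c(5, 8, 13), prefactor = 60)
  memb <- rep(1:3, times = c(5, 8, 13))
  fit <- community_weight_vs_size(pw, memb)
  expect_equal(fit$prefactor, 60, tolerance = 1e-12)
  expect_false(fit$degenerate)
  same <- make_fixture("planted_weight_cliques", c(6, 6), prefactor = 60)
  fit2 <- community_weight_vs_size(same, rep(1:2, each = 6))
  expect_true(fit2$degenerate)
})

test_that("first-level partitions are finer than (or equal to) final ones", {
  p <- model_params(250, "AGING", aging_factor = 0.9, w_th = 0.01,
                    p_r = 0.005, steps = 1200, seed = 9)
  net <- run_simulation(p)$network
  first <- louvain_partition(net, level = "first_level", seed = 4)
  final <- louvain_partition(net, level = "final", seed = 4)
  expect_gte(first$n_communities, final$n_communities)
  expect_gte(final$modularity, 0.5)
})
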