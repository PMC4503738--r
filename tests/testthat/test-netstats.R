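test_that("degree distribution covers all nodes including isolated ones", {
  star <- make_fixture("star", 4)
  d <- degree_distribution(star)
  expect_equal(d$x, c(1, 4))
  expect_equal(d$mass, c(0.8, 0.2))
  k5 <- make_fixture("clique", 5)
  d5 <- degree_distribution(k5)
  expect_equal(d5$x, 4)
  expect_equal(d5$mass, 1)
  d0 <- degree_distribution(empty_network(7))
  expect_equal(d0$x, 0)
  expect_equal(d0$mass, 1)
})

test_that("strength distribution log-bins s > 0 and reports the zero bucket", {
  k5 <- make_fixture("clique", 5, weight = 2)
  d <- strength_distribution(k5)
  expect_equal(sum(d$mass), 1)
  expect_equal(sum(d$count), 5)
  expect_equal(d$x[which.max(d$mass)], 8, tolerance = 0.15)  # bin center near 8
  # isolated nodes go to the zero bucket, not the log bins
  aug <- weighted_network(k5$edges, 7)
  d2 <- strength_distribution(aug)
  expect_equal(attr(d2, "zero_fraction"), 2 / 7)
  expect_equal(sum(d2$mass), 1)          # normalized over positive support
  dyad <- weighted_network(data.frame(i = 1, j = 2, w = 3), 2)
  expect_equal(strengths(dyad), c(3, 3))
})

test_that("weight distribution masses sum to 1 and degenerate fits are refused", {
  net <- small_fixtures()$random1
  d <- weight_distribution(net)
  expect_equal(sum(d$mass), 1)
  expect_true(all(diff(d$breaks) > 0))
  expect_error(weight_distribution(empty_network(3)), "no edges")
  expect_error(fit_power_law(rep(2, 50), 1, 10), "degenerate")
})

test_that("the ML power-law exponent recovers planted exponents", {
  # inverse-CDF sampling from p(w) ~ w^-alpha truncated to [1, 100]
  sample_pl <- function(n, alpha, wmin = 1, wmax = 100) {
    u <- runif(n)
    if (abs(alpha - 1) < 1e-12) return(wmin * (wmax / wmin)^u)
    om <- 1 - alpha
    (wmin^om + u * (wmax^om - wmin^om))^(1 / om)
  }
  set.seed(99)
  for (alpha in c(1, 1.8, 2.5)) {
    w <- sample_pl(20000, alpha)
    fit <- fit_power_law(w, 1, 100)
    expect_equal(fit$exponent, -alpha, tolerance = 0.05)
    expect_lt(abs(fit$exponent + alpha), 3 * fit$se)
  }
})

test_that("overlap matches the common-neighbour formula and its conventions", {
  tri <- make_fixture("clique", 3)
  expect_equal(overlap(tri, 1, 2), 1)
  dyad <- weighted_network(data.frame(i = 1, j = 2, w = 1), 2)
  expect_equal(overlap(dyad, 1, 2), 0)     # denominator-0 convention
  k4 <- make_fixture("clique", 4)
  expect_equal(overlap(k4, 1, 2), 1)       # 2 / (2 + 2 - 2)
  expect_error(overlap(k4, 1, 5), "not an edge")
  # weight rescaling cannot change a topological quantity
  net <- small_fixtures()$random2
  scaled <- weighted_network(transform(net$edges, w = w * 7.5), net$n_nodes)
  expect_equal(edge_overlaps(scaled), edge_overlaps(net))
})

test_that("clustering matches enumeration and ignores weights", {
  tp <- small_fixtures()$tri_pendant   # triangle 1-2-3 plus pendant 4 on 3
  expect_equal(local_clustering(tp), c(1, 1, 1 / 3, 0))
  expect_equal(average_clustering(tp), 7 / 12)
  expect_equal(local_clustering(make_fixture("clique", 3)), rep(1, 3))
  expect_equal(average_clustering(make_fixture("star", 5)), 0)
  rescaled <- weighted_network(transform(tp$edges, w = w * 100), 4)
  expect_equal(local_clustering(rescaled), local_clustering(tp))
})

test_that("knn and strength profiles match enumeration", {
  star <- make_fixture("star", 4)
  prof <- knn_vs_degree(star)
  expect_equal(prof$x, c(1, 4))
  expect_equal(prof$mean, c(4, 1))   # leaves see the hub; the hub sees leaves
  expect_equal(sum(prof$count), 5)
  kn <- make_fixture("clique", 6, weight = 2)
  p1 <- knn_vs_degree(kn)
  expect_equal(p1$x, 5)
  expect_equal(p1$mean, 5)
  p2 <- strength_vs_degree(kn)
  expect_equal(p2$mean, 2 * 5)
})

test_that("overlap, clustering and knn agree exactly with brute force on small graphs", {
  nets <- small_fixtures()
  for (nm in names(nets)) {
    net <- nets[[nm]]
    lc <- local_clustering(net)
    for (i in seq_len(net$n_nodes))
      expect_equal(lc[i], oracle_local_clustering(net, i),
                   info = sprintf("%s node %d", nm, i))
    o <- edge_overlaps(net)
    for (r in seq_len(edge_count(net)))
      expect_equal(o[r], oracle_overlap(net, net$edges$i[r], net$edges$j[r]),
                   info = sprintf("%s edge %d", nm, r))
    k <- degrees(net)
    if (edge_count(net)) {
      prof <- knn_vs_degree(net)
      for (kk in prof$x) {
        nodes <- which(k == kk)
        expect_equal(prof$mean[prof$x == kk],
                     mean(vapply(nodes, function(i) oracle_knn(net, i),
                                 numeric(1))),
                     info = sprintf("%s degree %d", nm, kk))
      }
    }
  }
})

test_that("overlap-weight profile collapses to one bin on uniform weights", {
  k5 <- make_fixture("clique", 5, weight = 3)
  prof <- overlap_vs_weight(k5)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$mean, 1)
  expect_equal(prof$count, 10L)
})

test_that("binned profile counts always sum to the sample size", {
  net <- small_fixtures()$random3
  expect_equal(sum(clustering_vs_degree(net)$count), net$n_nodes)
  expect_equal(sum(strength_vs_degree(net)$count), net$n_nodes)
  expect_equal(sum(overlap_vs_weight(net, n_bins = 6)$count),
               edge_count(net))
})
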