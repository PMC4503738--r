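path_net <- function() {
  weighted_network(data.frame(i = c(1, 2), j = c(2, 3), w = 1), 3)
}

test_that("a single local-attachment event follows the two-step walk rule", {
  p <- model_params(3, "LD", p_ld = 0, p_delta = 1, delta = 1, w0 = 1,
                    steps = 1)
  # path 1-2-3: both hops forced; closing edge created at w0, walk links + delta
  for (seed in 1:5) {
    out <- la_event(path_net(), node = 1, p, seed = seed)
    expect_equal(get_weight(out, 1, 2), 2)
    expect_equal(get_weight(out, 2, 3), 2)
    expect_equal(get_weight(out, 1, 3), 1)   # new edge keeps w0, no extra delta
  }
  # p_delta = 0: no closure, but the walk is still reinforced
  p0 <- model_params(3, "LD", p_ld = 0, p_delta = 0, delta = 1, steps = 1)
  out <- la_event(path_net(), node = 1, p0, seed = 1)
  expect_equal(edge_count(out), 2L)
  expect_equal(get_weight(out, 1, 2), 2)
  # pre-existing closing edge gains delta too
  tri <- weighted_network(data.frame(i = c(1, 2, 1), j = c(2, 3, 3), w = 1), 3)
  out <- la_event(tri, node = 1, p, seed = 1)
  expect_equal(sum(out$edges$w), 3 + 3)      # all three links reinforced
  # truncated walk (j has no neighbour besides i): nothing changes
  dyad <- weighted_network(data.frame(i = 1, j = 2, w = 5), 2)
  out <- la_event(dyad, node = 1, p, seed = 1)
  expect_equal(out$edges, dyad$edges)
})

test_that("the first hop picks neighbours proportionally to weight", {
  # 1 is linked to 2 (w = 3) and 3 (w = 1); 2 and 3 have outside neighbours
  # so the walk completes and the first hop is visible in the reinforcement
  net <- weighted_network(
    data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 5), w = c(3, 1, 1, 1)), 5)
  p <- model_params(5, "LD", p_ld = 0, p_delta = 0, delta = 1, steps = 1)
  hits <- 0
  n_trials <- 2000
  for (seed in seq_len(n_trials)) {
    out <- la_event(net, node = 1, p, seed = seed)
    if (get_weight(out, 1, 2) > 3) hits <- hits + 1
  }
  expect_equal(hits / n_trials, 3 / 4, tolerance = 0.04)
})

test_that("a local-attachment sweep leaves an empty network unchanged", {
  p <- model_params(10, "LD", p_ld = 0, p_delta = 1, steps = 1)
  out <- la_sweep(empty_network(10), p, seed = 3)
  expect_equal(edge_count(out), 0L)
})

test_that("one LA event changes total weight by one of the allowed amounts", {
  # delta = 1, w0 = 0.5 disambiguates: 0 (truncated), 2 (open walk),
  # 2.5 (closure created), 3 (closing edge existed)
  p <- model_params(8, "LD", p_ld = 0, p_delta = 0.5, delta = 1, w0 = 0.5,
                    steps = 1)
  for (nm in c("random1", "random2", "bowtie", "bridged")) {
    net0 <- small_fixtures()[[nm]]
    net0$edges$w <- ceiling(net0$edges$w)  # integer weights keep sums exact
    net0 <- weighted_network(net0$edges, net0$n_nodes)
    for (seed in 1:25) {
      node <- 1 + (seed %% net0$n_nodes)
      out <- la_event(net0, node, p, seed = seed)
      dw <- sum(out$edges$w) - sum(net0$edges$w)
      expect_true(isTRUE(all.equal(dw, 0)) || isTRUE(all.equal(dw, 2)) ||
                  isTRUE(all.equal(dw, 2.5)) || isTRUE(all.equal(dw, 3)),
                  info = sprintf("%s seed %d dw=%g", nm, seed, dw))
    }
  }
})

test_that("global attachment links isolated nodes and respects saturation", {
  p <- model_params(2, "LD", p_ld = 0, p_r = 0, w0 = 2, steps = 1)
  out <- ga_sweep(empty_network(2), p, seed = 1)
  expect_equal(out$edges, data.frame(i = 1L, j = 2L, w = 2))
  # p_r = 0 and no isolated nodes: unchanged
  p10 <- model_params(10, "LD", p_ld = 0, p_r = 0, steps = 1)
  ring <- make_fixture("ring", 10)
  expect_equal(ga_sweep(ring, p10, seed = 5)$edges, ring$edges)
  # complete graph: no non-neighbour exists, even at p_r = 1
  p4 <- model_params(4, "LD", p_ld = 0, p_r = 1, steps = 1)
  k4 <- make_fixture("clique", 4)
  expect_equal(ga_sweep(k4, p4, seed = 5)$edges, k4$edges)
  # single node: nothing to link to
  p1 <- model_params(1, "LD", p_ld = 0, steps = 1)
  expect_equal(edge_count(ga_sweep(empty_network(1), p1, seed = 1)), 0L)
  # every node links with p_r = 1 when targets exist
  pr1 <- model_params(10, "LD", p_ld = 0, p_r = 1, steps = 1)
  out <- ga_sweep(ring, pr1, seed = 2)
  expect_gte(min(degrees(out)), 3)
})

test_that("termination sweeps behave at the probability extremes", {
  k6 <- make_fixture("clique", 6)
  pnd0 <- model_params(6, "ND", p_nd = 0, steps = 1)
  pnd1 <- model_params(6, "ND", p_nd = 1, steps = 1)
  expect_equal(nd_sweep(k6, pnd0, seed = 1)$edges, k6$edges)
  expect_equal(edge_count(nd_sweep(k6, pnd1, seed = 1)), 0L)
  pld0 <- model_params(6, "LD", p_ld = 0, steps = 1)
  pld1 <- model_params(6, "LD", p_ld = 1, steps = 1)
  expect_equal(ld_sweep(k6, pld0, seed = 1)$edges, k6$edges)
  expect_equal(edge_count(ld_sweep(k6, pld1, seed = 1)), 0L)
})

test_that("node deletion removes whole neighbourhoods: survivors stay a clique", {
  k8 <- make_fixture("clique", 8)
  p <- model_params(8, "ND", p_nd = 0.3, steps = 1)
  for (seed in 1:30) {
    out <- nd_sweep(k8, p, seed = seed)
    k <- degrees(out)
    survivors <- which(k > 0)
    # every surviving node is connected to every other survivor
    expect_true(all(k[survivors] == length(survivors) - 1), info = seed)
    expect_equal(edge_count(out), choose(length(survivors), 2), info = seed)
  }
})

test_that("link deletion removes the binomial share of edges on average", {
  net <- make_fixture("clique", 20)                 # m = 190
  m <- edge_count(net)
  p <- model_params(20, "LD", p_ld = 0.3, steps = 1)
  surv <- vapply(1:300, function(seed)
    edge_count(ld_sweep(net, p, seed = seed)), numeric(1))
  expect_equal(mean(surv), m * 0.7, tolerance = 0.02)
  # ND at the same graph: per-edge survival is (1 - p_nd)^2
  pnd <- model_params(20, "ND", p_nd = 0.2, steps = 1)
  surv_nd <- vapply(1:300, function(seed)
    edge_count(nd_sweep(net, pnd, seed = seed)), numeric(1))
  expect_equal(mean(surv_nd), m * 0.8^2, tolerance = 0.03)
})

test_that("aging multiplies weights and prunes below the threshold", {
  p <- model_params(3, "AGING", aging_factor = 0.9, w_th = 0.01, steps = 1)
  net <- weighted_network(data.frame(i = c(1, 2), j = c(2, 3),
                                     w = c(1, 0.011)), 3)
  out <- aging_sweep(net, p)
  expect_equal(out$edges$w, 0.9)               # 0.011 * 0.9 < w_th: removed
  expect_equal(edge_count(out), 1L)
  expect_gte(min(out$edges$w), p$w_th)
  # f -> 1 limit: weights essentially unchanged
  p99 <- model_params(3, "AGING", aging_factor = 1 - 1e-12, w_th = 0.01,
                      steps = 1)
  out <- aging_sweep(net, p99)
  expect_equal(out$edges$w, net$edges$w, tolerance = 1e-9)
})

test_that("a step applies LA, GA, then termination, in that order", {
  # termination last: p_nd = 1 wipes everything including this step's edges
  p <- model_params(30, "ND", p_nd = 1, p_r = 0.5, steps = 1)
  out <- step_network(empty_network(30), p, seed = 4)
  expect_equal(edge_count(out), 0L)
  # GA guarantees isolated nodes link: after one step from empty, all k >= 1
  p2 <- model_params(30, "LD", p_ld = 0, p_r = 0.01, steps = 1)
  out2 <- step_network(empty_network(30), p2, seed = 4)
  expect_gte(min(degrees(out2)), 1)
})

test_that("with no creation, no focal closure and no termination the edge set is invariant", {
  net <- make_fixture("ring", 12)   # all degrees >= 1, so GA never fires
  p <- model_params(12, "LD", p_ld = 0, p_delta = 0, p_r = 0, delta = 1,
                    steps = 1)
  cur <- net
  for (t in 1:5) {
    nxt <- step_network(cur, p, seed = 100 + t)
    expect_equal(nxt$edges[, c("i", "j")], net$edges[, c("i", "j")])
    expect_true(all(nxt$edges$w >= cur$edges$w))
    cur <- nxt
  }
})

test_that("runs are deterministic and ensembles reproducible", {
  p <- model_params(60, "AGING", aging_factor = 0.9, w_th = 0.01,
                    p_r = 0.01, steps = 40, seed = 11)
  r1 <- run_simulation(p)
  r2 <- run_simulation(p)
  expect_identical(r1$network$edges, r2$network$edges)
  # T = 0 leaves the initial empty state
  p0 <- model_params(60, "AGING", aging_factor = 0.9, w_th = 0.01, steps = 0)
  expect_equal(edge_count(run_simulation(p0)$network), 0L)
  e1 <- run_ensemble(p, 3, base_seed = 5)
  e2 <- run_ensemble(p, 3, base_seed = 5)
  for (r in 1:3)
    expect_identical(e1[[r]]$network$edges, e2[[r]]$network$edges)
  # a 1-member ensemble is run_simulation at the base seed
  p5 <- p; p5$seed <- 5L
  expect_identical(run_ensemble(p, 1, base_seed = 5)[[1]]$network$edges,
                   run_simulation(p5)$network$edges)
})

test_that("network invariants hold along a mixed trajectory", {
  for (mech in c("ND", "LD", "AGING")) {
    p <- switch(mech,
      ND = model_params(80, "ND", p_nd = 0.02, p_r = 0.02, steps = 60,
                        seed = 2),
      LD = model_params(80, "LD", p_ld = 0.05, p_r = 0.02, steps = 60,
                        seed = 2),
      AGING = model_params(80, "AGING", aging_factor = 0.85, w_th = 0.05,
                           p_r = 0.02, steps = 60, seed = 2))
    net <- run_simulation(p)$network
    e <- net$edges
    expect_true(all(e$i < e$j), info = mech)            # no self-loops, canon
    expect_true(all(e$w > 0), info = mech)
    expect_equal(anyDuplicated(e[, c("i", "j")]), 0L, info = mech)
    if (mech == "AGING") expect_gte(min(e$w), p$w_th)
  }
})

test_that("the mean degree is stationary over the tail of a long run", {
  p <- model_params(500, "ND", p_nd = 0.001, p_r = 0.0005, steps = 4000,
                    seed = 8)
  res <- run_simulation(p, record_timeseries = TRUE)
  ts <- res$k_mean
  expect_length(ts, p$steps + 1)
  tail_idx <- seq(round(0.8 * length(ts)), length(ts))
  fit <- stats::lm(k ~ t, data.frame(t = tail_idx, k = ts[tail_idx]))
  drift <- abs(coef(fit)[["t"]]) * length(tail_idx)   # drift over the window
  expect_lt(drift / mean(ts[tail_idx]), 0.1)
})
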