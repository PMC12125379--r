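test_that("planted partition with extreme densities gives disjoint cliques", {
  gen <- generate_planted_partition(3, 4, 1, 0, seed = 1)
  expect_equal(gen$network$m, 3 * choose(4, 2))
  expect_equal(gen$clustering$k, 3)
  expect_equal(unname(community_sizes(gen$clustering)), rep(4, 3))
  # every edge is within its community
  for (cc in gen$clustering$communities) {
    tri <- edge_trisection(gen$network, gen$clustering, cc)
    expect_equal(tri$T_y, 0)
  }
})

test_that("planted-partition edge counts match binomial moments", {
  k <- 3; nc <- 5; p_in <- 0.6; p_out <- 0.05
  mu <- k * choose(nc, 2) * p_in + choose(k, 2) * nc^2 * p_out
  v <- k * choose(nc, 2) * p_in * (1 - p_in) +
    choose(k, 2) * nc^2 * p_out * (1 - p_out)
  ms <- vapply(1:200, function(s)
    generate_planted_partition(k, nc, p_in, p_out, seed = s)$network$m, 0)
  expect_lt(abs(mean(ms) - mu), 3 * sqrt(v / 200))
})

test_that("generators are seed-deterministic and produce valid simple graphs", {
  a <- generate_planted_partition(3, 9, 0.99, 0.01, seed = 42)
  b <- generate_planted_partition(3, 9, 0.99, 0.01, seed = 42)
  expect_identical(a$network$edges, b$network$edges)
  expect_silent(validate_inputs(a$network, a$clustering))
  for (model in c("ER", "BA", "SW", "FFN")) {
    g1 <- generate_topology(model, n = 60, target_m = 180, seed = 7)
    g2 <- generate_topology(model, n = 60, target_m = 180, seed = 7)
    expect_identical(g1$edges, g2$edges)
    expect_true(all(g1$edges[, "u"] != g1$edges[, "v"]))
    expect_gt(g1$m, 0)
  }
})

test_that("ER topologies hit the requested edge count", {
  g <- generate_topology("ER", n = 200, target_m = 600, seed = 3)
  expect_equal(g$m, 600)
  expect_equal(g$n, 200)
  expect_error(generate_topology("ER", n = 5, target_m = 100),
               "unreachable")
})

test_that("BA edge count is the deterministic attachment identity", {
  # igraph's preferential attachment: early vertices attach to all existing,
  # so attachment a on n vertices yields a*(n-2) edges for a = 3
  g <- generate_topology("BA", n = 200, target_m = 600, seed = 1)
  expect_equal(g$m, 3 * (200 - 2))
})

test_that("uniform probability assignment reproduces the entropy pairings", {
  topo <- generate_planted_partition(3, 9, 0.72, 0.12, seed = 5)$network
  expect_equal(entropy_ratio(assign_edge_probabilities(topo, "uniform",
                                                       p = 0.5)), 1)
  expect_equal(round(entropy_ratio(
    assign_edge_probabilities(topo, "uniform", p = 0.9)), 2), 0.47)
  expect_error(assign_edge_probabilities(topo, "uniform", p = 0), "0, 1")
})

test_that("entropy-targeted assignment realises the requested ratio", {
  topo <- generate_topology("ER", n = 60, target_m = 300, seed = 2)
  for (t in c(0.1, 0.4, 0.8, 1.0)) {
    net <- assign_edge_probabilities(topo, "entropy_target", target = t,
                                     spread = 0.05, seed = 6)
    expect_lt(abs(entropy_ratio(net) - t), 0.02)
    expect_identical(net$edges, topo$edges)
    # spread actually varies the probabilities away from degenerate targets
    if (t > 0.05 && t < 0.95) expect_gt(stats::sd(net$p), 0)
  }
  expect_error(assign_edge_probabilities(topo, "entropy_target",
                                         target = 1.5), "0, 1")
})

test_that("random clusterings cover all nodes with size imbalance knob", {
  net <- generate_topology("ER", n = 50, target_m = 150, seed = 1)
  even <- random_clustering(net, k = 5, alpha = 1e6, seed = 2)
  skew <- random_clustering(net, k = 5, alpha = 0.5, seed = 2)
  expect_silent(validate_inputs(net, even))
  expect_silent(validate_inputs(net, skew))
  expect_equal(even$k, 5)
  expect_lt(stats::var(community_sizes(even)),
            stats::var(community_sizes(skew)) + 1e-9)
})
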