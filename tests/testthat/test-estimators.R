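test_that("world sampling is seed-deterministic and honours probabilities", {
  net <- two_triangles(1)
  w <- sample_world(net, seed = 1)
  expect_true(all(w$present))
  w1 <- sample_world(two_triangles(0.4), seed = 7)
  w2 <- sample_world(two_triangles(0.4), seed = 7)
  expect_identical(w1$present, w2$present)

  # empirical inclusion frequency of a p = 0.3 edge over many draws
  netp <- prob_network("a", "b", 0.3)
  hits <- withr::with_seed(99, mean(stats::runif(10000) < netp$p))
  expect_lt(abs(hits - 0.3), 0.015)
})

test_that("sampling estimator is exact for deterministic networks", {
  net <- two_triangles(1)
  r <- sampling_expected_modularity(net, triangle_clustering(), theta = 10,
                                    seed = 3)
  expect_equal(r$value, 0.5)
  expect_equal(r$theta, 10)
})

test_that("sampling is reproducible under a seed and varies across seeds", {
  inst <- ccs_fixture(entropy = 1)
  a <- sampling_expected_modularity(inst$network, inst$clustering, 200,
                                    seed = 5)
  b <- sampling_expected_modularity(inst$network, inst$clustering, 200,
                                    seed = 5)
  c <- sampling_expected_modularity(inst$network, inst$clustering, 200,
                                    seed = 6)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, c$value))
  expect_error(sampling_expected_modularity(inst$network, inst$clustering,
                                            0), ">= 1")
})

test_that("sampling mean tracks the exact value within Monte Carlo error", {
  net <- prob_network("a", "b", 0.8)
  cl <- node_clustering(c("a", "b"), c("1", "2"))
  r <- sampling_expected_modularity(net, cl, theta = 100000, seed = 2,
                                    keep_samples = TRUE)
  se <- stats::sd(r$samples) / sqrt(r$theta)
  expect_lt(abs(r$value - (-0.4)), 4 * se)

  # grand mean over repeated medium runs on a structured fixture
  inst <- ccs_fixture(entropy = 0.47)
  exact <- expected_modularity_fpwp(inst$network, inst$clustering)$value
  runs <- vapply(1:20, function(s)
    sampling_expected_modularity(inst$network, inst$clustering, 500,
                                 seed = 100 + s)$value, 0)
  se <- stats::sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - exact), 4 * se)
})

test_that("time-budget sampling always draws and scales with the budget", {
  inst <- ccs_fixture(entropy = 1)
  r <- sampling_time_budget(inst$network, inst$clustering, budget = 0.01,
                            seed = 1, batch = 8L)
  expect_gte(r$theta, 1)
  r2 <- sampling_time_budget(inst$network, inst$clustering, budget = 0.2,
                             seed = 1, batch = 8L)
  expect_gte(r2$theta, r$theta)
  expect_error(sampling_time_budget(inst$network, inst$clustering, 0),
               "positive")
})

test_that("thresholding keeps exactly the edges at or above the cut", {
  net <- prob_network(c("a", "b"), c("b", "c"), c(0.3, 0.7))
  cl <- node_clustering(c("a", "b", "c"), c("1", "1", "2"))
  # t = 0.5 keeps only the 0.7 edge (a cross edge for community 1)
  kept <- net$p >= 0.5
  expect_equal(sum(kept), 1)
  expect_equal(threshold_modularity(net, cl, 0.5),
               modularity_communities(possible_world(net, kept), cl))
  # deterministic network: any threshold returns the exact Q
  t2 <- two_triangles(1)
  for (t in c(0.1, 0.5, 1)) {
    expect_equal(threshold_modularity(t2, triangle_clustering(), t), 0.5)
  }
  expect_error(threshold_modularity(net, cl, 0), "0, 1")
})

test_that("thresholding is near-exact only for near-deterministic networks", {
  eps <- 1e-7
  gen <- generate_planted_partition(3, 4, 0.9, 0.1, seed = 4)
  # probabilities all within eps of 0 or 1
  p <- withr::with_seed(8, ifelse(stats::runif(gen$network$m) < 0.8,
                                  1 - eps, eps))
  net <- prob_network(gen$network$edges[, "u"], gen$network$edges[, "v"], p,
                      nodes = gen$network$nodes)
  exact <- expected_modularity_fpwp(net, gen$clustering)$value
  expect_lt(abs(threshold_modularity(net, gen$clustering, 0.5) - exact),
            1e-3)
})
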