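test_that("cell modularity contribution matches hand values", {
  expect_equal(q_cell(0, 0, 0), 0)       # empty-world convention
  expect_equal(q_cell(1, 0, 0), 0)       # 1 - 1
  expect_equal(q_cell(0, 1, 2), -1 / 36)
  expect_equal(q_cell(1, 2, 0), 1 / 3 - (4 / 6)^2)
  # vectorised
  expect_equal(q_cell(c(0, 1), c(0, 2), c(0, 0)), c(0, -1 / 9))
})

test_that("cell world counts are binomial products summing to 2^m", {
  # worked example: community {1,2}; within l12, cross l23 l24,
  # outside l34 l45 -- capacities (1, 2, 2)
  net <- prob_network(c("n1", "n2", "n2", "n3", "n4"),
                      c("n2", "n3", "n4", "n4", "n5"),
                      c(0.9, 0.6, 0.4, 0.5, 0.7))
  cl <- node_clustering(c("n1", "n2", "n3", "n4", "n5"),
                        c("c", "c", "o", "o", "o"))
  tri <- edge_trisection(net, cl, "c")
  expect_equal(c(tri$T_x, tri$T_y, tri$T_z), c(1, 2, 2))
  expect_equal(partition_world_count(tri, 0, 1, 2), 2)
  expect_equal(partition_world_count(tri, 0, 0, 0), 1)
  total <- 0
  for (x in 0:tri$T_x) for (y in 0:tri$T_y) for (z in 0:tri$T_z) {
    total <- total + partition_world_count(tri, x, y, z)
  }
  expect_identical(total, 2^net$m)
  expect_error(partition_world_count(tri, 2, 0, 0), "capacities")
})

test_that("cell probability equals the summed probability of its worlds", {
  inst <- random_instance(13, max_edges = 6)
  net <- inst$network
  cl <- inst$clustering
  m <- net$m
  for (cc in cl$communities) {
    tri <- edge_trisection(net, cl, cc)
    # enumerate every world, bin it by its (x, y, z) signature
    cellsum <- array(0, dim = c(tri$T_x + 1, tri$T_y + 1, tri$T_z + 1))
    for (idx in 0:(2^m - 1)) {
      present <- as.logical(bitwAnd(idx, 2^(seq_len(m) - 1)))
      sig <- c(sum(present & tri$within), sum(present & tri$cross),
               sum(present & tri$outside)) + 1
      cellsum[sig[1], sig[2], sig[3]] <-
        cellsum[sig[1], sig[2], sig[3]] +
        world_probability(net, possible_world(net, present))
    }
    for (x in 0:tri$T_x) for (y in 0:tri$T_y) for (z in 0:tri$T_z) {
      for (eng in c("enumeration", "convolution", "dft")) {
        expect_equal(partition_probability(net, tri, x, y, z, engine = eng),
                     cellsum[x + 1, y + 1, z + 1], tolerance = 1e-10)
      }
    }
    expect_equal(sum(cellsum), 1, tolerance = 1e-9)
  }
})

test_that("deterministic edges concentrate the cell mass at the capacities", {
  net <- two_triangles(1)
  cl <- triangle_clustering()
  tri <- edge_trisection(net, cl, "1")
  expect_equal(partition_probability(net, tri, tri$T_x, tri$T_y, tri$T_z), 1)
  expect_equal(partition_probability(net, tri, 0, 0, 0), 0)
})

test_that("PWP and FPWP match brute force on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed + 2000, max_edges = 10)
    bf <- expected_modularity_bruteforce(inst$network, inst$clustering)$value
    pwp <- expected_modularity_pwp(inst$network, inst$clustering)$value
    fpwp <- expected_modularity_fpwp(inst$network, inst$clustering)$value
    expect_lt(abs(bf - pwp), 1e-9)
    expect_lt(abs(bf - fpwp), 1e-8)
  }
})

test_that("partition algorithms report per-community terms and hand values", {
  net <- prob_network("a", "b", 0.8)
  cl <- node_clustering(c("a", "b"), c("1", "2"))
  r <- expected_modularity_fpwp(net, cl)
  expect_equal(r$value, -0.4, tolerance = 1e-12)
  expect_equal(length(r$terms), 2)
  expect_equal(sum(r$terms), r$value)

  t2 <- two_triangles(1)
  expect_equal(expected_modularity_pwp(t2, triangle_clustering())$value, 0.5,
               tolerance = 1e-12)
  expect_equal(expected_modularity_fpwp(t2, triangle_clustering())$value, 0.5,
               tolerance = 1e-12)
})

test_that("FPWP visits a probability-independent number of cells", {
  gen <- generate_planted_partition(3, 5, 0.8, 0.1, seed = 9)
  expected_cells <- sum(vapply(gen$clustering$communities, function(cc) {
    tri <- edge_trisection(gen$network, gen$clustering, cc)
    (tri$T_x + 1) * (tri$T_y + 1) * (tri$T_z + 1)
  }, 0))
  for (seed in 1:3) {
    net <- assign_edge_probabilities(gen$network, "entropy_target",
                                     target = 0.3 * seed, seed = seed)
    expect_equal(expected_modularity_fpwp(net, gen$clustering)$cells,
                 expected_cells)
  }
})

test_that("PWP refuses trisection parts beyond the enumeration cap", {
  gen <- generate_planted_partition(2, 8, 0.99, 0.05, seed = 2)
  net <- assign_edge_probabilities(gen$network, "uniform", p = 0.5)
  expect_error(expected_modularity_pwp(net, gen$clustering),
               "enumeration cap")
  # FPWP handles the same input
  expect_silent(expected_modularity_fpwp(net, gen$clustering))
})
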