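# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write.

# Two disjoint triangles abc and def, all edges with probability p.
two_triangles <- function(p = 1) {
  prob_network(c("a", "b", "c", "d", "e", "f"),
               c("b", "c", "a", "e", "f", "d"), rep(p, 6))
}

triangle_clustering <- function() {
  node_clustering(letters[1:6], rep(c("1", "2"), each = 3))
}

# Small random probabilistic network + random clustering, deterministic
# under seed. Edge count bounded so brute force stays cheap.
random_instance <- function(seed, max_edges = 10, k = NULL) {
  withr::with_seed(seed, {
    n <- sample(4:8, 1)
    nodes <- letters[seq_len(n)]
    pairs <- t(utils::combn(nodes, 2))
    m <- sample(3:min(max_edges, nrow(pairs)), 1)
    sel <- sample(nrow(pairs), m)
    p <- stats::runif(m, 0.05, 1)
    k <- if (is.null(k)) sample(2:3, 1) else k
    labels <- as.character(sample(seq_len(k), n, replace = TRUE))
    list(network = prob_network(pairs[sel, 1], pairs[sel, 2], p,
                                nodes = nodes),
         clustering = node_clustering(nodes, labels))
  })
}

# CCS planted-partition fixture with a uniform probability chosen to hit a
# target entropy ratio.
ccs_fixture <- function(entropy = 0, seed = 11, p_in = 0.99, p_out = 0.01) {
  gen <- generate_planted_partition(3, 9, p_in, p_out, seed = seed)
  p <- probability_for_entropy_ratio(entropy, "high")
  list(network = assign_edge_probabilities(gen$network, "uniform", p = p),
       clustering = gen$clustering)
}
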