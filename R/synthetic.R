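node_ids <- function(n) sprintf("v%03d", seq_len(n))

igraph_to_network <- function(g, nodes) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) {
    return(prob_network(character(), character(), numeric(), nodes = nodes))
  }
  prob_network(nodes[el[, 1]], nodes[el[, 2]], rep(1, nrow(el)),
               nodes = nodes)
}

#' Generate a planted-partition (stochastic block model) network
#'
#' Builds `k` communities of `nc` nodes each; every within-community node
#' pair becomes an edge independently with density `p_in`, every
#' cross-community pair with density `p_out`. Returns the topology as a
#' degenerate probabilistic network (all edge probabilities 1, ready for
#' [assign_edge_probabilities()]) together with the planted ground-truth
#' clustering. Deterministic under `seed`.
#'
#' With `p_in` close to 1 and `p_out` close to 0 this produces
#' clear-community-structure (CCS) test networks that approximate `k`
#' disjoint cliques; moderate densities (e.g. `p_in = 0.72`,
#' `p_out = 0.12`) give the less-clear (LCCS) variant.
#'
#' @param k number of communities (>= 1).
#' @param nc nodes per community (>= 1).
#' @param p_in within-community edge density in `[0, 1]`.
#' @param p_out between-community edge density in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `network` (a [prob_network()], all `p = 1`) and
#'   `clustering` (the planted [node_clustering()]).
#' @examples
#' ccs <- generate_planted_partition(3, 9, 0.99, 0.01, seed = 1)
#' ccs$network$m
#' @export
generate_planted_partition <- function(k, nc, p_in, p_out, seed = 1L) {
  stopifnot(k >= 1, nc >= 1, p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  n <- k * nc
  nodes <- node_ids(n)
  labels <- rep(sprintf("c%02d", seq_len(k)), each = nc)
  pairs <- utils::combn(n, 2)
  same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  dens <- ifelse(same, p_in, p_out)
  keep <- withr::with_seed(as.integer(seed),
                           stats::runif(ncol(pairs)) < dens)
  net <- prob_network(nodes[pairs[1, keep]], nodes[pairs[2, keep]],
                      rep(1, sum(keep)), nodes = nodes)
  list(network = net, clustering = node_clustering(nodes, labels))
}

#' Generate a random topology
#'
#' Classical random-graph models used to probe how network structure (degree
#' skew, clustering, community size spread) affects the algorithms, all
#' produced through igraph and returned as degenerate probabilistic networks
#' (all `p = 1`):
#'
#' * `"ER"` -- Erdos-Renyi G(n, m): exactly `target_m` edges.
#' * `"BA"` -- Barabasi-Albert preferential attachment; each new vertex
#'   attaches `round(target_m / n)` edges, so the edge count is the exact
#'   deterministic function of `(n, attachment)` that construction gives.
#' * `"SW"` -- Watts-Strogatz small world on a ring lattice with
#'   `round(target_m / n)` neighbours and rewiring probability `rewire`;
#'   simplified, so the count can fall slightly below `n * nei`.
#' * `"FFN"` -- forest-fire growth (forward burning probability `fw_prob`),
#'   simplified to an undirected simple graph; its edge count is random, so
#'   `fw_prob` is the density knob.
#'
#' @param model one of `"ER"`, `"BA"`, `"SW"`, `"FFN"`.
#' @param n number of nodes.
#' @param target_m desired edge count (exact for ER, approximate otherwise).
#' @param seed integer seed; generation is deterministic given it.
#' @param rewire small-world rewiring probability.
#' @param fw_prob forest-fire forward-burning probability.
#' @return a [prob_network()] with all probabilities 1.
#' @export
generate_topology <- function(model = c("ER", "BA", "SW", "FFN"), n,
                              target_m, seed = 1L, rewire = 0.05,
                              fw_prob = 0.37) {
  model <- match.arg(model)
  stopifnot(n >= 2, target_m >= 1)
  max_m <- choose(n, 2)
  if (target_m > max_m) {
    stop(sprintf("target_m = %d unreachable on %d nodes (max %d)",
                 target_m, n, max_m), call. = FALSE)
  }
  per_vertex <- max(1L, as.integer(round(target_m / n)))
  if (model %in% c("BA", "SW") && per_vertex >= n) {
    stop(sprintf("target_m = %d unreachable for %s on %d nodes",
                 target_m, model, n), call. = FALSE)
  }
  g <- withr::with_seed(as.integer(seed), switch(
    model,
    ER = igraph::sample_gnm(n, target_m),
    BA = igraph::sample_pa(n, m = per_vertex, directed = FALSE),
    SW = igraph::simplify(
      igraph::sample_smallworld(1, n, per_vertex, rewire)),
    FFN = igraph::simplify(igraph::as_undirected(
      igraph::sample_forestfire(n, fw.prob = fw_prob,
                                bw.factor = 0.8)))
  ))
  igraph_to_network(g, node_ids(n))
}

#' Assign edge probabilities to a topology
#'
#' Turns a deterministic topology into a probabilistic network under one of
#' two schemes:
#'
#' * `"uniform"`: every edge receives the same probability `p`; the
#'   resulting entropy ratio is the binary entropy of `p` (e.g. `p = 0.5`
#'   gives 1.00, `p = 0.9` gives 0.47, `p = 1` gives 0.00).
#' * `"entropy_target"`: per-edge probabilities are spread symmetrically
#'   (half-width `spread`) around a centre probability on the chosen branch,
#'   and the centre is calibrated by root finding so the *realised* entropy
#'   ratio matches `target` (within `tol`, default 0.005; the spread is
#'   halved automatically when the target is otherwise unreachable, e.g.
#'   near ratio 1). Draws are deterministic under `seed`.
#'
#' @param topology a [prob_network()] supplying nodes and edges (its
#'   probabilities are ignored).
#' @param scheme `"uniform"` or `"entropy_target"`.
#' @param p uniform scheme: the shared edge probability in (0, 1].
#' @param target entropy-target scheme: desired entropy ratio in `[0, 1]`.
#' @param spread entropy-target scheme: half-width of the probability spread.
#' @param branch `"high"` (probabilities >= 0.5ish) or `"low"`.
#' @param tol acceptable |realised - target| entropy-ratio gap.
#' @param seed integer seed for the probability draws.
#' @return a [prob_network()] on the same topology.
#' @export
assign_edge_probabilities <- function(topology,
                                      scheme = c("uniform", "entropy_target"),
                                      p = 0.5, target = NULL, spread = 0.05,
                                      branch = c("high", "low"), tol = 0.005,
                                      seed = 1L) {
  scheme <- match.arg(scheme)
  branch <- match.arg(branch)
  m <- topology$m
  if (m == 0) stop("topology has no edges", call. = FALSE)
  probs <- if (scheme == "uniform") {
    if (p <= 0 || p > 1) stop("p must lie in (0, 1]", call. = FALSE)
    rep(p, m)
  } else {
    if (is.null(target) || target < 0 || target > 1) {
      stop("target entropy ratio must lie in [0, 1]", call. = FALSE)
    }
    u <- withr::with_seed(as.integer(seed), stats::runif(m, -1, 1))
    spread_eff <- spread
    repeat {
      pr <- entropy_spread_probs(target, spread_eff, branch, u)
      if (!is.null(pr) &&
            abs(mean(binary_entropy(pr)) - target) <= tol) break
      spread_eff <- spread_eff / 2
      if (spread_eff < 1e-9) {
        pr <- rep(probability_for_entropy_ratio(target, branch), m)
        break
      }
    }
    pr
  }
  prob_network(topology$edges[, "u"], topology$edges[, "v"], probs,
               nodes = topology$nodes)
}

# Probabilities centre + spread * u clamped to (0, 1], with the centre's
# nominal entropy ratio c calibrated so the realised ratio hits the target.
entropy_spread_probs <- function(target, spread, branch, u) {
  clamp <- function(x) pmin(1, pmax(1e-9, x))
  realised <- function(centre_ratio) {
    centre <- probability_for_entropy_ratio(centre_ratio, branch)
    mean(binary_entropy(clamp(centre + spread * u)))
  }
  f <- function(cr) realised(cr) - target
  lo <- 0
  hi <- 1
  if (f(lo) > 0 || f(hi) < 0) return(NULL)   # unreachable with this spread
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  centre <- probability_for_entropy_ratio(root, branch)
  clamp(centre + spread * u)
}

#' Random node clustering with controllable size imbalance
#'
#' Assigns the network's nodes to `k` communities with sizes drawn from a
#' Dirichlet split of `n` (symmetric concentration `alpha`): large `alpha`
#' gives near-equal sizes, small `alpha` gives skewed ones. Used for the
#' studies of how community count and size variance drive the partition
#' algorithms' cost. Every community receives at least one node.
#'
#' @param network a [prob_network()].
#' @param k number of communities.
#' @param alpha Dirichlet concentration (> 0); `Inf` gives maximally equal
#'   sizes.
#' @param seed integer seed.
#' @return a [node_clustering()].
#' @export
random_clustering <- function(network, k, alpha = 100, seed = 1L) {
  n <- network$n
  stopifnot(k >= 1, k <= n, alpha > 0)
  withr::with_seed(as.integer(seed), {
    w <- if (is.infinite(alpha)) rep(1, k) else stats::rgamma(k, alpha)
    sizes <- pmax(1L, as.integer(round(n * w / sum(w))))
    while (sum(sizes) > n) sizes[which.max(sizes)] <-
        sizes[which.max(sizes)] - 1L
    while (sum(sizes) < n) sizes[which.min(sizes)] <-
        sizes[which.min(sizes)] + 1L
    labels <- sample(rep(sprintf("c%02d", seq_len(k)), times = sizes))
    node_clustering(network$nodes, labels)
  })
}
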