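#' Probability of a possible world
#'
#' Under independent edges, the probability of observing a given
#' deterministic world is the product of `p(e)` over its present edges times
#' `1 - p(e)` over its absent edges.
#'
#' @param network a [prob_network()].
#' @param world a [possible_world()] of that network.
#' @return the world probability in `[0, 1]`.
#' @examples
#' net <- prob_network(c("a", "c"), c("b", "d"), c(0.8, 0.5))
#' world_probability(net, possible_world(net, c(TRUE, FALSE)))  # 0.4
#' @export
world_probability <- function(network, world) {
  if (!identical(world$network$edges, network$edges)) {
    stop("world does not belong to this network", call. = FALSE)
  }
  prod(ifelse(world$present, network$p, 1 - network$p))
}

# Chunked enumeration of all 2^m worlds. For each chunk, calls
# fun(B, pr, counted) with B the chunk x m 0/1 inclusion matrix and pr the
# world probabilities, and accumulates fun's numeric result by summation.
# Bit i (1-based edge index, canonical order) of world index w encodes
# inclusion of edge i.
enumerate_worlds <- function(network, fun, chunk_bits = 16L) {
  m <- network$m
  p <- network$p
  n_worlds <- 2^m
  chunk <- as.integer(min(n_worlds, 2^chunk_bits))
  acc <- NULL
  for (start in seq(0, n_worlds - 1, by = chunk)) {
    idx <- start + seq_len(min(chunk, n_worlds - start)) - 1
    B <- matrix(0, length(idx), m)
    pr <- rep(1, length(idx))
    for (i in seq_len(m)) {
      bit <- idx %% 2^i >= 2^(i - 1)
      B[, i] <- as.numeric(bit)
      pr <- pr * ifelse(bit, p[i], 1 - p[i])
    }
    res <- fun(B, pr)
    acc <- if (is.null(acc)) res else acc + res
  }
  acc
}

check_bruteforce_cap <- function(network, max_edges) {
  if (network$m > max_edges) {
    stop(sprintf(paste0(
      "intractable: %d edges means 2^%d possible worlds ",
      "(cap %d); use expected_modularity_fpwp() instead"),
      network$m, network$m, max_edges), call. = FALSE)
  }
}

#' Expected modularity by brute-force world enumeration
#'
#' Enumerates all `2^m` possible worlds, computes the community-form
#' modularity of each, and returns the probability-weighted mean
#' `E(Q) = sum_w Q_w Pr(w)`. Exponential in the edge count, but exact: it is
#' the correctness oracle for every other method in the package.
#'
#' @param network a [prob_network()].
#' @param clustering a [node_clustering()] covering the network's nodes.
#' @param max_edges refuse networks with more edges than this (default 25).
#' @return an object of class `expected_modularity`: list with `method`,
#'   `value`, `n_worlds` and `elapsed` (seconds).
#' @examples
#' net <- prob_network("a", "b", 0.8)
#' cl <- node_clustering(c("a", "b"), c("1", "2"))
#' expected_modularity_bruteforce(net, cl)$value  # -0.4
#' @export
expected_modularity_bruteforce <- function(network, clustering,
                                           max_edges = 25) {
  validate_inputs(network, clustering)
  check_bruteforce_cap(network, max_edges)
  t0 <- proc.time()[["elapsed"]]
  ind <- trisection_indicators(network, clustering)
  value <- enumerate_worlds(network, function(B, pr) {
    sum(modularity_batch(B, ind) * pr)
  })
  structure(
    list(method = "brute", value = value, n_worlds = 2^network$m,
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "expected_modularity"
  )
}

#' @export
print.expected_modularity <- function(x, ...) {
  cat(sprintf("Expected modularity (%s): %.6f\n", x$method, x$value))
  invisible(x)
}

#' Exact modularity distribution by world enumeration
#'
#' Aggregates world probabilities over worlds sharing the same modularity
#' value (values are merged at 1e-12 resolution), yielding the full discrete
#' distribution of modularity over the `2^m` possible worlds.
#'
#' @inheritParams expected_modularity_bruteforce
#' @return an object of class `modularity_distribution`: list with `support`
#'   (sorted distinct modularity values), `mass` (their probabilities) and
#'   `expectation`.
#' @export
modularity_distribution <- function(network, clustering, max_edges = 25) {
  validate_inputs(network, clustering)
  check_bruteforce_cap(network, max_edges)
  ind <- trisection_indicators(network, clustering)
  env <- new.env(parent = emptyenv())
  enumerate_worlds(network, function(B, pr) {
    q <- modularity_batch(B, ind)
    key <- sprintf("%.12f", q)
    for (lvl in unique(key)) {
      sel <- key == lvl
      prev <- if (exists(lvl, envir = env)) get(lvl, envir = env) else
        c(0, q[sel][1])   # exact representative of the merged group
      assign(lvl, c(prev[1] + sum(pr[sel]), prev[2]), envir = env)
    }
    0
  })
  keys <- ls(env)
  mass <- vapply(keys, function(k) get(k, envir = env)[1], 0)
  support <- vapply(keys, function(k) get(k, envir = env)[2], 0)
  keep <- mass > 0   # impossible worlds (deterministic edges) carry no atom
  mass <- mass[keep]
  support <- support[keep]
  ord <- order(support)
  support <- unname(support[ord])
  mass <- unname(mass[ord])
  structure(
    list(support = support, mass = mass,
         expectation = sum(support * mass)),
    class = "modularity_distribution"
  )
}

#' @export
print.modularity_distribution <- function(x, ...) {
  cat(sprintf("Modularity distribution: %d atoms, E(Q) = %.6f\n",
              length(x$support), x$expectation))
  invisible(x)
}
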