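#' Edge trisection of a community
#'
#' For a community `c`, splits the network's edges into the three disjoint
#' sets that drive the community form of modularity: *within* edges (both
#' endpoints in `c`), *cross* edges (exactly one endpoint in `c`) and
#' *outside* edges (no endpoint in `c`). Their sizes are the capacities
#' `T_x`, `T_y`, `T_z` with `T_x + T_y + T_z = m`.
#'
#' @param network a [prob_network()].
#' @param clustering a [node_clustering()] covering the network's nodes.
#' @param community a community label present in the clustering.
#' @return An object of class `edge_trisection`: list with logical index
#'   vectors `within`, `cross`, `outside` over the network's canonical edge
#'   order, capacities `T_x`, `T_y`, `T_z`, and the community label.
#' @export
edge_trisection <- function(network, clustering, community) {
  community <- as.character(community)
  if (!community %in% clustering$communities) {
    stop(sprintf("unknown community label '%s'", community), call. = FALSE)
  }
  lab <- clustering$membership
  in_u <- lab[network$edges[, "u"]] == community
  in_v <- lab[network$edges[, "v"]] == community
  within <- in_u & in_v
  cross <- xor(in_u, in_v)
  outside <- !in_u & !in_v
  structure(
    list(community = community, within = within, cross = cross,
         outside = outside,
         T_x = sum(within), T_y = sum(cross), T_z = sum(outside)),
    class = "edge_trisection"
  )
}

#' @export
print.edge_trisection <- function(x, ...) {
  cat(sprintf("Edge trisection of community '%s': T_x=%d, T_y=%d, T_z=%d\n",
              x$community, x$T_x, x$T_y, x$T_z))
  invisible(x)
}

# m x k 0/1 indicator matrices of within- and cross-community edge membership,
# columns in community order; shared by the community-form modularity, the
# sampler and the brute-force enumerator.
trisection_indicators <- function(network, clustering) {
  lab <- clustering$membership
  lu <- lab[network$edges[, "u"]]
  lv <- lab[network$edges[, "v"]]
  k <- clustering$k
  Win <- matrix(0, network$m, k)
  Cross <- matrix(0, network$m, k)
  for (j in seq_len(k)) {
    cj <- clustering$communities[j]
    iu <- lu == cj
    iv <- lv == cj
    Win[, j] <- as.numeric(iu & iv)
    Cross[, j] <- as.numeric(xor(iu, iv))
  }
  list(within = Win, cross = Cross)
}

# Vectorised community-form modularity for a batch of worlds.
# B: worlds x m matrix of 0/1 edge inclusions. Returns one Q per row,
# with the empty world mapped to 0 by convention.
modularity_batch <- function(B, ind) {
  mw <- rowSums(B)
  x <- B %*% ind$within   # worlds x k within-edge counts
  y <- B %*% ind$cross
  safe_m <- ifelse(mw == 0, 1, mw)
  qc <- x / safe_m - ((2 * x + y) / (2 * safe_m))^2
  q <- rowSums(qc)
  q[mw == 0] <- 0
  q
}

#' Modularity of a deterministic world, community form
#'
#' Evaluates modularity as a sum of per-community terms,
#' `Q = sum_c x_c/m - ((2 x_c + y_c) / (2m))^2`, where `x_c` and `y_c` count
#' the world's within- and cross-community edges for community `c` and `m`
#' is the world's edge count. This is the formulation the possible-world
#' partitioning algorithm builds on. The empty world (no edges) has
#' modularity 0 by convention: the formula is 0/0 there, and a single shared
#' convention keeps the exact, sampling and brute-force routes identical.
#'
#' @param world a [possible_world()].
#' @param clustering a [node_clustering()] covering the network's nodes.
#' @return the modularity value `Q` in `[-1, 1]`.
#' @examples
#' tri2 <- prob_network(c("a","b","c","d","e","f"),
#'                      c("b","c","a","e","f","d"), rep(1, 6))
#' cl <- node_clustering(letters[1:6], rep(c("1","2"), each = 3))
#' modularity_communities(full_world(tri2), cl)  # 0.5
#' @export
modularity_communities <- function(world, clustering) {
  net <- world$network
  validate_inputs(net, clustering)
  ind <- trisection_indicators(net, clustering)
  modularity_batch(matrix(as.numeric(world$present), 1), ind)[[1]]
}

#' Modularity of a deterministic world, adjacency form
#'
#' The textbook definition
#' `Q = 1/(2M) * sum_ij (A_ij - k_i k_j / (2M)) delta(x_i, x_j)` over ordered
#' node pairs, with `A` the world's adjacency matrix, `k_i` node degrees and
#' `M` the world's edge count. Algebraically identical to
#' [modularity_communities()]; kept as an independent formulation for
#' cross-checking. Empty world returns 0 by the shared convention.
#'
#' @inheritParams modularity_communities
#' @return the modularity value `Q`.
#' @export
modularity_adjacency <- function(world, clustering) {
  net <- world$network
  validate_inputs(net, clustering)
  M <- sum(world$present)
  if (M == 0) return(0)
  n <- net$n
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges[world$present, , drop = FALSE]
  A[cbind(e[, "u"], e[, "v"])] <- 1
  A[cbind(e[, "v"], e[, "u"])] <- 1
  deg <- rowSums(A)
  lab <- clustering$membership[net$nodes]
  delta <- outer(lab, lab, "==")
  sum((A - outer(deg, deg) / (2 * M)) * delta) / (2 * M)
}

#' Weighted modularity of a probabilistic network
#'
#' Baseline that treats edge probabilities as edge weights and evaluates the
#' standard weighted generalisation of modularity: `A_ij = p_ij`, total
#' weight `W = sum p_ij`, node strengths `s_i = sum_j p_ij`,
#' `Q_w = sum_c w_c/W - (S_c/(2W))^2` with `w_c` the within-community weight
#' and `S_c` the community strength sum. Because weights only enter as
#' ratios, scaling all probabilities by a common factor leaves the value
#' unchanged -- which is exactly why this baseline cannot track expected
#' modularity across uncertainty levels.
#'
#' @param network a nonempty [prob_network()].
#' @param clustering a [node_clustering()] covering the network's nodes.
#' @return the weighted modularity value.
#' @export
weighted_modularity <- function(network, clustering) {
  validate_inputs(network, clustering)
  if (network$m == 0) stop("weighted modularity needs at least one edge",
                           call. = FALSE)
  ind <- trisection_indicators(network, clustering)
  W <- sum(network$p)
  win_w <- as.numeric(network$p %*% ind$within)    # per-community within weight
  cross_w <- as.numeric(network$p %*% ind$cross)
  sum(win_w / W - ((2 * win_w + cross_w) / (2 * W))^2)
}
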