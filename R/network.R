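#' Construct a probabilistic network
#'
#' A probabilistic network is an undirected simple graph in which every edge
#' carries an independent existence probability in (0, 1]. Under possible-world
#' semantics the network is a generative model for deterministic graphs: each
#' of the `2^m` edge subsets is a *possible world* whose probability is the
#' product of its edge inclusion/exclusion probabilities.
#'
#' Edges are stored under the canonical (lexicographically sorted) endpoint
#' pair and ordered deterministically (radix order on endpoints), so that
#' enumeration, sampling streams and file round trips are reproducible across
#' platforms and locales. Node identifiers are opaque strings.
#'
#' @param u,v character vectors of edge endpoints (recycled pairwise).
#' @param p numeric vector of edge probabilities, each in (0, 1].
#' @param nodes optional character vector of node identifiers; endpoints are
#'   always added, so this is only needed to register isolated nodes.
#' @return An object of class `prob_network` with components `nodes`
#'   (sorted character vector), `edges` (m x 2 character matrix, each row
#'   sorted), `p` (numeric vector of probabilities), `n` and `m`.
#' @examples
#' net <- prob_network(c("a", "b"), c("b", "c"), c(0.8, 0.5))
#' net$m
#' @export
prob_network <- function(u, v, p, nodes = NULL) {
  u <- as.character(u)
  v <- as.character(v)
  p <- as.numeric(p)
  if (length(u) != length(v) || length(u) != length(p)) {
    stop("u, v and p must have equal length", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    bad <- which(!is.finite(p) | p <= 0 | p > 1)[1]
    stop(sprintf("edge %d: probability %s out of range (0,1]", bad,
                 format(p[bad])), call. = FALSE)
  }
  if (any(u == v)) {
    stop(sprintf("self-loop at node '%s' not allowed", u[u == v][1]),
         call. = FALSE)
  }
  # canonical unordered pair: smaller endpoint first (C-locale order)
  swap <- stri_gt(u, v)
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  key <- paste(u, v, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate edge: %s", gsub("\r", " -- ", dup)),
         call. = FALSE)
  }
  ord <- order(u, v, method = "radix")
  u <- u[ord]; v <- v[ord]; p <- p[ord]
  nodes <- sort(unique(c(nodes, u, v)), method = "radix")
  structure(
    list(nodes = nodes, edges = cbind(u = u, v = v), p = p,
         n = length(nodes), m = length(p)),
    class = "prob_network"
  )
}

# C-locale string "greater than", independent of the session locale
stri_gt <- function(a, b) {
  if (!length(a)) return(logical(0))
  lv <- sort(unique(c(a, b)), method = "radix")
  match(a, lv) > match(b, lv)
}

#' @export
print.prob_network <- function(x, ...) {
  cat(sprintf("Probabilistic network: %d nodes, %d edges\n", x$n, x$m))
  if (x$m > 0) {
    cat(sprintf("  edge probabilities in [%.3g, %.3g]\n",
                min(x$p), max(x$p)))
  }
  invisible(x)
}

#' Construct a node clustering
#'
#' A clustering is a total assignment of the network's nodes to community
#' labels (a partition of the node set). Labels are opaque strings, kept
#' verbatim; the community order is the deterministic sorted label order.
#'
#' @param nodes character vector of node identifiers.
#' @param labels character vector of community labels, parallel to `nodes`.
#' @return An object of class `node_clustering` with components `membership`
#'   (named character vector node -> label), `communities` (sorted unique
#'   labels) and `k`.
#' @examples
#' cl <- node_clustering(c("a", "b", "c"), c("1", "1", "2"))
#' cl$k
#' @export
node_clustering <- function(nodes, labels) {
  nodes <- as.character(nodes)
  labels <- as.character(labels)
  if (length(nodes) != length(labels)) {
    stop("nodes and labels must have equal length", call. = FALSE)
  }
  dup <- duplicated(nodes)
  if (any(dup)) {
    # duplicates are allowed only when they repeat the same label
    for (nd in unique(nodes[dup])) {
      if (length(unique(labels[nodes == nd])) > 1) {
        stop(sprintf("conflicting assignment for node '%s'", nd),
             call. = FALSE)
      }
    }
    labels <- labels[!dup]
    nodes <- nodes[!dup]
  }
  ord <- order(nodes, method = "radix")
  membership <- stats::setNames(labels[ord], nodes[ord])
  communities <- sort(unique(labels), method = "radix")
  structure(
    list(membership = membership, communities = communities,
         k = length(communities)),
    class = "node_clustering"
  )
}

#' @export
print.node_clustering <- function(x, ...) {
  cat(sprintf("Clustering: %d nodes in %d communities\n",
              length(x$membership), x$k))
  invisible(x)
}

#' Community sizes of a clustering
#' @param clustering a [node_clustering()].
#' @return named integer vector of community sizes, in community order.
#' @export
community_sizes <- function(clustering) {
  tab <- table(factor(clustering$membership, levels = clustering$communities))
  stats::setNames(as.integer(tab), clustering$communities)
}

split_fields <- function(lines, delimiter) {
  if (identical(delimiter, "") || is.null(delimiter)) {
    strsplit(trimws(lines), "[ \t]+")
  } else {
    strsplit(lines, delimiter, fixed = TRUE)
  }
}

#' Read a probabilistic edge list
#'
#' Parses the plain-text format `u <sep> v <sep> p`, one edge per line, where
#' `p` is the edge existence probability in (0, 1]. Lines starting with `#`
#' and blank lines are skipped. Endpoints are registered as nodes and the
#' edge is stored under its canonical sorted pair, so `u v p` and `v u p`
#' load to identical networks.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator; the default `""` splits on any run of
#'   whitespace.
#' @return a [prob_network()].
#' @seealso [write_probabilistic_edgelist()], [read_clustering()]
#' @export
read_probabilistic_edgelist <- function(path, delimiter = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- split_fields(lines[keep], delimiter)
  if (!length(fields)) return(prob_network(character(), character(), numeric()))
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("line %d: expected at least 3 fields (u, v, p)",
                 lineno[which(nf < 3)[1]]), call. = FALSE)
  }
  u <- vapply(fields, `[`, "", 1L)
  v <- vapply(fields, `[`, "", 2L)
  p <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(p)) {
    stop(sprintf("line %d: unparseable probability", lineno[which(is.na(p))[1]]),
         call. = FALSE)
  }
  bad <- p <= 0 | p > 1
  if (any(bad)) {
    stop(sprintf("line %d: probability %s out of range (0,1]",
                 lineno[which(bad)[1]], format(p[which(bad)[1]])),
         call. = FALSE)
  }
  if (any(u == v)) {
    stop(sprintf("line %d: self-loop not allowed", lineno[which(u == v)[1]]),
         call. = FALSE)
  }
  key <- vapply(seq_along(u), function(i)
    paste(sort(c(u[i], v[i]), method = "radix"), collapse = "\r"), "")
  if (anyDuplicated(key)) {
    stop(sprintf("line %d: duplicate edge", lineno[which(duplicated(key))[1]]),
         call. = FALSE)
  }
  prob_network(u, v, p)
}

#' Write a probabilistic edge list
#'
#' Inverse of [read_probabilistic_edgelist()]; probabilities are written at
#' full precision (17 significant digits) so that a read/write round trip is
#' exact.
#'
#' @param network a [prob_network()].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @export
write_probabilistic_edgelist <- function(network, path, delimiter = "\t") {
  lines <- sprintf("%s%s%s%s%.17g",
                   network$edges[, "u"], delimiter,
                   network$edges[, "v"], delimiter, network$p)
  writeLines(lines, path)
  invisible(path)
}

#' Export a deterministic world as a plain edge list
#'
#' Writes the edges present in a possible world as `u <sep> v` lines, the
#' standard deterministic edge-list format (no probability column).
#'
#' @param world a [possible_world()].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @export
write_world_edgelist <- function(world, path, delimiter = "\t") {
  e <- world$network$edges[world$present, , drop = FALSE]
  writeLines(sprintf("%s%s%s", e[, "u"], delimiter, e[, "v"]), path)
  invisible(path)
}

#' Read a node-community file
#'
#' Parses the plain-text format `node <sep> label`, one node per line, with
#' `#` comments. Labels are kept verbatim. A node listed twice with different
#' labels is rejected.
#'
#' @inheritParams read_probabilistic_edgelist
#' @return a [node_clustering()].
#' @export
read_clustering <- function(path, delimiter = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- split_fields(lines[keep], delimiter)
  if (!length(fields)) return(node_clustering(character(), character()))
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop(sprintf("line %d: expected 2 fields (node, label)",
                 lineno[which(nf < 2)[1]]), call. = FALSE)
  }
  node_clustering(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L))
}

#' Write a node-community file
#' @param clustering a [node_clustering()].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @export
write_clustering <- function(clustering, path, delimiter = "\t") {
  writeLines(sprintf("%s%s%s", names(clustering$membership), delimiter,
                     clustering$membership), path)
  invisible(path)
}

#' Validate a network / clustering pair
#'
#' Checks that the clustering is a partition of exactly the network's node
#' set, and returns a small summary report for logging.
#'
#' @param network a [prob_network()].
#' @param clustering a [node_clustering()].
#' @return invisibly, a list with `n`, `m`, `k` and the community `sizes`.
#'   Coverage violations raise an error naming the offending nodes.
#' @export
validate_inputs <- function(network, clustering) {
  covered <- names(clustering$membership)
  missing <- setdiff(network$nodes, covered)
  extra <- setdiff(covered, network$nodes)
  if (length(missing)) {
    stop(sprintf("uncovered nodes (in network, not in clustering): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(extra)) {
    stop(sprintf("unknown nodes (in clustering, not in network): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(list(n = network$n, m = network$m, k = clustering$k,
                 sizes = community_sizes(clustering)))
}

#' Possible worlds of a probabilistic network
#'
#' A possible world is one deterministic network obtainable from the
#' probabilistic network by fixing each edge as present or absent; it is
#' represented by a logical inclusion vector over the network's canonical
#' edge order.
#'
#' @param network a [prob_network()].
#' @param present logical vector of length `network$m`: which edges exist in
#'   this world.
#' @return an object of class `possible_world` (list with `network` and
#'   `present`).
#' @examples
#' net <- prob_network(c("a", "b"), c("b", "c"), c(0.8, 0.5))
#' w <- possible_world(net, c(TRUE, FALSE))
#' @export
possible_world <- function(network, present) {
  stopifnot(inherits(network, "prob_network"))
  present <- as.logical(present)
  if (length(present) != network$m || anyNA(present)) {
    stop("present must be a logical vector over the network's edges",
         call. = FALSE)
  }
  structure(list(network = network, present = present),
            class = "possible_world")
}

#' @rdname possible_world
#' @export
full_world <- function(network) {
  possible_world(network, rep(TRUE, network$m))
}

#' @export
print.possible_world <- function(x, ...) {
  cat(sprintf("Possible world: %d of %d edges present\n",
              sum(x$present), x$network$m))
  invisible(x)
}
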