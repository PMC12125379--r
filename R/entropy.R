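#' Entropy ratio of a probabilistic network
#'
#' The joint entropy of the independent edges is the sum of the per-edge
#' binary entropies, `H = -sum p log2 p - sum (1-p) log2 (1-p)`; dividing by
#' the edge count `m` normalises it to the `[0, 1]` *entropy ratio*, which
#' summarises how uncertain the network is independent of its size: 0 means
#' every edge is deterministic (`p = 1`), 1 means every edge is a fair coin
#' (`p = 0.5`). Base-2 logarithms are what make the range `[0, 1]`;
#' a uniform `p = 0.9` network, for instance, has entropy ratio 0.47.
#'
#' @param network a [prob_network()] with at least one edge.
#' @return the entropy ratio in `[0, 1]`.
#' @examples
#' net <- prob_network(c("a", "b"), c("b", "c"), c(0.5, 0.5))
#' entropy_ratio(net)  # 1
#' @export
entropy_ratio <- function(network) {
  if (network$m == 0) {
    stop("entropy ratio is undefined for an empty network", call. = FALSE)
  }
  mean(binary_entropy(network$p))
}

binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  q <- 1 - p[ok]
  h[ok] <- -p[ok] * log2(p[ok]) - q * log2(q)   # 0 log 0 := 0 at the ends
  h
}

#' Uniform edge probability achieving a target entropy ratio
#'
#' Inverts the per-edge binary entropy: returns the probability `p` with
#' `h(p)` equal to the target, so that a network whose edges all carry `p`
#' has exactly that entropy ratio. The binary entropy is symmetric about
#' 0.5, so the caller picks the branch: `"high"` gives `p >= 0.5` (the usual
#' choice when emulating mostly-present edges), `"low"` gives `p <= 0.5`.
#' Solved by bisection to 1e-12.
#'
#' @param target entropy ratio in `[0, 1]`.
#' @param branch `"high"` for `p >= 0.5`, `"low"` for `p <= 0.5`.
#' @return the probability.
#' @examples
#' probability_for_entropy_ratio(1)            # 0.5
#' probability_for_entropy_ratio(0.469, "high")  # ~0.90
#' @export
probability_for_entropy_ratio <- function(target,
                                          branch = c("high", "low")) {
  branch <- match.arg(branch)
  if (!is.numeric(target) || target < 0 || target > 1) {
    stop("target entropy ratio must lie in [0, 1]", call. = FALSE)
  }
  if (target == 1) return(0.5)
  lo <- if (branch == "high") 0.5 else 0
  hi <- if (branch == "high") 1 else 0.5
  if (target == 0) return(if (branch == "high") 1 else 0)
  # h is monotone on each half; bisect
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    hmid <- binary_entropy(mid)
    rising <- branch == "low"
    if ((hmid < target) == rising) lo <- mid else hi <- mid
    if (hi - lo < 1e-13) break
  }
  (lo + hi) / 2
}
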