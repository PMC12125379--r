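#' Sample one possible world
#'
#' Draws a deterministic world from the probabilistic network by including
#' each edge independently with its probability. One uniform variate is
#' consumed per edge, in the network's canonical edge order, from R's
#' current random stream -- so a fixed `seed` yields an identical world on
#' every platform.
#'
#' @param network a [prob_network()].
#' @param seed optional integer; when given, the draw uses an isolated RNG
#'   state seeded with it and leaves the session RNG untouched.
#' @return a [possible_world()].
#' @export
sample_world <- function(network, seed = NULL) {
  draw <- function() possible_world(network,
                                    stats::runif(network$m) < network$p)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Expected modularity by Monte Carlo sampling
#'
#' Draws `theta` independent possible worlds (each edge kept with its
#' probability) and averages their community-form modularity. Unbiased for
#' `E(Q)`, with Monte Carlo error shrinking as `1/sqrt(theta)`; convergence
#' is slowest for high-entropy networks, where the world distribution is
#' widest.
#'
#' The sampler consumes `theta * m` uniforms in world-major, canonical
#' edge-order sequence from a stream seeded with `seed`, so runs are exactly
#' reproducible and distinct seeds give independent streams.
#'
#' @param network a [prob_network()].
#' @param clustering a [node_clustering()] covering the network's nodes.
#' @param theta number of sampled worlds (>= 1).
#' @param seed integer seed for the sampling stream.
#' @param keep_samples retain the per-world modularities in the result?
#' @return an object of class `sampling_result`: list with `method`,
#'   `value` (the mean), `theta`, `seed`, `elapsed`, and `samples` when
#'   retained.
#' @export
sampling_expected_modularity <- function(network, clustering, theta,
                                         seed = 1L, keep_samples = FALSE) {
  validate_inputs(network, clustering)
  theta <- as.integer(theta)
  if (is.na(theta) || theta < 1) stop("theta must be >= 1", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  ind <- trisection_indicators(network, clustering)
  q <- withr::with_seed(as.integer(seed), {
    out <- numeric(theta)
    done <- 0L
    while (done < theta) {
      nb <- min(theta - done, 4096L)
      # world-major: row t holds the m draws of sample done + t
      U <- matrix(stats::runif(nb * network$m), nrow = nb, byrow = TRUE)
      B <- (U < matrix(network$p, nb, network$m, byrow = TRUE)) * 1
      out[done + seq_len(nb)] <- modularity_batch(B, ind)
      done <- done + nb
    }
    out
  })
  structure(
    list(method = "sample", value = mean(q), theta = theta,
         seed = as.integer(seed),
         elapsed = proc.time()[["elapsed"]] - t0,
         samples = if (keep_samples) q else NULL),
    class = c("sampling_result", "expected_modularity")
  )
}

#' Monte Carlo sampling under a time budget
#'
#' Repeatedly draws batches of possible worlds until `budget` seconds of
#' elapsed (monotonic) time have been spent, then returns the running mean
#' and the number of samples achieved. At least one sample is always drawn.
#' Used for time-accuracy comparisons against the exact algorithms.
#'
#' @inheritParams sampling_expected_modularity
#' @param budget time budget in seconds (> 0).
#' @param batch worlds drawn per clock check.
#' @return a `sampling_result` whose `theta` is the achieved sample count.
#' @export
sampling_time_budget <- function(network, clustering, budget, seed = 1L,
                                 batch = 64L) {
  validate_inputs(network, clustering)
  if (!is.numeric(budget) || budget <= 0) {
    stop("budget must be a positive number of seconds", call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  ind <- trisection_indicators(network, clustering)
  total <- 0
  theta <- 0L
  withr::with_seed(as.integer(seed), {
    repeat {
      U <- matrix(stats::runif(batch * network$m), nrow = batch,
                  byrow = TRUE)
      B <- (U < matrix(network$p, batch, network$m, byrow = TRUE)) * 1
      total <- total + sum(modularity_batch(B, ind))
      theta <- theta + batch
      if (proc.time()[["elapsed"]] - t0 >= budget) break
    }
  })
  structure(
    list(method = "sample", value = total / theta, theta = theta,
         seed = as.integer(seed),
         elapsed = proc.time()[["elapsed"]] - t0, samples = NULL),
    class = c("sampling_result", "expected_modularity")
  )
}

#' Modularity after probability thresholding
#'
#' Baseline that converts the probabilistic network into a deterministic one
#' by keeping exactly the edges with probability at or above the threshold
#' (edges with `p` *lower* than the threshold are removed), then evaluates
#' ordinary modularity on that single world. Accurate only for networks
#' that are nearly deterministic; the threshold choice dominates the result
#' otherwise.
#'
#' @param network a [prob_network()].
#' @param clustering a [node_clustering()] covering the network's nodes.
#' @param threshold probability cut in (0, 1].
#' @return the deterministic modularity of the thresholded world.
#' @export
threshold_modularity <- function(network, clustering, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  modularity_communities(possible_world(network, network$p >= threshold),
                         clustering)
}
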