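method_names <- c("brute", "pwp", "fpwp", "sample", "threshold", "weight")

#' Run one expected-modularity computation
#'
#' Dispatches a single computation over a network / clustering pair to one of
#' the implemented methods and returns a machine-readable result record.
#' This is the programmatic core of the `compute` command of the shipped
#' command-line tool.
#'
#' @param network a [prob_network()], or a path to a probabilistic edge-list
#'   file.
#' @param clustering a [node_clustering()], or a path to a node-community
#'   file.
#' @param method one of `"brute"`, `"pwp"`, `"fpwp"`, `"sample"`,
#'   `"threshold"`, `"weight"`.
#' @param theta sampling: number of worlds (ignored when `budget` is given).
#' @param budget sampling: time budget in seconds, instead of `theta`.
#' @param seed sampling: stream seed.
#' @param threshold thresholding: probability cut in (0, 1].
#' @param max_edges brute force: enumeration cap.
#' @param output optional path; when given, the result record is written
#'   there as JSON.
#' @return a list record with `method`, `value`, diagnostics (per-community
#'   terms, cells or theta where applicable), `elapsed` and the echoed
#'   parameters.
#' @examples
#' net <- prob_network("a", "b", 0.8)
#' cl <- node_clustering(c("a", "b"), c("1", "2"))
#' run_compute(net, cl, method = "fpwp")$value  # -0.4
#' @export
run_compute <- function(network, clustering, method = method_names,
                        theta = 1000L, budget = NULL, seed = 1L,
                        threshold = 0.5, max_edges = 25, output = NULL) {
  method <- match.arg(method)
  if (is.character(network)) network <- read_probabilistic_edgelist(network)
  if (is.character(clustering)) clustering <- read_clustering(clustering)
  validate_inputs(network, clustering)
  t0 <- proc.time()[["elapsed"]]
  res <- switch(
    method,
    brute = expected_modularity_bruteforce(network, clustering,
                                           max_edges = max_edges),
    pwp = expected_modularity_pwp(network, clustering),
    fpwp = expected_modularity_fpwp(network, clustering),
    sample = if (is.null(budget)) {
      sampling_expected_modularity(network, clustering, theta = theta,
                                   seed = seed)
    } else {
      sampling_time_budget(network, clustering, budget = budget,
                           seed = seed)
    },
    threshold = list(method = "threshold",
                     value = threshold_modularity(network, clustering,
                                                  threshold),
                     threshold = threshold),
    weight = list(method = "weight",
                  value = weighted_modularity(network, clustering))
  )
  record <- list(
    method = res$method, value = res$value,
    n = network$n, m = network$m, k = clustering$k,
    terms = res$terms, cells = res$cells, theta = res$theta,
    seed = res$seed, threshold = res$threshold,
    elapsed = res$elapsed %||% (proc.time()[["elapsed"]] - t0)
  )
  record <- record[!vapply(record, is.null, TRUE)]
  if (!is.null(output)) {
    jsonlite::write_json(record, output, auto_unbox = TRUE, digits = NA)
  }
  record
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Desk-scale method-comparison study
#'
#' Runs a grid of (network condition) x (method) x (repeat) computations on
#' planted-partition networks with entropy-controlled uniform probabilities,
#' and returns one tidy row per run -- the package's reproduction, at desk
#' scale, of the published sampling-convergence, weighting and thresholding
#' comparisons.
#'
#' Each condition builds a planted-partition topology (parameters in
#' `conditions`), assigns the uniform probability matching the condition's
#' entropy ratio (high branch), and evaluates the requested methods.
#' Sampling repeats use stream seeds `seed + rep`, so every row is
#' reproducible from its logged `(condition, method, seed)` triple.
#'
#' @param conditions data frame with columns `k`, `nc`, `p_in`, `p_out`,
#'   `entropy` (target entropy ratio); one row per network condition.
#' @param methods character vector drawn from
#'   `c("fpwp", "sample", "threshold", "weight")`.
#' @param repeats number of repeated runs per condition for stochastic
#'   methods (deterministic methods run once).
#' @param theta sampling: worlds per run.
#' @param thresholds thresholding: probability cuts to sweep (one row each).
#' @param seed master seed; topology uses `seed`, repeat `r` uses
#'   `seed + r`.
#' @return a data frame with columns `condition`, `k`, `nc`, `p_in`,
#'   `p_out`, `entropy`, `method`, `param`, `rep`, `seed`, `value`,
#'   `elapsed`. Rows where a method fails carry `NA` value and the error
#'   message in `note`.
#' @export
run_comparison_study <- function(conditions,
                                 methods = c("fpwp", "sample", "threshold",
                                             "weight"),
                                 repeats = 5L, theta = 1000L,
                                 thresholds = seq(0.1, 0.9, by = 0.2),
                                 seed = 1L) {
  stopifnot(all(c("k", "nc", "p_in", "p_out", "entropy") %in%
                  names(conditions)))
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  add <- function(cond_id, cond, method, param, rep_i, run_seed, value,
                  elapsed, note = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      condition = cond_id, k = cond$k, nc = cond$nc, p_in = cond$p_in,
      p_out = cond$p_out, entropy = cond$entropy, method = method,
      param = param, rep = rep_i, seed = run_seed, value = value,
      elapsed = elapsed, note = note, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(conditions))) {
    cond <- conditions[i, ]
    gen <- generate_planted_partition(cond$k, cond$nc, cond$p_in,
                                      cond$p_out, seed = seed)
    p_unif <- probability_for_entropy_ratio(cond$entropy, "high")
    net <- assign_edge_probabilities(gen$network, "uniform", p = p_unif)
    cl <- gen$clustering
    for (method in methods) {
      runs <- switch(method,
                     sample = seq_len(repeats),
                     threshold = seq_along(thresholds),
                     1L)
      for (r in runs) {
        run_seed <- as.integer(seed) + r
        param <- switch(method, sample = theta,
                        threshold = thresholds[r], NA_real_)
        t0 <- proc.time()[["elapsed"]]
        value <- tryCatch(
          switch(method,
                 fpwp = expected_modularity_fpwp(net, cl)$value,
                 sample = sampling_expected_modularity(
                   net, cl, theta = theta, seed = run_seed)$value,
                 threshold = threshold_modularity(net, cl, thresholds[r]),
                 weight = weighted_modularity(net, cl)),
          error = function(e) e)
        elapsed <- proc.time()[["elapsed"]] - t0
        if (inherits(value, "error")) {
          add(i, cond, method, param, r, run_seed, NA_real_, elapsed,
              conditionMessage(value))
        } else {
          add(i, cond, method, param, r, run_seed, value, elapsed)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summary line of a probabilistic network
#'
#' Backs the `inspect` command: node/edge counts, entropy ratio and, when a
#' clustering is supplied, the community count and sizes.
#'
#' @param network a [prob_network()] or a path to an edge-list file.
#' @param clustering optional [node_clustering()] or path.
#' @return a list with `n`, `m`, `entropy_ratio`, and `k`/`sizes` when a
#'   clustering was given.
#' @export
inspect_network <- function(network, clustering = NULL) {
  if (is.character(network)) network <- read_probabilistic_edgelist(network)
  out <- list(n = network$n, m = network$m,
              entropy_ratio = if (network$m > 0) entropy_ratio(network)
              else NA_real_)
  if (!is.null(clustering)) {
    if (is.character(clustering)) clustering <- read_clustering(clustering)
    validate_inputs(network, clustering)
    out$k <- clustering$k
    out$sizes <- community_sizes(clustering)
  }
  out
}
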