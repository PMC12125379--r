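#' Poisson-binomial probability mass functions
#'
#' The number of successes among independent, non-identically distributed
#' Bernoulli trials follows the Poisson-binomial distribution. In this
#' package the trials are the edges of one part of a community's edge
#' trisection and a "success" is the edge existing in a possible world, so
#' these pmfs are the building blocks of the possible-world partitioning
#' algorithms. Three engines are provided:
#'
#' * `poisbin_pmf_enum()` -- literal subset enumeration: `pmf[k]` sums, over
#'   all size-`k` subsets `A` of the trials, the product of `p` over `A` and
#'   `1 - p` off `A`. Exponential; guarded at `max_trials` (default 20).
#' * `poisbin_pmf_conv()` -- exact dynamic-programming convolution of the
#'   `(1 - p_i, p_i)` kernels; `O(T^2)`. The internal cross-check engine.
#' * `poisbin_pmf_dft()` -- the closed form via the discrete Fourier
#'   transform: `pmf[k] = 1/(T+1) * sum_l C^(-lk) prod_i (1 + (C^l - 1) p_i)`
#'   with `C = exp(2i*pi/(T+1))`; exact in exact arithmetic, `O(T^2)`.
#'   Tiny negative entries from floating-point roundoff are clamped to zero
#'   and the pmf renormalised; a total mass off 1 by more than `1e-8` after
#'   clamping raises an error.
#'
#' All engines return the same pmf up to floating point; the DFT engine is
#' the production path (used by FPWP), enumeration mirrors the formal
#' definition (used by PWP), and convolution is the independent referee.
#'
#' @param probs numeric vector of success probabilities in `[0, 1]`.
#' @param max_trials enumeration guard: refuse more than this many trials.
#' @return An object of class `count_distribution`: list with `probs` and
#'   `pmf` (numeric vector of length `length(probs) + 1`; `pmf[k + 1]` is
#'   `Pr(count = k)`).
#' @examples
#' poisbin_pmf_enum(c(0.8, 0.5))$pmf   # 0.1 0.5 0.4
#' poisbin_pmf_dft(c(0.8, 0.5))$pmf    # identical
#' @name poisson_binomial
NULL

count_distribution <- function(probs, pmf) {
  structure(list(probs = probs, pmf = pmf), class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("Poisson-binomial count distribution on %d trials, mean %.4f\n",
              length(x$probs), sum(seq_along(x$pmf[-1]) * x$pmf[-1])))
  invisible(x)
}

check_probs <- function(probs) {
  probs <- as.numeric(probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("success probabilities must lie in [0, 1]", call. = FALSE)
  }
  probs
}

#' @rdname poisson_binomial
#' @export
poisbin_pmf_enum <- function(probs, max_trials = 20) {
  probs <- check_probs(probs)
  t_len <- length(probs)
  if (t_len > max_trials) {
    stop(sprintf("enumeration over 2^%d subsets refused (cap %d); use %s",
                 t_len, max_trials,
                 "poisbin_pmf_dft() or poisbin_pmf_conv()"), call. = FALSE)
  }
  # doubling construction: after trial i, w holds the probability and cnt
  # the success count of each of the 2^i subsets
  w <- 1
  cnt <- 0L
  for (p in probs) {
    w <- c(w * (1 - p), w * p)
    cnt <- c(cnt, cnt + 1L)
  }
  pmf <- as.numeric(rowsum(w, cnt))
  count_distribution(probs, pmf)
}

#' @rdname poisson_binomial
#' @export
poisbin_pmf_conv <- function(probs) {
  probs <- check_probs(probs)
  pmf <- 1
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  count_distribution(probs, pmf)
}

#' @rdname poisson_binomial
#' @export
poisbin_pmf_dft <- function(probs) {
  probs <- check_probs(probs)
  t_len <- length(probs)
  N <- t_len + 1
  C <- exp(2i * pi / N)
  z <- vapply(0:t_len,
              function(l) prod(1 + (C^l - 1) * probs),
              complex(1))
  pmf <- Re(stats::fft(z)) / N   # fft gives sum_l z_l C^(-lk)
  pmf[pmf < 0] <- 0
  s <- sum(pmf)
  if (abs(s - 1) > 1e-8) {
    stop(sprintf(
      "DFT pmf failed to normalise (total mass %.12g on %d trials)",
      s, t_len), call. = FALSE)
  }
  count_distribution(probs, pmf / s)
}
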