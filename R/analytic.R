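# Closed-form model of aggregated AP-MS testing: every protein u is selected
# b(u) times as bait and each selection tests u against the whole proteome;
# an edge enters the observed network if at least one test is positive. With
# an Erdos-Renyi ground truth (edge probability p) and per-test error rates
# FPR/FNR, edge and degree probabilities are available in closed form.

#' Observed edge probability under aggregated bait testing
#'
#' Probability that the unordered pair \{u, v\} appears in the observed
#' network when u and v were selected `bu` and `bv` times as bait:
#' \deqn{p_{uv} = p (1 - FNR^{b_u + b_v}) + (1 - p)(1 - (1 - FPR)^{b_u + b_v}).}
#' The convention \eqn{0^0 = 1} makes a never-tested pair unobservable.
#'
#' @param bu,bv Bait-usage counts of the two proteins (vectorised).
#' @param p Ground-truth edge probability.
#' @param fpr,fnr Per-test false-positive and false-negative rates.
#' @return Numeric vector of probabilities.
#' @examples
#' obs_edge_prob(1, 0, p = 0, fpr = 0.5) # 0.5
#' obs_edge_prob(0, 0, p = 0.3, fpr = 0.1) # 0: untested pair
#' @export
obs_edge_prob <- function(bu, bv, p, fpr, fnr = 0) {
  p <- check_prob(p, "p"); fpr <- check_prob(fpr, "fpr"); fnr <- check_prob(fnr, "fnr")
  b <- bu + bv
  p * (1 - fnr^b) + (1 - p) * (1 - (1 - fpr)^b)
}

#' Directed observed edge probability (v as bait)
#'
#' Probability that the ordered pair (u, v) is observed as a consequence of
#' testing with v as bait only:
#' \deqn{p_{(u,v)} = p (1 - FNR^{b_v}) + (1 - p)(1 - (1 - FPR)^{b_v}).}
#' Satisfies the sandwich \eqn{p_{(u,v)} \le p_{uv} \le p_{(u,v)} + p_{(v,u)}}.
#'
#' @param bv Bait-usage count of the bait protein (vectorised).
#' @inheritParams obs_edge_prob
#' @return Numeric vector of probabilities.
#' @export
obs_edge_prob_directed <- function(bv, p, fpr, fnr = 0) {
  p <- check_prob(p, "p"); fpr <- check_prob(fpr, "fpr"); fnr <- check_prob(fnr, "fnr")
  p * (1 - fnr^bv) + (1 - p) * (1 - (1 - fpr)^bv)
}

#' First-order bounds on the expected observed degree
#'
#' For small FPR, the expected observed degree of protein v is sandwiched as
#' \deqn{(1-p)\,FPR\,(n-1)\,b(v) \;\le\; E[\deg(v)] \;\le\;
#'       (1-p)\,FPR\,(n-1)\,b(v) + A,}
#' with the uniform additive constant \eqn{A = p n + (1 - p)\,FPR\,B} and
#' \eqn{B = \sum_u b(u)}. The bounds use the first-order approximation
#' \eqn{(1-FPR)^a \approx 1 - a\,FPR}, meaningful when `fpr * max(b)` is small.
#'
#' @param usage Integer vector of bait-usage counts for all n proteins.
#' @param p Ground-truth edge probability.
#' @param fpr Per-test false-positive rate.
#' @param v Node index (or indices) whose degree bounds are requested;
#'   defaults to all nodes.
#' @return A list with numeric vectors `lower`, `upper` and the scalar `A`.
#' @export
expected_degree_bounds <- function(usage, p, fpr, v = seq_along(usage)) {
  p <- check_prob(p, "p"); fpr <- check_prob(fpr, "fpr")
  n <- length(usage)
  B <- sum(usage)
  A <- p * n + (1 - p) * fpr * B
  lower <- (1 - p) * fpr * (n - 1) * usage[v]
  list(lower = lower, upper = lower + A, A = A)
}

#' Expected bait usage under the power-law usage model
#'
#' Mean of the bait-usage distribution with a point mass `zero_frac` at zero
#' and a discrete power law (exponent `alpha`, cutoff 1) otherwise:
#' \deqn{E[b] = (1 - zero\_frac)\,\zeta(\alpha - 1) / \zeta(\alpha).}
#' At the catalog-calibrated defaults (`alpha = 3.13`, `zero_frac = 0.24`)
#' this is approximately 0.99.
#'
#' @param alpha Power-law exponent of the positive part; must exceed 2 for the
#'   mean to be finite.
#' @param zero_frac Probability of zero usage (never tested as bait).
#' @return Scalar mean bait usage.
#' @examples
#' expected_bait_usage() # about 0.99
#' @export
expected_bait_usage <- function(alpha = 3.13, zero_frac = 0.24) {
  zero_frac <- check_prob(zero_frac, "zero_frac")
  if (alpha <= 2) {
    stop_baitbias("`alpha` must exceed 2 for a finite mean", "baitbias_invalid_parameter")
  }
  (1 - zero_frac) * hurwitz_zeta(alpha - 1) / hurwitz_zeta(alpha)
}

#' Sample bait-usage counts from the power-law usage model
#'
#' Draws i.i.d. bait-usage counts: zero with probability `zero_frac`
#' (proteins never tested as bait), otherwise from the discrete power law
#' with exponent `alpha` and cutoff `kmin`. The defaults (`alpha = 3.13`,
#' `zero_frac = 0.24`) match the bait-usage statistics of large aggregated
#' PPI catalogs.
#'
#' @param n Number of proteins.
#' @param alpha Power-law exponent (> 1).
#' @param zero_frac Probability of zero usage.
#' @param kmin Cutoff of the positive part (default 1).
#' @param seed Optional integer seed.
#' @return Integer vector of length `n` of non-negative usage counts.
#' @examples
#' b <- rbait_usage(10000, seed = 1)
#' mean(b == 0) # about 0.24
#' @export
rbait_usage <- function(n, alpha = 3.13, zero_frac = 0.24, kmin = 1, seed = NULL) {
  n <- check_count(n, "n", min = 1)
  zero_frac <- check_prob(zero_frac, "zero_frac")
  with_seed(seed, {
    out <- integer(n)
    pos <- stats::runif(n) >= zero_frac
    if (any(pos)) out[pos] <- rpowerlaw(sum(pos), alpha, kmin)
    out
  })
}

# Binomial draw supporting a number of trials beyond .Machine$integer.max by
# chunking; exact, not an approximation.
rbinom_big <- function(size, prob) {
  if (prob <= 0 || size <= 0) return(0)
  imax <- .Machine$integer.max
  if (size <= imax) return(stats::rbinom(1L, as.integer(size), prob))
  full <- floor(size / imax)
  rest <- size - full * imax
  sum(stats::rbinom(full, imax, prob)) + stats::rbinom(1L, as.integer(rest), prob)
}

#' Simulate aggregated AP-MS testing in one shot
#'
#' Samples the observed network of the closed-form aggregated testing model
#' directly, without iterating over studies: each unordered pair \{u, v\} is
#' included independently with probability [obs_edge_prob()] evaluated at the
#' pair's bait usages, and the degree sequence of the resulting network is
#' returned.
#'
#' Proteins are grouped by usage value; within each pair of usage classes the
#' edge probability is constant, so the number of edges is a single binomial
#' draw assigned uniformly to distinct member pairs. The cost is near-linear
#' in n plus the realised edge count, which makes proteome-scale runs
#' (n of order 10^4) take seconds.
#'
#' @param usage Integer vector of bait-usage counts, one per protein (e.g.
#'   from [rbait_usage()]).
#' @param fpr Per-test false-positive rate.
#' @param p Ground-truth Erdős–Rényi edge probability (default 0: empty
#'   ground truth).
#' @param fnr Per-test false-negative rate (default 0).
#' @param seed Optional integer seed.
#' @return Integer degree sequence of length `length(usage)`.
#' @examples
#' b <- rbait_usage(2000, seed = 1)
#' deg <- simulate_apms_degrees(b, fpr = 1 / 2000, seed = 2)
#' mean(deg) # about mean(b) + 0.99 for this calibration
#' @export
simulate_apms_degrees <- function(usage, fpr, p = 0, fnr = 0, seed = NULL) {
  if (!is.numeric(usage) || length(usage) < 2 || any(usage < 0) ||
      any(usage != floor(usage))) {
    stop_baitbias("`usage` must be a vector (length >= 2) of non-negative integers",
                  "baitbias_invalid_parameter")
  }
  p <- check_prob(p, "p"); fpr <- check_prob(fpr, "fpr"); fnr <- check_prob(fnr, "fnr")
  n <- length(usage)
  with_seed(seed, {
    deg <- integer(n)
    classes <- split(seq_len(n), usage)
    kvals <- as.numeric(names(classes))
    nc <- length(classes)
    for (c1 in seq_len(nc)) {
      for (c2 in c1:nc) {
        members1 <- classes[[c1]]
        members2 <- classes[[c2]]
        pe <- obs_edge_prob(kvals[c1], kvals[c2], p, fpr, fnr)
        if (pe <= 0) next
        if (c1 == c2) {
          m1 <- as.double(length(members1))
          npairs <- m1 * (m1 - 1) / 2
          if (npairs < 1) next
          e <- rbinom_big(npairs, pe)
          if (e == 0) next
          ij <- unrank_pairs(sample(npairs, e))
          deg <- deg + tabulate(members1[ij], nbins = n)
        } else {
          npairs <- as.double(length(members1)) * length(members2)
          e <- rbinom_big(npairs, pe)
          if (e == 0) next
          slot <- sample(npairs, e) - 1
          i <- members1[slot %% length(members1) + 1]
          j <- members2[slot %/% length(members1) + 1]
          deg <- deg + tabulate(c(i, j), nbins = n)
        }
      }
    }
    deg
  })
}
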