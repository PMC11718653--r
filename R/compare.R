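# Distribution-level comparison of an observed degree distribution against
# ensembles of simulated networks: earth mover's distance on the integer
# line, the signed sum-of-distances difference (Delta SOD), and K-NN origin
# classification.

#' Empirical degree distribution
#'
#' Normalised probability mass function of a degree sequence (or of the
#' degree sequence of a graph).
#'
#' @param x Integer vector of degrees, a `"ppi_graph"`, or a named numeric
#'   vector that already is a PMF (names = degree values).
#' @return An object of class `"deg_dist"`: named numeric PMF over the
#'   observed support.
#' @examples
#' degree_distribution(c(0, 1, 1, 2))
#' @export
degree_distribution <- function(x) {
  if (inherits(x, "deg_dist")) return(x)
  if (inherits(x, "ppi_graph")) x <- degree_sequence(x)
  if (!is.null(names(x))) {
    support <- as.numeric(names(x))
    if (any(is.na(support)) || any(support < 0) || any(support != floor(support))) {
      stop_baitbias("PMF names must be non-negative integers", "baitbias_invalid_input")
    }
    if (abs(sum(x) - 1) > 1e-12 || any(x < 0)) {
      stop_baitbias("PMF must be non-negative and sum to 1", "baitbias_invalid_input")
    }
    ord <- order(support)
    return(structure(as.numeric(x)[ord], names = support[ord], class = "deg_dist"))
  }
  if (!is.numeric(x) || length(x) == 0 || any(x < 0) || any(x != floor(x))) {
    stop_baitbias("degrees must be non-negative integers", "baitbias_invalid_input")
  }
  tab <- table(x) / length(x)
  structure(as.numeric(tab), names = names(tab), class = "deg_dist")
}

#' @export
print.deg_dist <- function(x, ...) {
  cat(sprintf("Degree distribution on %d support points (mean %.3f)\n",
              length(x), sum(as.numeric(names(x)) * x)))
  invisible(x)
}

#' Earth mover's distance between two degree distributions
#'
#' First Wasserstein distance between two PMFs on the non-negative integers,
#' computed as the sum of absolute CDF differences (unit transport cost per
#' integer step). Symmetric, zero iff the distributions coincide.
#'
#' @param p,q Degree distributions (anything accepted by
#'   [degree_distribution()]).
#' @return Non-negative scalar distance.
#' @examples
#' emd(c(1, 1, 1), c(3, 3, 3)) # point masses at 1 and 3: distance 2
#' @export
emd <- function(p, q) {
  p <- degree_distribution(p)
  q <- degree_distribution(q)
  sp <- as.numeric(names(p)); sq <- as.numeric(names(q))
  hi <- max(sp, sq)
  fp <- fq <- numeric(hi + 1)
  fp[sp + 1] <- p
  fq[sq + 1] <- q
  sum(abs(cumsum(fp) - cumsum(fq)))
}

#' Signed sum-of-distances difference between two ensembles
#'
#' Given distances `d_ba` from a reference distribution to an ensemble
#' simulated from power-law (BA) ground truths, and `d_er` to an ensemble
#' from binomial (ER) ground truths, computes
#' \deqn{\Delta SOD = (\sum d_{BA} - \sum d_{ER}) / \sum d_{ER}}
#' (the default form), or the range-normalised variant dividing by
#' \eqn{\max(\sum d_{BA}, \sum d_{ER})}, which is guaranteed to lie in
#' `[-1, 1]`. Negative values mean the reference is closer to the power-law
#' origin ensemble.
#'
#' @param d_ba,d_er Non-empty numeric distance vectors.
#' @param normalized Use the range-normalised denominator? Default `FALSE`
#'   (the plain form).
#' @return Scalar Delta SOD.
#' @export
delta_sod <- function(d_ba, d_er, normalized = FALSE) {
  if (!length(d_ba) || !length(d_er)) {
    stop_baitbias("both ensembles must be non-empty", "baitbias_invalid_input")
  }
  sba <- sum(d_ba); ser <- sum(d_er)
  denom <- if (normalized) max(sba, ser) else ser
  if (denom == 0) {
    if (sba == 0) return(0)
    stop_baitbias("sum of ER distances is zero; use `normalized = TRUE`",
                  "baitbias_undefined_division")
  }
  (sba - ser) / denom
}

#' K-NN origin probabilities
#'
#' Sorts all ensemble members by distance to the reference (ties broken by
#' label, power-law ensemble first, then insertion index) and returns the
#' fraction of power-law-origin members among the K nearest, interpreted as
#' the probability that the reference emerged from a power-law ground truth.
#'
#' @param d_ba,d_er Distance vectors to the power-law and binomial ensembles.
#' @param K Neighbourhood size(s), each between 1 and
#'   `length(d_ba) + length(d_er)`. Defaults to all possible K.
#' @return Data frame with columns `K`, `prob_pl`, `prob_binom`
#'   (`prob_pl + prob_binom == 1` for every K).
#' @export
knn_origin <- function(d_ba, d_er, K = seq_len(length(d_ba) + length(d_er))) {
  total <- length(d_ba) + length(d_er)
  if (!length(d_ba) || !length(d_er)) {
    stop_baitbias("both ensembles must be non-empty", "baitbias_invalid_input")
  }
  if (any(K < 1) || any(K > total) || any(K != floor(K))) {
    stop_baitbias("`K` must be integers in [1, total ensemble size]",
                  "baitbias_invalid_parameter")
  }
  dist <- c(d_ba, d_er)
  label_pl <- c(rep(TRUE, length(d_ba)), rep(FALSE, length(d_er)))
  ord <- order(dist, !label_pl, seq_along(dist))
  is_pl <- cumsum(label_pl[ord])
  prob_pl <- is_pl[K] / K
  data.frame(K = as.integer(K), prob_pl = prob_pl, prob_binom = 1 - prob_pl)
}

#' Compare a reference degree distribution against two simulated ensembles
#'
#' Computes EMD distances from a reference distribution to every member of a
#' power-law-origin ensemble and a binomial-origin ensemble, both Delta SOD
#' variants, and K-NN origin probabilities for all K.
#'
#' @param ref Reference degree distribution (or degree vector / graph).
#' @param ens_ba,ens_er Lists of degree distributions (or degree vectors /
#'   graphs) simulated from power-law and binomial ground truths.
#' @return Object of class `"ensemble_comparison"` with components `d_ba`,
#'   `d_er`, `delta_sod`, `delta_sod_normalized`, and `knn` (data frame).
#' @export
compare_to_ensembles <- function(ref, ens_ba, ens_er) {
  ref <- degree_distribution(ref)
  d_ba <- vapply(ens_ba, function(g) emd(ref, g), numeric(1))
  d_er <- vapply(ens_er, function(g) emd(ref, g), numeric(1))
  structure(
    list(d_ba = d_ba, d_er = d_er,
         delta_sod = tryCatch(delta_sod(d_ba, d_er),
                              baitbias_undefined_division = function(e) NA_real_),
         delta_sod_normalized = delta_sod(d_ba, d_er, normalized = TRUE),
         knn = knn_origin(d_ba, d_er)),
    class = "ensemble_comparison"
  )
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat("Reference vs simulated ensembles\n")
  cat(sprintf("  sum EMD to power-law origin: %.4f (n = %d)\n",
              sum(x$d_ba), length(x$d_ba)))
  cat(sprintf("  sum EMD to binomial origin:  %.4f (n = %d)\n",
              sum(x$d_er), length(x$d_er)))
  cat(sprintf("  Delta SOD = %.4f (normalised: %.4f)\n",
              x$delta_sod, x$delta_sod_normalized))
  k <- min(10, nrow(x$knn))
  cat(sprintf("  K-NN Pr[power-law origin] at K = %d: %.2f\n",
              k, x$knn$prob_pl[k]))
  invisible(x)
}

#' Locate the FPR tipping point of Delta SOD
#'
#' Finds the first consecutive pair of an increasing FPR grid where Delta SOD
#' changes sign from negative to non-negative.
#'
#' @param delta_sods Numeric Delta SOD values; `names(delta_sods)` are the
#'   FPR grid values unless `fpr` is given.
#' @param fpr Optional numeric FPR grid (same length, strictly increasing).
#' @return A list of class `"tipping_point"`: `found` flag and, when found,
#'   `fpr_below`, `fpr_above` bracketing the sign change.
#' @examples
#' tipping_point(c(`0.00625` = -0.2, `0.0125` = 0.1))
#' @export
tipping_point <- function(delta_sods, fpr = NULL) {
  fpr <- fpr %||% suppressWarnings(as.numeric(names(delta_sods)))
  if (length(delta_sods) < 2 || length(fpr) != length(delta_sods) || any(is.na(fpr))) {
    stop_baitbias("need >= 2 Delta SOD values keyed by an FPR grid",
                  "baitbias_invalid_input")
  }
  ord <- order(fpr)
  fpr <- fpr[ord]; v <- delta_sods[ord]
  if (any(diff(fpr) <= 0)) {
    stop_baitbias("FPR grid values must be distinct", "baitbias_invalid_input")
  }
  cross <- which(v[-length(v)] < 0 & v[-1] >= 0)
  if (!length(cross)) {
    return(structure(list(found = FALSE, fpr_below = NA_real_, fpr_above = NA_real_),
                     class = "tipping_point"))
  }
  i <- cross[1]
  structure(list(found = TRUE, fpr_below = fpr[i], fpr_above = fpr[i + 1]),
            class = "tipping_point")
}

#' @export
print.tipping_point <- function(x, ...) {
  if (x$found) {
    cat(sprintf("Delta SOD sign change between FPR = %g and FPR = %g\n",
                x$fpr_below, x$fpr_above))
  } else {
    cat("No Delta SOD sign change in the FPR range\n")
  }
  invisible(x)
}
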