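# Iterative simulator of biased aggregated PPI testing. Studies are simulated
# one after the other; baits are drawn preferentially towards proteins that
# already have high degree in the current observed network (the study-bias
# feedback loop), every bait x prey pair is tested with per-test error rates,
# and a pair enters the observed network once its positive fraction clears
# the acceptance threshold gamma.
#
# Pair counters are kept as dense integer matrices over the upper triangle
# (u < v), which targets ground truths up to a few thousand nodes; the
# closed-form model (simulate_apms_degrees) covers proteome-scale runs.

MAX_SIM_NODES <- 5000L

#' Simulation configuration for biased aggregated testing
#'
#' @param study_sizes Two-column matrix or data frame of per-study sizes
#'   `(n_bait, n_prey)`; the number of rows is the number of simulated
#'   experiments.
#' @param method Test method: `"AP-MS"` (preys sampled uniformly) or `"Y2H"`
#'   (preys also degree-biased).
#' @param fnr,fpr Per-test false-negative and false-positive rates.
#' @param gamma Acceptance threshold in `[0, 1)`: a pair is an edge when its
#'   positive fraction strictly exceeds `gamma` (and is positive at least
#'   once).
#' @param delta Baseline sampling weight added to every degree (default 0.01),
#'   so untested proteins retain a small selection probability.
#' @param seed Optional integer seed for the whole simulation.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(study_sizes, method = c("AP-MS", "Y2H"),
                       fnr = 0, fpr = 0, gamma = 0, delta = 0.01, seed = NULL) {
  method <- match.arg(method)
  fnr <- check_prob(fnr, "fnr"); fpr <- check_prob(fpr, "fpr")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma >= 1) {
    stop_baitbias("`gamma` must lie in [0, 1)", "baitbias_invalid_parameter")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop_baitbias("`delta` must be positive", "baitbias_invalid_parameter")
  }
  study_sizes <- as.matrix(study_sizes)
  if (ncol(study_sizes) != 2 || nrow(study_sizes) < 1 ||
      any(study_sizes < 1) || any(study_sizes != floor(study_sizes))) {
    stop_baitbias("`study_sizes` must be a positive integer matrix with columns (n_bait, n_prey)",
                  "baitbias_invalid_parameter")
  }
  structure(
    list(method = method, fnr = fnr, fpr = fpr, gamma = gamma, delta = delta,
         n_experiments = nrow(study_sizes), study_sizes = study_sizes,
         seed = seed),
    class = "sim_config"
  )
}

#' Sample bait proteins with study-bias weighting
#'
#' Draws `n_bait` distinct proteins without replacement, with selection
#' probability proportional to `degree + delta` (sequential
#' draw-and-renormalise). With all degrees zero this is uniform sampling.
#'
#' @param degrees Current observed degrees, one per protein.
#' @param n_bait Number of baits to draw.
#' @param delta Baseline weight (default 0.01).
#' @param seed Optional integer seed.
#' @return Integer vector of distinct node indices, in draw order.
#' @export
sample_baits <- function(degrees, n_bait, delta = 0.01, seed = NULL) {
  n_bait <- check_count(n_bait, "n_bait", min = 1)
  if (n_bait > length(degrees)) {
    stop_baitbias("`n_bait` exceeds the number of proteins", "baitbias_invalid_parameter")
  }
  with_seed(seed, sample(seq_along(degrees), n_bait, prob = degrees + delta))
}

#' Sample prey proteins
#'
#' AP-MS preys are drawn uniformly without replacement; Y2H preys are actively
#' selected and therefore drawn with the same `degree + delta` bias as baits.
#'
#' @param degrees Current observed degrees, one per protein.
#' @param n_prey Number of preys to draw.
#' @param method `"AP-MS"` or `"Y2H"`.
#' @param delta Baseline weight used in Y2H mode.
#' @param seed Optional integer seed.
#' @return Integer vector of distinct node indices, in draw order.
#' @export
sample_preys <- function(degrees, n_prey, method = c("AP-MS", "Y2H"),
                         delta = 0.01, seed = NULL) {
  method <- match.arg(method)
  n_prey <- check_count(n_prey, "n_prey", min = 1)
  if (n_prey > length(degrees)) {
    stop_baitbias("`n_prey` exceeds the number of proteins", "baitbias_invalid_parameter")
  }
  with_seed(seed, {
    if (method == "AP-MS") {
      sample(seq_along(degrees), n_prey)
    } else {
      sample(seq_along(degrees), n_prey, prob = degrees + delta)
    }
  })
}

#' Create an empty pair-test counter
#'
#' Symmetric counters of how often each unordered pair was tested (`a`) and
#' how often it tested positive (`b`), stored over the upper triangle
#' (`u < v`).
#'
#' @param n Number of proteins.
#' @return An object of class `"test_counts"`.
#' @export
test_counts <- function(n) {
  n <- check_count(n, "n", min = 2)
  if (n > MAX_SIM_NODES) {
    stop_baitbias(
      sprintf("dense pair counters support up to %d nodes; use simulate_apms_degrees() for larger models",
              MAX_SIM_NODES),
      "baitbias_invalid_parameter"
    )
  }
  structure(
    list(n = n,
         a = matrix(0L, n, n),
         b = matrix(0L, n, n)),
    class = "test_counts"
  )
}

#' @export
print.test_counts <- function(x, ...) {
  tested <- sum(x$a > 0)
  cat(sprintf("Pair-test counters on %d proteins: %d pairs tested, %d tests, %d positives\n",
              x$n, tested, sum(x$a), sum(x$b)))
  invisible(x)
}

# Upper-triangle adjacency lookup matrix for a ground-truth graph.
gt_adjacency <- function(gt) {
  adj <- matrix(FALSE, gt$n, gt$n)
  if (nrow(gt$edges)) adj[gt$edges] <- TRUE
  adj
}

#' Run one simulated bait-prey experiment
#'
#' Tests every ordered pair `(u, v)` in `baits x preys` with `u != v`: a true
#' edge tests positive with probability `1 - fnr`, a non-edge with probability
#' `fpr`. Each test increments the symmetric tested counter of the unordered
#' pair, each positive the positive counter.
#'
#' @param ground_truth A `"ppi_graph"`.
#' @param baits,preys Integer vectors of distinct node indices.
#' @param fnr,fpr Error rates.
#' @param counts A `"test_counts"` object (state before the experiment).
#' @param seed Optional integer seed.
#' @return The updated `"test_counts"` object.
#' @export
run_experiment <- function(ground_truth, baits, preys, fnr, fpr, counts,
                           seed = NULL) {
  stopifnot(inherits(ground_truth, "ppi_graph"), inherits(counts, "test_counts"))
  if (anyDuplicated(baits) || anyDuplicated(preys)) {
    stop_baitbias("`baits` and `preys` must each be distinct", "baitbias_invalid_input")
  }
  fnr <- check_prob(fnr, "fnr"); fpr <- check_prob(fpr, "fpr")
  adj <- gt_adjacency(ground_truth)
  with_seed(seed, {
    upd <- experiment_tally(adj, counts$n, baits, preys, fnr, fpr)
    if (length(upd$ntest)) {
      counts$a[upd$idx] <- counts$a[upd$idx] + upd$ntest
      counts$b[upd$idx] <- counts$b[upd$idx] + upd$npos
    }
    counts
  })
}

# Bernoulli-test all ordered bait x prey pairs and tally per unordered pair.
# Returns idx (2-col canonical pair matrix), ntest, npos, and the total
# number of positive results.
experiment_tally <- function(adj, n, baits, preys, fnr, fpr) {
  u <- rep(baits, each = length(preys))
  v <- rep.int(preys, length(baits))
  keep <- u != v # self-pairs are skipped
  u <- u[keep]; v <- v[keep]
  if (!length(u)) {
    return(list(idx = matrix(integer(0), ncol = 2), ntest = integer(0),
                npos = integer(0), total_pos = 0L))
  }
  cu <- pmin(u, v); cv <- pmax(u, v)
  is_edge <- adj[cbind(cu, cv)]
  res <- stats::runif(length(u)) < ifelse(is_edge, 1 - fnr, fpr)
  code <- (cu - 1) * as.double(n) + cv
  tal <- rowsum(cbind(test = rep(1L, length(code)), pos = as.integer(res)), code)
  ucode <- as.numeric(rownames(tal))
  icu <- as.integer((ucode - 1) %/% n + 1)
  icv <- as.integer(ucode - (icu - 1) * as.double(n))
  list(idx = cbind(icu, icv), ntest = as.integer(tal[, "test"]),
       npos = as.integer(tal[, "pos"]), total_pos = sum(res))
}

#' Edges accepted by the gamma rule
#'
#' A pair is an edge of the observed network when it tested positive at least
#' once and its positive fraction strictly exceeds `gamma`.
#'
#' @param counts A `"test_counts"` object.
#' @param gamma Acceptance threshold in `[0, 1)`.
#' @return Two-column integer matrix of node-index pairs (`u < v`).
#' @export
current_edges <- function(counts, gamma) {
  stopifnot(inherits(counts, "test_counts"))
  sel <- which(counts$b > 0L & counts$b > gamma * counts$a, arr.ind = TRUE)
  dimnames(sel) <- NULL
  sel
}

#' Simulate an observed aggregated PPI network under study bias
#'
#' Runs `n_experiments` simulated studies against a fixed ground-truth
#' interactome. For each study, baits (and in Y2H mode preys) are sampled
#' preferentially towards the proteins with the highest degree in the
#' currently accepted observed network, every bait x prey pair is tested with
#' the configured error rates, and the observed edge set is re-derived from
#' the accumulated counters with the `gamma` acceptance rule.
#'
#' @param ground_truth A `"ppi_graph"`.
#' @param config A [sim_config()] object.
#' @return An object of class `"bias_sim"`: `network` (the observed
#'   `"ppi_graph"`), `counts` (data frame `u, v, a, b` over tested pairs),
#'   `log` (per-experiment baits, preys and positive count) and `config`.
#' @examples
#' gt <- generate_er(200, 400, seed = 1)
#' cfg <- sim_config(cbind(2, 20)[rep(1, 30), ], fpr = 0.01, seed = 2)
#' sim <- simulate_observed(gt, cfg)
#' sim$network
#' @export
simulate_observed <- function(ground_truth, config) {
  stopifnot(inherits(ground_truth, "ppi_graph"), inherits(config, "sim_config"))
  n <- ground_truth$n
  if (n > MAX_SIM_NODES) {
    stop_baitbias(
      sprintf("iterative simulator supports up to %d nodes; use simulate_apms_degrees() beyond that",
              MAX_SIM_NODES),
      "baitbias_invalid_parameter"
    )
  }
  if (any(config$study_sizes > n)) {
    stop_baitbias("study sizes exceed the number of proteins", "baitbias_invalid_parameter")
  }
  adj <- gt_adjacency(ground_truth)
  with_seed(config$seed, {
    a <- matrix(0L, n, n)
    b <- matrix(0L, n, n)
    status <- matrix(FALSE, n, n)
    deg <- integer(n)
    log <- vector("list", config$n_experiments)
    for (i in seq_len(config$n_experiments)) {
      nb <- config$study_sizes[i, 1]
      np <- config$study_sizes[i, 2]
      baits <- sample(n, nb, prob = deg + config$delta)
      preys <- if (config$method == "AP-MS") {
        sample(n, np)
      } else {
        sample(n, np, prob = deg + config$delta)
      }
      upd <- experiment_tally(adj, n, baits, preys, config$fnr, config$fpr)
      if (length(upd$ntest)) {
        a[upd$idx] <- a[upd$idx] + upd$ntest
        b[upd$idx] <- b[upd$idx] + upd$npos
        new_status <- b[upd$idx] > 0L & b[upd$idx] > config$gamma * a[upd$idx]
        dchange <- new_status - status[upd$idx]
        if (any(dchange != 0)) {
          deg <- deg + tabulate(upd$idx[rep(dchange > 0, 2)], nbins = n) -
            tabulate(upd$idx[rep(dchange < 0, 2)], nbins = n)
        }
        status[upd$idx] <- new_status
      }
      log[[i]] <- list(baits = baits, preys = preys, n_pos = upd$total_pos)
    }
    tested <- which(a > 0L, arr.ind = TRUE)
    dimnames(tested) <- NULL
    counts_df <- data.frame(u = tested[, 1], v = tested[, 2],
                            a = a[tested], b = b[tested])
    net_edges <- which(status, arr.ind = TRUE)
    dimnames(net_edges) <- NULL
    structure(
      list(network = ppi_graph(net_edges, n = n, nodes = ground_truth$nodes),
           counts = counts_df, log = log, config = config),
      class = "bias_sim"
    )
  })
}

#' @export
print.bias_sim <- function(x, ...) {
  cat(sprintf("Biased aggregated testing simulation (%s): %d experiments\n",
              x$config$method, x$config$n_experiments))
  cat(sprintf("  observed network: %d nodes, %d edges (fnr = %g, fpr = %g, gamma = %g)\n",
              x$network$n, nrow(x$network$edges),
              x$config$fnr, x$config$fpr, x$config$gamma))
  invisible(x)
}

#' Times each protein was selected as bait during a simulation
#'
#' @param sim A `"bias_sim"` result.
#' @return Integer vector of per-protein bait-selection counts.
#' @export
bait_selection_counts <- function(sim) {
  stopifnot(inherits(sim, "bias_sim"))
  tabulate(unlist(lapply(sim$log, `[[`, "baits")), nbins = sim$network$n)
}
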