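# Hyper-parameter grid harness: simulate ensembles of observed networks from
# power-law (BA) and binomial (ER) ground truths across a grid of
# (method, FNR, FPR, gamma) cells, compare each cell's ensembles to a
# reference degree distribution, and locate Delta SOD tipping points.

#' Grid configuration
#'
#' @param study_sizes Two-column matrix of per-study `(n_bait, n_prey)` sizes
#'   used for every simulated network.
#' @param n Number of nodes of the ground-truth networks.
#' @param m_er Number of edges of the ER ground truths (BA ground truths are
#'   matched via [ba_edges_for_target()]).
#' @param methods Character vector, subset of `c("AP-MS", "Y2H")`.
#' @param fnr_grid,fpr_grid,gamma_grid Numeric grids of error rates and
#'   acceptance thresholds.
#' @param n_networks_per_arm Simulated networks per ground-truth model per
#'   cell.
#' @param reference `"simulate"` (default: a held-out network simulated from
#'   a BA ground truth with error-free testing) or a numeric degree sequence.
#' @param delta Baseline sampling weight (default 0.01).
#' @param seed Optional integer seed for the whole grid run.
#' @return A list of class `"grid_config"`.
#' @export
grid_config <- function(study_sizes, n, m_er,
                        methods = "AP-MS",
                        fnr_grid = 0,
                        fpr_grid = c(0, 0.4 * 2^(-7:0)),
                        gamma_grid = 0,
                        n_networks_per_arm = 10,
                        reference = "simulate",
                        delta = 0.01,
                        seed = NULL) {
  stopifnot(all(methods %in% c("AP-MS", "Y2H")), length(methods) >= 1,
            length(fnr_grid) >= 1, length(fpr_grid) >= 1, length(gamma_grid) >= 1)
  n <- check_count(n, "n", min = 2)
  m_er <- check_count(m_er, "m_er", min = 1)
  n_networks_per_arm <- check_count(n_networks_per_arm, "n_networks_per_arm", min = 1)
  structure(
    list(study_sizes = as.matrix(study_sizes), n = n, m_er = m_er,
         methods = methods, fnr_grid = fnr_grid, fpr_grid = fpr_grid,
         gamma_grid = gamma_grid, n_networks_per_arm = n_networks_per_arm,
         reference = reference, delta = delta, seed = seed),
    class = "grid_config"
  )
}

#' Run the simulation grid
#'
#' For every `(method, fnr, fpr, gamma)` cell, simulates
#' `n_networks_per_arm` observed networks from fresh BA ground truths and as
#' many from fresh ER ground truths (matched edge counts), computes the EMD
#' of each network's degree distribution to the reference, and summarises the
#' cell with both Delta SOD variants and the K-NN power-law-origin
#' probability at `K = n_networks_per_arm`. Fully reproducible given the
#' config seed.
#'
#' @param config A [grid_config()] object.
#' @return A list of class `"grid_result"`: `cells` (one row per grid cell),
#'   `distances` (one row per simulated network), `reference` (the reference
#'   degree distribution) and `config`.
#' @export
run_grid <- function(config) {
  stopifnot(inherits(config, "grid_config"))
  m_ba <- ba_edges_for_target(config$n, config$m_er)
  with_seed(config$seed, {
    ref <- if (identical(config$reference, "simulate")) {
      gt <- generate_ba(config$n, m_ba)
      cfg <- sim_config(config$study_sizes, method = config$methods[1],
                        fnr = 0, fpr = 0, gamma = 0, delta = config$delta)
      degree_distribution(degree_sequence(simulate_observed(gt, cfg)$network))
    } else {
      degree_distribution(config$reference)
    }
    cells <- expand.grid(method = config$methods, fnr = config$fnr_grid,
                         fpr = config$fpr_grid, gamma = config$gamma_grid,
                         stringsAsFactors = FALSE)
    cell_rows <- vector("list", nrow(cells))
    dist_rows <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      sim_arm <- function(arm) {
        vapply(seq_len(config$n_networks_per_arm), function(j) {
          gt <- if (arm == "BA") generate_ba(config$n, m_ba)
                else generate_er(config$n, config$m_er)
          cfg <- sim_config(config$study_sizes, method = cell$method,
                            fnr = cell$fnr, fpr = cell$fpr,
                            gamma = cell$gamma, delta = config$delta)
          net <- simulate_observed(gt, cfg)$network
          emd(ref, degree_distribution(degree_sequence(net)))
        }, numeric(1))
      }
      d_ba <- sim_arm("BA")
      d_er <- sim_arm("ER")
      knn <- knn_origin(d_ba, d_er, K = config$n_networks_per_arm)
      cell_rows[[ci]] <- data.frame(
        cell, n_per_arm = config$n_networks_per_arm,
        delta_sod = tryCatch(delta_sod(d_ba, d_er),
                             baitbias_undefined_division = function(e) NA_real_),
        delta_sod_normalized = delta_sod(d_ba, d_er, normalized = TRUE),
        knn_prob_pl = knn$prob_pl
      )
      dist_rows[[ci]] <- data.frame(
        cell[rep(1, 2 * config$n_networks_per_arm), ],
        arm = rep(c("BA", "ER"), each = config$n_networks_per_arm),
        emd = c(d_ba, d_er), row.names = NULL
      )
    }
    structure(
      list(cells = do.call(rbind, cell_rows),
           distances = do.call(rbind, dist_rows),
           reference = ref, config = config),
      class = "grid_result"
    )
  })
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("Simulation grid: %d cells, %d networks per arm\n",
              nrow(x$cells), x$config$n_networks_per_arm))
  print(utils::head(x$cells, 12))
  invisible(x)
}

#' Tipping-point summary of a grid run
#'
#' For each `(method, gamma, fnr)` stratum with at least two FPR values,
#' locates the bracket of the first Delta SOD sign change along the FPR grid.
#'
#' @param result A `"grid_result"` from [run_grid()].
#' @param normalized Use the range-normalised Delta SOD? Default `FALSE`.
#' @return Data frame with one row per stratum: `method`, `gamma`, `fnr`,
#'   `found`, `fpr_below`, `fpr_above`.
#' @export
summarize_tipping <- function(result, normalized = FALSE) {
  stopifnot(inherits(result, "grid_result"))
  cells <- result$cells
  col <- if (normalized) "delta_sod_normalized" else "delta_sod"
  strata <- unique(cells[, c("method", "gamma", "fnr")])
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    sub <- cells[cells$method == s$method & cells$gamma == s$gamma &
                   cells$fnr == s$fnr, ]
    row <- data.frame(s, found = FALSE, fpr_below = NA_real_,
                      fpr_above = NA_real_, row.names = NULL)
    if (nrow(sub) >= 2) {
      tp <- tipping_point(sub[[col]], fpr = sub$fpr)
      row$found <- tp$found
      row$fpr_below <- tp$fpr_below
      row$fpr_above <- tp$fpr_above
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}
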