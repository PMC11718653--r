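# Independent oracles used by the tests. These deliberately re-derive
# quantities with different algorithms than the package (brute-force
# summation, dense grid search, greedy transport) so agreement is evidence,
# not tautology.

# Hurwitz zeta by plain partial summation with an integral tail bound;
# slow but transparent.
brute_hzeta <- function(s, q, terms = 2e6) {
  k <- seq(q, q + terms - 1)
  sum(k^(-s)) + (q + terms)^(1 - s) / (s - 1) + 0.5 * (q + terms)^(-s)
}

# Dense grid-search MLE for the discrete power-law exponent at fixed kmin.
grid_mle_alpha <- function(tail, kmin, grid = seq(1.05, 6, by = 1e-3)) {
  S <- sum(log(tail))
  ll <- -length(tail) * log(vapply(grid, brute_hzeta, numeric(1), q = kmin,
                                   terms = 2e4)) - grid * S
  grid[which.max(ll)]
}

# Greedy transport (classic earth mover's algorithm) between two PMFs on the
# integers; independent of the CDF-difference formula used by the package.
greedy_emd <- function(p, q) {
  sup_p <- as.numeric(names(p)); sup_q <- as.numeric(names(q))
  pi <- 1; qi <- 1
  p <- as.numeric(p); q <- as.numeric(q)
  cost <- 0
  while (pi <= length(p) && qi <= length(q)) {
    m <- min(p[pi], q[qi])
    cost <- cost + m * abs(sup_p[pi] - sup_q[qi])
    p[pi] <- p[pi] - m
    q[qi] <- q[qi] - m
    if (p[pi] <= 1e-15) pi <- pi + 1
    if (qi <= length(q) && q[qi] <= 1e-15) qi <- qi + 1
  }
  cost
}

# Long-tailed asymmetric study-size matrix used by simulator tests.
make_study_sizes <- function(n_studies, seed, prey_range = c(5, 100)) {
  set.seed(seed)
  np <- round(exp(runif(n_studies, log(prey_range[1]), log(prey_range[2]))))
  nb <- pmax(1, round(rbeta(n_studies, 0.7, 3) * np))
  cbind(nb, np)
}

# Minimal PSI-MITAB 2.7-style fixture writer: 15+ tab-separated columns with
# experimental roles in columns 19/20.
write_mitab_fixture <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    f <- rep("-", 20)
    f[1] <- paste0("uniprotkb:", r$a)
    f[2] <- paste0("uniprotkb:", r$b)
    f[7] <- 'psi-mi:"MI:0004"(affinity chromatography technology)'
    f[9] <- paste0("pubmed:", r$study)
    f[17] <- 'psi-mi:"MI:0499"(unspecified role)'
    f[18] <- 'psi-mi:"MI:0499"(unspecified role)'
    f[19] <- r$role_a %||% 'psi-mi:"MI:0496"(bait)'
    f[20] <- r$role_b %||% 'psi-mi:"MI:0498"(prey)'
    paste(f, collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x
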