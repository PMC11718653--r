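test_that("degree-weighted bait sampling follows the delta-smoothed weights", {
  # all degrees zero: uniform
  picks <- vapply(1:4000, function(s) sample_baits(c(0, 0, 0, 0), 1, seed = s),
                  integer(1))
  expect_gt(min(table(factor(picks, levels = 1:4))), 4000 / 4 * 0.8)
  # degrees (100, 0, 0): node 1 weight 100.01 of 100.03
  picks <- vapply(1:20000, function(s) sample_baits(c(100, 0, 0), 1, seed = s),
                  integer(1))
  p1 <- 100.01 / 100.03
  expect_lt(abs(mean(picks == 1) - p1), 4 * sqrt(p1 * (1 - p1) / 20000) + 1e-4)
  # full draw is a permutation
  expect_setequal(sample_baits(c(5, 0, 2), 3, seed = 1), 1:3)
  expect_error(sample_baits(c(0, 0), 3), class = "baitbias_invalid_parameter")
})

test_that("prey sampling is uniform for AP-MS and degree-biased for Y2H", {
  deg <- c(10, 0)
  y2h <- vapply(1:20000, function(s) sample_preys(deg, 1, "Y2H", seed = s), integer(1))
  p1 <- 10.01 / 10.02
  expect_lt(abs(mean(y2h == 1) - p1), 4 * sqrt(p1 * (1 - p1) / 20000) + 1e-4)
  apms <- vapply(1:4000, function(s) sample_preys(c(50, 0), 1, "AP-MS", seed = s),
                 integer(1))
  expect_lt(abs(mean(apms == 1) - 0.5), 0.03)
})

test_that("single experiments update the symmetric counters correctly", {
  gt <- ppi_graph(rbind(c(1, 2)), n = 4)
  cnt <- test_counts(4)
  # error-free: true edge tested once -> a = b = 1; non-edge -> a = 1, b = 0
  cnt <- run_experiment(gt, baits = 1, preys = c(2, 3), fnr = 0, fpr = 0,
                        counts = cnt, seed = 1)
  expect_equal(cnt$a[1, 2], 1L); expect_equal(cnt$b[1, 2], 1L)
  expect_equal(cnt$a[1, 3], 1L); expect_equal(cnt$b[1, 3], 0L)
  # fpr = 1: non-edge tested 5 times -> a = b = 5
  cnt2 <- test_counts(4)
  for (i in 1:5) {
    cnt2 <- run_experiment(gt, baits = 3, preys = 4, fnr = 0, fpr = 1,
                           counts = cnt2, seed = i)
  }
  expect_equal(cnt2$a[3, 4], 5L); expect_equal(cnt2$b[3, 4], 5L)
  # self-pairs skipped; both orientations within one experiment both tallied
  cnt3 <- run_experiment(gt, baits = c(1, 2), preys = c(1, 2), fnr = 0, fpr = 0,
                         counts = test_counts(4), seed = 2)
  expect_equal(cnt3$a[1, 2], 2L) # (1,2) and (2,1), no (1,1)/(2,2)
  expect_equal(cnt3$b[1, 2], 2L)
  expect_equal(sum(cnt3$a), 2L)
})

test_that("the gamma acceptance rule uses strict inequality", {
  cnt <- test_counts(3)
  cnt$a[1, 2] <- 4L; cnt$b[1, 2] <- 2L
  cnt$a[1, 3] <- 4L; cnt$b[1, 3] <- 3L
  cnt$a[2, 3] <- 7L; cnt$b[2, 3] <- 1L
  e05 <- current_edges(cnt, 0.5)
  expect_equal(e05, rbind(c(1L, 3L))) # 2/4 excluded at gamma = 0.5, 3/4 included
  e0 <- current_edges(cnt, 0)
  expect_equal(nrow(e0), 3L) # any positive detection suffices at gamma = 0
})

test_that("error-free simulation recovers exactly the tested true edges", {
  gt <- generate_er(150, 300, seed = 3)
  cfg <- sim_config(make_study_sizes(40, seed = 4, prey_range = c(5, 40)),
                    fnr = 0, fpr = 0, gamma = 0, seed = 5)
  sim <- simulate_observed(gt, cfg)
  truth <- gt_edge_keys <- paste(gt$edges[, 1], gt$edges[, 2])
  obs <- paste(sim$network$edges[, 1], sim$network$edges[, 2])
  expect_true(all(obs %in% truth))
  tested_true <- sim$counts[paste(sim$counts$u, sim$counts$v) %in% truth, ]
  expect_setequal(obs, paste(tested_true$u, tested_true$v))
  # and with an empty ground truth nothing is ever observed
  empty <- ppi_graph(matrix(integer(0), ncol = 2), n = 100)
  cfg2 <- sim_config(cbind(2, 10)[rep(1, 20), ], fnr = 0, fpr = 0, seed = 6)
  expect_equal(edge_count(simulate_observed(empty, cfg2)$network), 0L)
})

test_that("counters dominate positives and gamma filtering is monotone", {
  gt <- generate_er(100, 300, seed = 7)
  cfg <- sim_config(make_study_sizes(30, seed = 8, prey_range = c(5, 30)),
                    fnr = 0.2, fpr = 0.1, gamma = 0, seed = 9)
  sim <- simulate_observed(gt, cfg)
  expect_true(all(sim$counts$b <= sim$counts$a))
  expect_true(all(sim$counts$a >= 1))
  # rebuild counters and check E'(0.5) subset of E'(0)
  cnt <- test_counts(100)
  idx <- cbind(sim$counts$u, sim$counts$v)
  cnt$a[idx] <- sim$counts$a; cnt$b[idx] <- sim$counts$b
  e0 <- paste(current_edges(cnt, 0)[, 1], current_edges(cnt, 0)[, 2])
  e5 <- paste(current_edges(cnt, 0.5)[, 1], current_edges(cnt, 0.5)[, 2])
  expect_true(all(e5 %in% e0))
  # the simulated network satisfies its own gamma rule
  keep <- sim$counts$b > 0 & sim$counts$b / sim$counts$a > cfg$gamma
  expect_setequal(paste(sim$network$edges[, 1], sim$network$edges[, 2]),
                  paste(sim$counts$u[keep], sim$counts$v[keep]))
})

test_that("false positives on an empty interactome match the analytic count", {
  empty <- ppi_graph(matrix(integer(0), ncol = 2), n = 500)
  devs <- vapply(1:10, function(s) {
    cfg <- sim_config(cbind(2, 50)[rep(1, 200), ], fnr = 0, fpr = 0.05,
                      gamma = 0, seed = 50 + s)
    sim <- simulate_observed(empty, cfg)
    expected <- sum(1 - (1 - 0.05)^sim$counts$a)
    vr <- sum((1 - (1 - 0.05)^sim$counts$a) * (1 - 0.05)^sim$counts$a)
    (edge_count(sim$network) - expected) / sqrt(vr)
  }, numeric(1))
  expect_lt(max(abs(devs)), 4)
  expect_lt(abs(mean(devs)), 1.5)
})

test_that("study-bias feedback couples degree and bait selection", {
  empty <- ppi_graph(matrix(integer(0), ncol = 2), n = 300)
  rhos <- vapply(1:8, function(s) {
    cfg <- sim_config(cbind(3, 30)[rep(1, 120), ], fnr = 0, fpr = 0.1,
                      gamma = 0, seed = 80 + s)
    sim <- simulate_observed(empty, cfg)
    cor(degree_sequence(sim$network), bait_selection_counts(sim),
        method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0))
})

test_that("simulation is bit-reproducible given the config seed", {
  gt <- generate_er(80, 150, seed = 10)
  cfg <- sim_config(cbind(2, 15)[rep(1, 25), ], fnr = 0.1, fpr = 0.05,
                    gamma = 0.5, seed = 11)
  s1 <- simulate_observed(gt, cfg)
  s2 <- simulate_observed(gt, cfg)
  expect_identical(s1$network$edges, s2$network$edges)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$log, s2$log)
})
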