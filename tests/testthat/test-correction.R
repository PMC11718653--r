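test_that("size balance is the min/max ratio and symmetric", {
  expect_equal(size_balance(3, 12), 0.25)
  expect_equal(size_balance(12, 3), 0.25)
  expect_equal(size_balance(7, 7), 1)
  expect_error(size_balance(0, 5), class = "baitbias_invalid_parameter")
})

test_that("role-corrected degrees follow the asymmetry rule exactly", {
  st <- data.frame(bait = c("A", "A", "B", "B"), prey = c("C", "D", "C", "A"))
  cd <- corrected_degrees(st) # 2 baits < 3 preys -> prey-degrees
  expect_equal(cd, c(A = 1L, B = 0L, C = 2L, D = 1L))
  ud <- study_degrees(st)
  expect_equal(ud, c(A = 3L, B = 2L, C = 2L, D = 1L))
  expect_true(all(cd <= ud[names(cd)]))
  expect_equal(sum(cd), 4L) # one endpoint per record
  # more baits than preys -> bait-degrees
  st2 <- data.frame(bait = c("A", "B", "C"), prey = c("D", "D", "D"))
  expect_equal(corrected_degrees(st2), c(A = 1L, B = 1L, C = 1L, D = 0L))
  # tie n_bait = n_prey -> prey-degree branch
  st3 <- data.frame(bait = c("A", "B"), prey = c("B", "A"))
  expect_equal(corrected_degrees(st3), c(A = 1L, B = 1L))
})

test_that("degenerate studies are cleaned or rejected", {
  expect_error(corrected_degrees(data.frame(bait = character(0),
                                            prey = character(0))),
               class = "baitbias_invalid_input")
  expect_warning(
    cd <- corrected_degrees(data.frame(bait = c("A", "A"), prey = c("A", "B"))),
    "self-interaction"
  )
  expect_equal(cd, c(A = 0L, B = 1L))
  # duplicates collapse
  st <- data.frame(bait = c("A", "A", "A"), prey = c("B", "B", "C"))
  expect_equal(sum(corrected_degrees(st)), 2L)
})

test_that("corrected degrees never exceed aggregated degrees", {
  set.seed(61)
  for (i in 1:20) {
    k <- sample(5:30, 1)
    st <- data.frame(bait = sample(LETTERS[1:8], k, replace = TRUE),
                     prey = sample(LETTERS[1:8], k, replace = TRUE))
    st <- st[st$bait != st$prey, , drop = FALSE]
    if (nrow(st) == 0) next
    cd <- corrected_degrees(st)
    ud <- study_degrees(st)
    expect_true(all(cd <= ud[names(cd)]))
    dedup <- unique(st)
    expect_equal(sum(cd), nrow(dedup))
  }
})

test_that("bait-usage normalisation and hub extraction behave as documented", {
  nd <- normalized_degrees(c(P1 = 40, P2 = 5, P3 = 10), c(P1 = 10, P2 = 0, P3 = 2))
  expect_equal(unname(nd[1:3]), c(4, 5, 5))
  expect_equal(attr(nd, "never_baited"), "P2")
  # equal degree: less-baited protein ranks higher
  nd2 <- normalized_degrees(c(X = 12, Y = 12), c(X = 6, Y = 2))
  expect_equal(top_hubs(nd2, 1), "Y")
  expect_equal(top_hubs(c(a = 3, b = 1, c = 2), 2), c("a", "c"))
  expect_equal(top_hubs(c(b = 1, a = 1, c = 1), 2), c("a", "b")) # ties: lexicographic
  expect_equal(top_hubs(c(a = 3, b = 1, c = 2), 3), c("a", "c", "b"))
  expect_error(top_hubs(c(a = 1), 2), class = "baitbias_invalid_parameter")
})

test_that("asymmetric bait-driven designs lose power-law plausibility after correction", {
  # Asymmetric studies (size balance 0.1) on a heavy-tailed interactome with
  # degree-biased bait selection: the uncorrected degree tail is carried by
  # the bait hubs, while prey-only degrees are Poisson-like. Correcting to
  # the minority role therefore demotes the power-law verdict.
  n <- 2000
  gt <- generate_ba(n, 3, seed = 1)
  dg <- degree_sequence(gt)
  adj <- matrix(FALSE, n, n); adj[gt$edges] <- TRUE
  plaus <- function(deg) {
    tryCatch(is_plausible(bootstrap_gof(fit_power_law(deg), n_boot = 30)),
             baitbias_fit_error = function(e) FALSE)
  }
  set.seed(101)
  nb <- 150; np <- 1500; fpr <- 0.01
  tally <- replicate(20, {
    baits <- sample(n, nb, prob = (dg + 0.5)^1.5)
    preys <- sample(n, np)
    u <- rep(baits, each = np); v <- rep.int(preys, nb)
    keep <- u != v; u <- u[keep]; v <- v[keep]
    is_edge <- adj[cbind(pmin(u, v), pmax(u, v))]
    pos <- runif(length(u)) < ifelse(is_edge, 1, fpr)
    st <- data.frame(bait = sprintf("P%04d", u[pos]),
                     prey = sprintf("P%04d", v[pos]))
    c(uncorrected = plaus(study_degrees(st)),
      corrected = plaus(corrected_degrees(st)))
  })
  expect_gt(sum(tally["uncorrected", ]), sum(tally["corrected", ]))
})
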