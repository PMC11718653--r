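test_that("MITAB reader extracts identifiers, roles, studies and methods", {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_mitab_fixture(path, list(
    list(a = "P1", b = "P2", study = "1001"),
    list(a = "P3", b = "P1", study = "1001"),
    list(a = "P4", b = "P5", study = "1002",
         role_a = 'psi-mi:"MI:0498"(prey)', role_b = 'psi-mi:"MI:0496"(bait)')
  ))
  cat <- read_mitab_lite(path)
  expect_s3_class(cat, "study_catalog")
  expect_equal(nrow(cat), 3)
  # role_a = bait by default; third row has roles swapped
  expect_equal(cat$bait, c("P1", "P3", "P5"))
  expect_equal(cat$prey, c("P2", "P1", "P4"))
  expect_equal(cat$study_id, c("1001", "1001", "1002"))
  expect_match(cat$method[1], "affinity chromatography")
})

test_that("MITAB reader drops self-interactions and flags missing roles", {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  rows <- list(
    list(a = "P1", b = "P1", study = "2001"), # self-interaction
    list(a = "P2", b = "P3", study = "2001",
         role_a = "-", role_b = "-") # no role info
  )
  writeLines(c(
    readLines(write_mitab_fixture(path, rows)),
    "malformed line with too few columns"
  ), path)
  expect_warning(cat <- read_mitab_lite(path), "unspecified")
  expect_equal(nrow(cat), 1)
  expect_equal(attr(cat, "n_self"), 1L)
  expect_equal(attr(cat, "n_skipped"), 1L)
  expect_equal(cat$role_annotated, "unspecified")
  expect_error(suppressWarnings(read_mitab_lite(tempfile())), class = "baitbias_io_error")
})

test_that("study TSV round-trips and the whitelist filters records", {
  df <- data.frame(study_id = c("s1", "s1", "s2"),
                   bait = c("A", "B", "A"), prey = c("B", "C", "C"),
                   method = "apms")
  cat <- study_catalog(df)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_study_tsv(cat, path)
  back <- read_study_tsv(path)
  expect_equal(as.data.frame(back)[1:4], as.data.frame(cat)[1:4])
  filtered <- study_catalog(df, universe = c("A", "B"))
  expect_equal(nrow(filtered), 1)
})

test_that("aggregation unions unique interactions and counts bait usage per study", {
  df <- data.frame(
    study_id = c("s1", "s1", "s2", "s2", "s3"),
    bait = c("A", "A", "B", "A", "A"),
    prey = c("B", "C", "A", "C", "B"))
  agg <- aggregate_studies(study_catalog(df))
  expect_equal(edge_count(agg$graph), 2) # {A,B}, {A,C}
  prov <- agg$provenance
  ab <- prov[prov$u == "A" & prov$v == "B", ]
  expect_setequal(ab$studies[[1]], c("s1", "s2", "s3"))
  expect_equal(agg$bait_usage[["A"]], 3L) # baited in s1, s2, s3
  expect_equal(agg$bait_usage[["B"]], 1L)
  expect_equal(agg$bait_usage[["C"]], 0L)
  # idempotence: re-aggregating the aggregate's edge records changes nothing
  redf <- data.frame(study_id = "all", bait = prov$u, prey = prov$v, method = "x")
  agg2 <- aggregate_studies(study_catalog(redf))
  expect_equal(edge_count(agg2$graph), edge_count(agg$graph))
  # union property against per-study edge sets
  per_study <- unique(unlist(lapply(split(df, df$study_id), function(s) {
    paste(pmin(s$bait, s$prey), pmax(s$bait, s$prey))
  })))
  expect_setequal(paste(prov$u, prov$v), per_study)
})

test_that("synthetic catalogs emulate the target descriptive statistics", {
  n <- 800
  empty <- ppi_graph(matrix(integer(0), ncol = 2), n = n)
  # error-free testing of an empty interactome yields no records
  cat0 <- synthetic_catalog(n, 50, empty, fpr = 0, fnr = 0, seed = 1)
  expect_equal(nrow(cat0), 0)
  cat <- synthetic_catalog(n, 400, empty, fpr = 0.05, seed = 2)
  expect_gt(nrow(cat), 0)
  sizes <- attr(cat, "study_sizes")
  expect_true(all(sizes >= 1))
  expect_true(all(sizes[, 1] <= sizes[, 2])) # asymmetric towards preys
  # study-size distribution is long-tailed: median well below the maximum
  expect_lt(median(sizes[, 2]), max(sizes[, 2]) / 2)
  # zero-interest proteins can never be baited; zero fraction is calibrated
  agg <- aggregate_studies(cat)
  interest <- attr(cat, "interest")
  baited <- names(agg$bait_usage)[agg$bait_usage > 0]
  expect_true(all(interest[baited] > 0))
  expect_equal(mean(interest == 0), 0.24, tolerance = 0.06)
})

test_that("realised bait usage of a synthetic catalog is power-law plausible", {
  n <- 2000
  empty <- ppi_graph(matrix(integer(0), ncol = 2), n = n)
  hits <- vapply(1:5, function(s) {
    cat <- synthetic_catalog(n, 1200, empty, fpr = 0.03, seed = 90 + s)
    agg <- aggregate_studies(cat)
    usage <- rep(0L, n)
    usage[match(names(agg$bait_usage), sprintf("P%05d", 1:n))] <- agg$bait_usage
    is_plausible(bootstrap_gof(fit_power_law(usage), n_boot = 50,
                               seed = 190 + s))
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("random merging of non-power-law studies is reproducible and bounded", {
  n <- 600
  gt <- generate_er(n, 1500, seed = 3)
  cat <- synthetic_catalog(n, 120, gt, fpr = 0.01, fnr = 0.1, seed = 4,
                           size_range = c(10, 60))
  expect_error(merge_random_subsets(cat, subset_size = 10000, reps = 2),
               class = "baitbias_invalid_parameter")
  expect_error(merge_random_subsets(cat, subset_size = 5, reps = 0),
               class = "baitbias_invalid_parameter")
  m1 <- merge_random_subsets(cat, subset_size = 20, reps = 5, n_boot = 30, seed = 5)
  m2 <- merge_random_subsets(cat, subset_size = 20, reps = 5, n_boot = 30, seed = 5)
  expect_equal(m1$fraction_plausible, m2$fraction_plausible)
  expect_gte(m1$fraction_plausible, 0)
  expect_lte(m1$fraction_plausible, 1)
  # merging everything each rep is degenerate: identical networks every rep
  full <- merge_random_subsets(cat, subset_size = length(unique(cat$study_id)),
                               reps = 2, n_boot = 20, seed = 6)
  ps <- vapply(full$results, function(r) r$p_value %||% NA_real_, numeric(1))
  expect_equal(length(unique(round(ps, 10))) <= 2, TRUE)
})

test_that("aggregating more studies raises the chance of a power-law verdict", {
  n <- 1200
  empty <- ppi_graph(matrix(integer(0), ncol = 2), n = n)
  cat <- synthetic_catalog(n, 200, empty, fpr = 0.04, seed = 7,
                           size_range = c(10, 80))
  fracs <- vapply(c(20, 80, 160), function(k) {
    merge_random_subsets(cat, subset_size = k, reps = 10, n_boot = 30,
                         seed = 8)$fraction_plausible
  }, numeric(1))
  expect_gte(fracs[3], fracs[1] - 0.1) # directional, noise-tolerant
})
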