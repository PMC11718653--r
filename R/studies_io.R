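# Study catalogs: reading PSI-MITAB and role-annotated TSV files, aggregating
# single-study networks into one observed network, random-subset merging
# experiments, and a fully synthetic catalog generator that emulates the
# descriptive statistics of large real catalogs (long-tailed study sizes,
# asymmetric designs, power-law bait usage with a never-tested fraction).

#' Construct a study catalog
#'
#' A catalog is a data frame of role-annotated interaction records with
#' columns `study_id`, `bait`, `prey`, `method`, optionally restricted to a
#' protein universe (records with proteins outside the universe are dropped).
#'
#' @param records Data frame with columns `study_id`, `bait`, `prey` and
#'   optionally `method`.
#' @param universe Optional character vector of allowed protein identifiers.
#' @return Object of class `c("study_catalog", "data.frame")`.
#' @export
study_catalog <- function(records, universe = NULL) {
  need <- c("study_id", "bait", "prey")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop_baitbias("`records` must have columns study_id, bait, prey",
                  "baitbias_invalid_input")
  }
  if (is.null(records$method)) records$method <- "unspecified"
  records <- records[, c("study_id", "bait", "prey", "method")]
  records[] <- lapply(records, as.character)
  if (!is.null(universe)) {
    keep <- records$bait %in% universe & records$prey %in% universe
    records <- records[keep, , drop = FALSE]
  }
  attr(records, "universe") <- universe
  class(records) <- c("study_catalog", "data.frame")
  records
}

#' @export
print.study_catalog <- function(x, ...) {
  cat(sprintf("Study catalog: %d interaction records, %d studies, %d proteins\n",
              nrow(x), length(unique(x$study_id)),
              length(unique(c(x$bait, x$prey)))))
  invisible(x)
}

#' Read a PSI-MITAB 2.5/2.7 file into a study catalog
#'
#' Extracts interactor primary identifiers (columns 1-2), the
#' interaction-detection-method label (column 7) and the publication
#' identifier (column 9, used as study id). Experimental roles (bait,
#' MI:0496; prey, MI:0498) are searched in columns 17-20 (biological and
#' experimental role columns differ between MITAB dialects); records without
#' recognisable roles are kept with the A interactor as bait and flagged
#' `"unspecified"` in the returned `role_annotated` column. Self-interactions
#' and malformed lines are dropped and counted.
#'
#' @param path Path to a tab-separated MITAB file (with or without a
#'   `#`-prefixed header line).
#' @param universe Optional protein identifier whitelist.
#' @return A `"study_catalog"`; attributes `n_skipped` (malformed lines) and
#'   `n_self` (self-interactions dropped) report what was filtered.
#' @export
read_mitab_lite <- function(path, universe = NULL) {
  if (!file.exists(path)) {
    stop_baitbias(sprintf("cannot read '%s'", path), "baitbias_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 15
  n_skipped <- sum(!ok)
  fields <- fields[ok]
  if (!length(fields)) {
    stop_baitbias("no parseable MITAB lines", "baitbias_invalid_input")
  }
  strip_id <- function(x) sub("^[^:]*:", "", sub("\\|.*$", "", x))
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else "-",
                                character(1))
  id_a <- strip_id(get_col(1))
  id_b <- strip_id(get_col(2))
  method <- gsub("^.*\\((.*)\\).*$", "\\1", get_col(7))
  study <- strip_id(get_col(9))
  # experimental roles: scan columns 17-20 for bait/prey CV terms
  role_of <- function(x) {
    ifelse(grepl("MI:0496|\\(bait\\)", x), "bait",
           ifelse(grepl("MI:0498|\\(prey\\)", x), "prey", NA_character_))
  }
  role_a <- rep(NA_character_, length(fields))
  role_b <- rep(NA_character_, length(fields))
  for (col in c(17L, 19L)) {
    ra <- role_of(get_col(col)); rb <- role_of(get_col(col + 1L))
    fill <- is.na(role_a) & is.na(role_b) & !(is.na(ra) & is.na(rb))
    role_a[fill] <- ra[fill]; role_b[fill] <- rb[fill]
  }
  annotated <- !is.na(role_a) | !is.na(role_b)
  if (any(!annotated)) {
    warning(sprintf("%d record(s) lack experimental role annotations; kept with role 'unspecified'",
                    sum(!annotated)))
  }
  bait <- ifelse(!is.na(role_b) & role_b == "bait", id_b, id_a)
  prey <- ifelse(!is.na(role_b) & role_b == "bait", id_a, id_b)
  self <- bait == prey
  keep <- !self
  n_self <- sum(self)
  out <- study_catalog(
    data.frame(study_id = study[keep], bait = bait[keep], prey = prey[keep],
               method = method[keep], stringsAsFactors = FALSE),
    universe = universe
  )
  out$role_annotated <- ifelse(annotated[keep], "annotated", "unspecified")
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_self") <- n_self
  out
}

#' Write / read a role-annotated study TSV
#'
#' Four-column TSV `(study_id, bait, prey, method)` with header.
#'
#' @param catalog A `"study_catalog"`.
#' @param path File path.
#' @return `write_study_tsv` returns `path` invisibly; `read_study_tsv`
#'   returns a `"study_catalog"`.
#' @export
write_study_tsv <- function(catalog, path) {
  stopifnot(inherits(catalog, "study_catalog"))
  utils::write.table(catalog[, c("study_id", "bait", "prey", "method")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_tsv
#' @param universe Optional protein identifier whitelist.
#' @export
read_study_tsv <- function(path, universe = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  study_catalog(df, universe = universe)
}

#' Aggregate a study catalog into one observed network
#'
#' Unions the unique undirected interactions of all studies; records the
#' supporting studies of every edge and counts, for each protein, the number
#' of studies in which it appears at least once as bait.
#'
#' @param catalog A `"study_catalog"`.
#' @return Object of class `"aggregated_network"`: `graph` (a `"ppi_graph"`
#'   over all catalog proteins), `provenance` (data frame `u`, `v`,
#'   `n_studies`, `studies`), and `bait_usage` (named integer vector).
#' @export
aggregate_studies <- function(catalog) {
  stopifnot(inherits(catalog, "study_catalog"))
  if (nrow(catalog) == 0) {
    stop_baitbias("catalog is empty", "baitbias_invalid_input")
  }
  keep <- catalog$bait != catalog$prey
  cat2 <- catalog[keep, , drop = FALSE]
  proteins <- sort(unique(c(catalog$bait, catalog$prey)))
  u <- pmin(cat2$bait, cat2$prey)
  v <- pmax(cat2$bait, cat2$prey)
  key <- paste(u, v, sep = "\r")
  by_edge <- split(cat2$study_id, key)
  studies <- lapply(by_edge, unique)
  uv <- do.call(rbind, strsplit(names(by_edge), "\r", fixed = TRUE))
  prov <- data.frame(u = uv[, 1], v = uv[, 2],
                     n_studies = vapply(studies, length, integer(1)),
                     stringsAsFactors = FALSE)
  prov$studies <- unname(studies)
  usage_pairs <- unique(cat2[, c("study_id", "bait")])
  usage <- table(factor(usage_pairs$bait, levels = proteins))
  graph <- ppi_graph(cbind(prov$u, prov$v), nodes = proteins)
  structure(
    list(graph = graph, provenance = prov,
         bait_usage = stats::setNames(as.integer(usage), proteins)),
    class = "aggregated_network"
  )
}

#' @export
print.aggregated_network <- function(x, ...) {
  cat(sprintf("Aggregated PPI network: %d proteins, %d edges, %d baited proteins\n",
              x$graph$n, nrow(x$graph$edges), sum(x$bait_usage > 0)))
  invisible(x)
}

#' Power-law testing of randomly merged study subsets
#'
#' Repeatedly samples `subset_size` studies without replacement, aggregates
#' them, and tests the power-law plausibility of the aggregated degree
#' sequence. Used to study whether the aggregation process itself favours
#' the emergence of the power-law property.
#'
#' @param catalog A `"study_catalog"`.
#' @param subset_size Number of studies per merge (at most the catalog size).
#' @param reps Number of random merges.
#' @param n_boot Bootstrap replicates per goodness-of-fit test (default 100).
#' @param seed Optional integer seed.
#' @return A list of class `"merge_experiment"`: `results` (per-rep
#'   `"plgof"` objects, `NULL` where fitting failed), `fraction_plausible`,
#'   `n_failed_fits`.
#' @export
merge_random_subsets <- function(catalog, subset_size, reps, n_boot = 100,
                                 seed = NULL) {
  stopifnot(inherits(catalog, "study_catalog"))
  subset_size <- check_count(subset_size, "subset_size", min = 1)
  reps <- check_count(reps, "reps", min = 1)
  ids <- unique(catalog$study_id)
  if (subset_size > length(ids)) {
    stop_baitbias("`subset_size` exceeds the number of studies",
                  "baitbias_invalid_parameter")
  }
  with_seed(seed, {
    results <- vector("list", reps)
    plausible <- logical(reps)
    failed <- 0L
    for (r in seq_len(reps)) {
      chosen <- sample(ids, subset_size)
      sub <- catalog[catalog$study_id %in% chosen, , drop = FALSE]
      class(sub) <- class(catalog)
      deg <- degree_sequence(aggregate_studies(sub)$graph)
      gof <- tryCatch({
        bootstrap_gof(fit_power_law(deg), n_boot = n_boot)
      }, baitbias_fit_error = function(e) NULL)
      results[[r]] <- gof
      if (is.null(gof)) failed <- failed + 1L else plausible[r] <- is_plausible(gof)
    }
    structure(
      list(results = results,
           fraction_plausible = mean(plausible),
           n_failed_fits = failed),
      class = "merge_experiment"
    )
  })
}

#' @export
print.merge_experiment <- function(x, ...) {
  cat(sprintf("Random-merge experiment: %d merges, %.0f%% power-law plausible (%d failed fits)\n",
              length(x$results), 100 * x$fraction_plausible, x$n_failed_fits))
  invisible(x)
}

#' Generate a synthetic study catalog
#'
#' Builds a download-free stand-in for a real interaction catalog. Each
#' protein gets a global research-interest weight drawn from the power-law
#' usage family (zero with probability `zero_frac`, otherwise a discrete
#' power law with exponent `bias_alpha`); per study, a long-tailed prey count
#' is drawn log-uniformly from `size_range`, an asymmetric bait count as a
#' Beta-distributed fraction of it, baits are sampled proportionally to
#' interest weight, preys per the test method, and interaction records are
#' emitted by testing every bait x prey pair against the ground truth with
#' the given error rates. Only positive tests become records, so studies can
#' be empty (they are omitted).
#'
#' @param n_proteins Number of proteins in the universe (`P1 ... Pn`).
#' @param n_studies Number of studies to simulate.
#' @param ground_truth A `"ppi_graph"` on `n_proteins` nodes (e.g. an empty
#'   graph or [generate_ba()] output).
#' @param bias_alpha Power-law exponent of the interest weights (default 3.13).
#' @param zero_frac Fraction of proteins never eligible as bait (default 0.24).
#' @param size_range Range of prey counts per study, sampled log-uniformly
#'   (default `c(5, 200)`), giving many small and few large studies.
#' @param balance_shape Beta shape parameters of the bait/prey balance
#'   (default `c(0.7, 3)`: mostly asymmetric designs).
#' @param fpr,fnr Per-test error rates.
#' @param method `"AP-MS"` (uniform preys) or `"Y2H"` (interest-biased preys).
#' @param seed Optional integer seed.
#' @return A `"study_catalog"` with attributes `interest` (the weight vector)
#'   and `study_sizes` (matrix of realised `(n_bait, n_prey)`).
#' @export
synthetic_catalog <- function(n_proteins, n_studies, ground_truth,
                              bias_alpha = 3.13, zero_frac = 0.24,
                              size_range = c(5, 200), balance_shape = c(0.7, 3),
                              fpr = 0.01, fnr = 0, method = c("AP-MS", "Y2H"),
                              seed = NULL) {
  n_proteins <- check_count(n_proteins, "n_proteins", min = 2)
  n_studies <- check_count(n_studies, "n_studies", min = 1)
  method <- match.arg(method)
  fpr <- check_prob(fpr, "fpr"); fnr <- check_prob(fnr, "fnr")
  stopifnot(inherits(ground_truth, "ppi_graph"), ground_truth$n == n_proteins)
  adj <- gt_adjacency(ground_truth)
  width <- max(6, nchar(as.character(n_proteins)) + 1)
  proteins <- sprintf(paste0("P%0", width - 1, "d"), seq_len(n_proteins))
  with_seed(seed, {
    interest <- rbait_usage(n_proteins, alpha = bias_alpha, zero_frac = zero_frac)
    baitable <- which(interest > 0)
    recs <- vector("list", n_studies)
    sizes <- matrix(0L, n_studies, 2, dimnames = list(NULL, c("n_bait", "n_prey")))
    for (s in seq_len(n_studies)) {
      np <- round(exp(stats::runif(1, log(size_range[1]), log(size_range[2]))))
      np <- min(max(np, 1L), n_proteins)
      nb <- max(1L, round(stats::rbeta(1, balance_shape[1], balance_shape[2]) * np))
      nb <- min(nb, length(baitable))
      baits <- baitable[sample(length(baitable), nb,
                               prob = interest[baitable])]
      preys <- if (method == "AP-MS") {
        sample(n_proteins, np)
      } else {
        sample(n_proteins, np, prob = interest + 0.01)
      }
      sizes[s, ] <- c(nb, np)
      u <- rep(baits, each = np)
      v <- rep.int(preys, nb)
      keep <- u != v
      u <- u[keep]; v <- v[keep]
      if (!length(u)) next
      is_edge <- adj[cbind(pmin(u, v), pmax(u, v))]
      pos <- stats::runif(length(u)) < ifelse(is_edge, 1 - fnr, fpr)
      if (!any(pos)) next
      recs[[s]] <- data.frame(study_id = sprintf("S%05d", s),
                              bait = proteins[u[pos]], prey = proteins[v[pos]],
                              method = method, stringsAsFactors = FALSE)
    }
    recs <- recs[!vapply(recs, is.null, logical(1))]
    records <- if (length(recs)) do.call(rbind, recs) else {
      data.frame(study_id = character(0), bait = character(0),
                 prey = character(0), method = character(0))
    }
    out <- study_catalog(records)
    attr(out, "interest") <- stats::setNames(interest, proteins)
    attr(out, "study_sizes") <- sizes
    out
  })
}
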