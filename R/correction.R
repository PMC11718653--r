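# Study-bias corrections of node degree: single-role degree recomputation for
# asymmetric study designs, design size balance, bait-usage normalisation,
# and hub extraction.

#' Size balance of a study design
#'
#' Ratio of the smaller to the larger of the bait and prey counts; 1 for a
#' symmetric design, near 0 for highly asymmetric ones.
#'
#' @param n_bait,n_prey Positive counts of distinct baits and preys.
#' @return Scalar in `(0, 1]`.
#' @examples
#' size_balance(3, 12) # 0.25
#' @export
size_balance <- function(n_bait, n_prey) {
  n_bait <- check_count(n_bait, "n_bait", min = 1)
  n_prey <- check_count(n_prey, "n_prey", min = 1)
  min(n_bait, n_prey) / max(n_bait, n_prey)
}

# Normalise a single study to a deduplicated data.frame(bait, prey) with
# self-interactions dropped (with a warning).
as_study_interactions <- function(study) {
  if (is.matrix(study)) study <- as.data.frame(study, stringsAsFactors = FALSE)
  if (!is.data.frame(study) || !all(c("bait", "prey") %in% names(study))) {
    stop_baitbias("`study` must be a data frame with columns `bait` and `prey`",
                  "baitbias_invalid_input")
  }
  if (nrow(study) == 0) {
    stop_baitbias("study has no interactions", "baitbias_invalid_input")
  }
  self <- study$bait == study$prey
  if (any(self)) {
    warning(sprintf("dropping %d self-interaction record(s)", sum(self)))
    study <- study[!self, , drop = FALSE]
  }
  if (nrow(study) == 0) {
    stop_baitbias("study has no non-self interactions", "baitbias_invalid_input")
  }
  study[!duplicated(paste(study$bait, study$prey, sep = "\r")), c("bait", "prey")]
}

#' Role-corrected degrees of a single study
#'
#' Recomputes per-protein degrees counting only one experimental role,
#' chosen by the study's design asymmetry: if the study used at most as many
#' baits as preys, only interactions in which a protein served as prey count
#' towards its degree (prey-degree); if it used more baits than preys, only
#' bait-role interactions count. Proteins appearing only in the non-counted
#' role get degree 0 but stay in the result. Duplicate `(bait, prey)` records
#' are collapsed and self-interactions dropped first.
#'
#' @param study Data frame with columns `bait` and `prey` (one study's
#'   interaction records).
#' @return Named integer vector: corrected degree per protein (all proteins
#'   of the study present).
#' @examples
#' st <- data.frame(bait = c("A", "A", "B", "B"), prey = c("C", "D", "C", "A"))
#' corrected_degrees(st) # prey-degrees: A 1, B 0, C 2, D 1
#' @export
corrected_degrees <- function(study) {
  study <- as_study_interactions(study)
  proteins <- sort(unique(c(study$bait, study$prey)))
  n_bait <- length(unique(study$bait))
  n_prey <- length(unique(study$prey))
  role <- if (n_bait <= n_prey) study$prey else study$bait
  deg <- table(factor(role, levels = proteins))
  stats::setNames(as.integer(deg), proteins)
}

#' Uncorrected (both-role) degrees of a single study
#'
#' Degree of each protein in the undirected simple graph of the study's
#' deduplicated interactions.
#'
#' @inheritParams corrected_degrees
#' @return Named integer vector of degrees.
#' @export
study_degrees <- function(study) {
  study <- as_study_interactions(study)
  u <- pmin(study$bait, study$prey)
  v <- pmax(study$bait, study$prey)
  keep <- !duplicated(paste(u, v, sep = "\r"))
  proteins <- sort(unique(c(study$bait, study$prey)))
  deg <- table(factor(c(u[keep], v[keep]), levels = proteins))
  stats::setNames(as.integer(deg), proteins)
}

#' Bait-usage-normalised degrees
#'
#' Divides each protein's aggregated degree by the number of times it was
#' used as bait, damping the direct effect of study bias on degree. Proteins
#' never used as bait divide by 1 (they keep their raw degree and are flagged),
#' so the least-baited proteins are not silently dropped.
#'
#' @param degrees Named numeric vector of aggregated degrees.
#' @param usage Named numeric vector of bait-usage counts (same protein
#'   universe; missing proteins count as usage 0).
#' @return Named numeric vector of normalised degrees, with attribute
#'   `"never_baited"` listing proteins with zero usage.
#' @examples
#' normalized_degrees(c(P1 = 40, P2 = 5), c(P1 = 10, P2 = 0))
#' @export
normalized_degrees <- function(degrees, usage) {
  if (is.null(names(degrees)) || is.null(names(usage))) {
    stop_baitbias("`degrees` and `usage` must be named by protein", "baitbias_invalid_input")
  }
  b <- usage[names(degrees)]
  b[is.na(b)] <- 0
  out <- degrees / pmax(b, 1)
  attr(out, "never_baited") <- names(degrees)[b == 0]
  out
}

#' Top-k hub proteins by score
#'
#' @param scores Named numeric vector (e.g. degrees or normalised degrees).
#' @param k Number of hubs to return (default 50).
#' @return Character vector of the k highest-scoring proteins, ties broken
#'   lexicographically by identifier.
#' @examples
#' top_hubs(c(a = 3, b = 1, c = 2), k = 2) # "a" "c"
#' @export
top_hubs <- function(scores, k = 50) {
  k <- check_count(k, "k", min = 1)
  if (is.null(names(scores))) {
    stop_baitbias("`scores` must be named by protein", "baitbias_invalid_input")
  }
  if (k > length(scores)) {
    stop_baitbias("`k` exceeds the number of scored proteins", "baitbias_invalid_parameter")
  }
  names(scores)[order(-scores, names(scores))][seq_len(k)]
}
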