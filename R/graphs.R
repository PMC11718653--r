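# Ground-truth interactome generators and the simple undirected graph
# container used throughout the package. A graph is a list(n, edges) where
# `edges` is a 2-column integer matrix of node indices with edges[, 1] <
# edges[, 2], each unordered pair stored once, and `nodes` holds identifiers
# (integers for synthetic graphs, accession strings for loaded ones).

#' Construct a simple undirected graph
#'
#' Validates and canonicalises an edge list into the package's graph
#' container: self-loops are rejected, duplicate edges (in either orientation)
#' are collapsed, and each edge is stored once with the smaller endpoint first.
#'
#' @param edges Two-column matrix or data frame of endpoints; either integer
#'   node indices in `1:n` or identifiers matching `nodes`.
#' @param n Number of nodes (required when `nodes` is absent and `edges` uses
#'   integer indices; isolated nodes are allowed).
#' @param nodes Optional vector of node identifiers; its length defines `n`.
#' @return An object of class `"ppi_graph"`.
#' @examples
#' g <- ppi_graph(rbind(c(1, 2), c(2, 3)), n = 4)
#' degree_sequence(g)
#' @export
ppi_graph <- function(edges, n = NULL, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(integer(0), ncol = 2)
  }
  if (ncol(edges) != 2) {
    stop_baitbias("`edges` must have two columns", "baitbias_invalid_input")
  }
  if (!is.null(nodes)) {
    nodes <- as.vector(nodes)
    if (anyDuplicated(nodes)) {
      stop_baitbias("`nodes` must be unique", "baitbias_invalid_input")
    }
    n <- length(nodes)
    if (!is.numeric(edges)) {
      idx <- match(edges, nodes)
      if (anyNA(idx)) {
        stop_baitbias("edge endpoints must appear in `nodes`", "baitbias_invalid_input")
      }
      edges <- matrix(idx, ncol = 2)
    }
  } else {
    if (is.null(n)) n <- if (length(edges)) max(edges) else 0L
    nodes <- seq_len(n)
  }
  n <- check_count(n, "n", min = 0)
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n)) {
      stop_baitbias("edge endpoints out of range", "baitbias_invalid_input")
    }
    if (any(edges[, 1] == edges[, 2])) {
      stop_baitbias("self-loops are not allowed in a simple graph",
                    "baitbias_invalid_input")
    }
    u <- pmin(edges[, 1], edges[, 2])
    v <- pmax(edges[, 1], edges[, 2])
    keep <- !duplicated((u - 1) * as.double(n) + v)
    edges <- cbind(u[keep], v[keep])
  }
  dimnames(edges) <- NULL
  structure(list(n = n, edges = edges, nodes = nodes), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("Simple undirected graph: %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a graph
#' @param g A `"ppi_graph"`.
#' @return Integer edge count.
#' @export
edge_count <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  nrow(g$edges)
}

#' Degree sequence of a graph
#'
#' @param g A `"ppi_graph"`.
#' @return Integer vector with one entry per node (number of incident edges),
#'   in node order.
#' @examples
#' degree_sequence(generate_er(10, 15, seed = 1))
#' @export
degree_sequence <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  tabulate(g$edges, nbins = g$n)
}

# Map linear pair indices t in 1..n(n-1)/2 (colexicographic order over pairs
# i < j) back to endpoints; exact in double precision for n < 2^26.
unrank_pairs <- function(t) {
  j <- floor((3 + sqrt(8 * t - 7)) / 2)
  i <- t - (j - 1) * (j - 2) / 2
  cbind(as.integer(i), as.integer(j))
}

#' Erdős–Rényi graph with a fixed number of edges, G(n, m)
#'
#' Draws a graph uniformly at random among all simple graphs with `n` nodes
#' and exactly `m_er` edges.
#'
#' @param n Number of nodes.
#' @param m_er Number of edges, at most `n * (n - 1) / 2`.
#' @param seed Optional integer seed.
#' @return A `"ppi_graph"`.
#' @examples
#' g <- generate_er(200, 400, seed = 1)
#' mean(degree_sequence(g)) # about 4
#' @export
generate_er <- function(n, m_er, seed = NULL) {
  n <- check_count(n, "n", min = 1)
  m_er <- check_count(m_er, "m_er", min = 0)
  npairs <- n * (n - 1) / 2
  if (m_er > npairs) {
    stop_baitbias("`m_er` exceeds the number of possible edges",
                  "baitbias_invalid_parameter")
  }
  with_seed(seed, {
    idx <- if (m_er > 0) sample(npairs, m_er) else numeric(0)
    ppi_graph(unrank_pairs(idx), n = n)
  })
}

#' Erdős–Rényi graph with independent edge probability, G(n, p)
#'
#' Includes each of the `n * (n - 1) / 2` possible edges independently with
#' probability `p`. `p = 0` yields the empty graph.
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A `"ppi_graph"`.
#' @export
generate_er_p <- function(n, p, seed = NULL) {
  n <- check_count(n, "n", min = 1)
  p <- check_prob(p, "p")
  npairs <- n * (n - 1) / 2
  if (npairs > .Machine$integer.max) {
    stop_baitbias("`n` too large for G(n, p) sampling", "baitbias_invalid_parameter")
  }
  with_seed(seed, {
    m <- stats::rbinom(1L, as.integer(npairs), p)
    idx <- if (m > 0) sample(npairs, m) else numeric(0)
    ppi_graph(unrank_pairs(idx), n = n)
  })
}

#' Barabási–Albert edge parameter matching a target edge count
#'
#' Computes the number of edges per growth step, `m_ba`, such that a
#' Barabási–Albert graph initialised with the star on `m_ba + 1` nodes ends
#' with approximately `m_er` edges: `m_ba = round(n/2 - sqrt(n^2/4 - m_er))`.
#' The final BA edge count is exactly `m_ba + m_ba * (n - (m_ba + 1))`.
#'
#' @param n Number of nodes.
#' @param m_er Target edge count, at most `n^2 / 4`.
#' @return Positive integer `m_ba`.
#' @examples
#' ba_edges_for_target(10, 21) # 3; and 3 + 3 * (10 - 4) == 21
#' @export
ba_edges_for_target <- function(n, m_er) {
  n <- check_count(n, "n", min = 1)
  m_er <- check_count(m_er, "m_er", min = 1)
  disc <- n^2 / 4 - m_er
  if (disc < 0) {
    stop_baitbias("`m_er` must not exceed n^2 / 4", "baitbias_invalid_parameter")
  }
  m_ba <- as.integer(round(n / 2 - sqrt(disc)))
  max(m_ba, 1L)
}

#' Barabási–Albert preferential-attachment graph
#'
#' Grows a graph by preferential attachment, starting from the star on
#' `m_ba + 1` nodes (the hub counts towards attachment like any other node).
#' Each subsequent node attaches `m_ba` edges to distinct existing nodes with
#' probability proportional to their current degree (urn sampling; duplicate
#' targets within one step are re-drawn, so the final edge count is exactly
#' `m_ba + m_ba * (n - (m_ba + 1))`).
#'
#' @param n Number of nodes (`> m_ba`).
#' @param m_ba Edges added per growth step.
#' @param seed Optional integer seed.
#' @return A `"ppi_graph"`.
#' @examples
#' g <- generate_ba(1000, 2, seed = 1)
#' edge_count(g) # 2 + 2 * 997
#' @export
generate_ba <- function(n, m_ba, seed = NULL) {
  n <- check_count(n, "n", min = 2)
  m_ba <- check_count(m_ba, "m_ba", min = 1)
  if (m_ba >= n) {
    stop_baitbias("`m_ba` must be smaller than `n`", "baitbias_invalid_parameter")
  }
  with_seed(seed, {
    total_edges <- m_ba + m_ba * (n - (m_ba + 1))
    eu <- integer(total_edges)
    ev <- integer(total_edges)
    # star on m_ba + 1 nodes, centre = node 1
    eu[seq_len(m_ba)] <- 1L
    ev[seq_len(m_ba)] <- seq_len(m_ba) + 1L
    # degree urn: node id repeated once per unit of degree
    urn <- integer(2 * total_edges)
    urn[seq_len(m_ba)] <- 1L
    urn[m_ba + seq_len(m_ba)] <- seq_len(m_ba) + 1L
    urn_len <- 2L * m_ba
    pos <- m_ba
    for (v in seq.int(from = m_ba + 2L, length.out = n - m_ba - 1L)) {
      targets <- unique(urn[sample.int(urn_len, m_ba, replace = TRUE)])
      while (length(targets) < m_ba) {
        extra <- urn[sample.int(urn_len, m_ba - length(targets), replace = TRUE)]
        targets <- unique(c(targets, extra))
      }
      eu[pos + seq_len(m_ba)] <- targets
      ev[pos + seq_len(m_ba)] <- v
      pos <- pos + m_ba
      urn[urn_len + seq_len(m_ba)] <- targets
      urn[urn_len + m_ba + seq_len(m_ba)] <- v
      urn_len <- urn_len + 2L * m_ba
    }
    ppi_graph(cbind(pmin(eu, ev), pmax(eu, ev)), n = n)
  })
}

#' Write a graph as a two-column TSV edge list
#'
#' One undirected edge per line with endpoints in ascending order.
#'
#' @param g A `"ppi_graph"`.
#' @param path Output file path.
#' @param header Write a header line (`u  v`)? Default `FALSE`.
#' @export
write_edges <- function(g, path, header = FALSE) {
  stopifnot(inherits(g, "ppi_graph"))
  df <- data.frame(u = g$nodes[g$edges[, 1]], v = g$nodes[g$edges[, 2]])
  swap <- as.character(df$u) > as.character(df$v)
  tmp <- df$u[swap]; df$u[swap] <- df$v[swap]; df$v[swap] <- tmp
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a graph from a two-column TSV edge list
#'
#' @param path Input file path.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @param nodes Optional full node universe (to keep isolated nodes).
#' @return A `"ppi_graph"` with string node identifiers.
#' @export
read_edges <- function(path, header = FALSE, nodes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "character")
  if (ncol(df) < 2) {
    stop_baitbias("edge list must have two columns", "baitbias_invalid_input")
  }
  ids <- nodes %||% sort(unique(c(df[[1]], df[[2]])))
  ppi_graph(cbind(df[[1]], df[[2]]), nodes = ids)
}
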