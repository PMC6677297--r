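# Connectivity analysis of interface structural space: threshold digraph,
# k-th neighbour directed-pair fractions, k-closure and strongly connected
# components.

#' Assemble an asymmetric IS-score matrix
#'
#' `score[q, t]` holds the IS-score of aligning query interface `q` against
#' template `t`; the score is not symmetric because it is normalized by the
#' query interface length. The diagonal is undefined (`NA`). Missing
#' (skipped) alignments may be left `NA` and are treated as below any
#' threshold when building graphs.
#'
#' @param records list of `domain_pair_record`s.
#' @param params a [ddi_params()] object.
#' @return N x N numeric matrix with interface ids as dimnames.
#' @export
score_matrix <- function(records, params = ddi_params()) {
  n <- length(records)
  stopifnot(n >= 2L)
  ids <- vapply(records, function(r) r$record_id, "")
  m <- matrix(NA_real_, n, n, dimnames = list(query = ids, template = ids))
  for (q in seq_len(n)) for (t in seq_len(n)) {
    if (q == t) next
    m[q, t] <- align_interfaces(records[[q]]$interface,
                                records[[t]]$interface,
                                params)$scores$IS_score
  }
  m
}

#' Threshold digraph over interfaces
#'
#' Nodes are interfaces; a directed edge points from template `t` to query
#' `q` whenever `score[q, t]` meets the IS-score threshold (inclusive by
#' default, see `params$edge_inclusive`). No self-edges; `NA` scores never
#' produce an edge.
#'
#' @param scores square score matrix from [score_matrix()] (rows queries,
#'   columns templates).
#' @param threshold IS-score threshold in (0, 1).
#' @param params a [ddi_params()] object.
#' @return An igraph directed graph with a `threshold` attribute.
#' @export
build_digraph <- function(scores, threshold, params = ddi_params()) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores),
            threshold > 0, threshold < 1)
  s <- scores
  diag(s) <- NA_real_
  hit <- if (params$edge_inclusive) s >= threshold else s > threshold
  hit[is.na(hit)] <- FALSE
  # edge template -> query: from column t to row q
  adj <- t(hit) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  g$threshold <- threshold
  g
}

#' Fraction of ordered node pairs within k directed steps
#'
#' An interface `B` is a k-th neighbour of `A` when the minimum directed
#' path length from `A` to `B` is at most `k`. The fraction is
#' `n_k / (N (N - 1))` over ordered pairs, self-pairs excluded.
#'
#' @param graph directed igraph graph.
#' @param k maximum path length, >= 1.
#' @return Fraction in `[0, 1]`.
#' @export
kth_neighbor_fraction <- function(graph, k) {
  stopifnot(k >= 1)
  n <- igraph::vcount(graph)
  if (n < 2L) return(NA_real_)
  d <- igraph::distances(graph, mode = "out")
  diag(d) <- Inf
  sum(d <= k) / (n * (n - 1))
}

#' k-closure of a digraph
#'
#' Graph with an edge `u -> v` whenever the directed distance from `u` to
#' `v` in the input graph is at most `k`.
#'
#' @param graph directed igraph graph.
#' @param k maximum path length, >= 1.
#' @return Directed igraph graph on the same nodes.
#' @export
k_closure <- function(graph, k) {
  stopifnot(k >= 1)
  d <- igraph::distances(graph, mode = "out")
  diag(d) <- Inf
  adj <- (d <= k) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  igraph::V(g)$name <- igraph::V(graph)$name
  g
}

#' Relative size of the largest strongly connected component at depth k
#'
#' Size of the largest strongly connected component of the k-closure (all
#' member nodes mutually reachable within k steps of the original graph),
#' divided by the node count.
#'
#' @param graph directed igraph graph.
#' @param k maximum path length, >= 1.
#' @return Fraction in `(0, 1]`.
#' @export
largest_scc_fraction <- function(graph, k = 1L) {
  g <- k_closure(graph, k)
  comp <- igraph::components(g, mode = "strong")
  max(comp$csize) / igraph::vcount(g)
}

#' Sweep connectivity metrics over thresholds and depths
#'
#' For every combination of IS-score threshold and path-length bound `k`,
#' reports the fraction of directed pairs within k steps and the relative
#' size of the largest strongly connected component of the k-closure.
#'
#' @param scores square score matrix (rows queries, columns templates).
#' @param thresholds numeric vector of IS-score thresholds.
#' @param ks integer vector of depths.
#' @param params a [ddi_params()] object.
#' @return Long-format data frame: `threshold`, `k`, `pair_fraction`,
#'   `lscc_fraction`, `n_edges`.
#' @export
sweep_connectivity <- function(scores, thresholds, ks,
                               params = ddi_params()) {
  stopifnot(length(thresholds) >= 1L, length(ks) >= 1L)
  out <- expand.grid(threshold = thresholds, k = as.integer(ks))
  out$pair_fraction <- NA_real_
  out$lscc_fraction <- NA_real_
  out$n_edges <- NA_integer_
  for (th in thresholds) {
    g <- build_digraph(scores, th, params)
    d <- igraph::distances(g, mode = "out")
    diag(d) <- Inf
    n <- igraph::vcount(g)
    for (k in ks) {
      i <- which(out$threshold == th & out$k == k)
      out$pair_fraction[i] <- sum(d <= k) / (n * (n - 1))
      out$lscc_fraction[i] <- largest_scc_fraction(g, k)
      out$n_edges[i] <- igraph::ecount(g)
    }
  }
  out
}

#' Write a score matrix as long-format TSV
#'
#' @param scores square score matrix.
#' @param file output path.
#' @return Invisibly, the data frame written (query, template, IS_score).
#' @export
write_score_matrix_tsv <- function(scores, file) {
  ids <- rownames(scores)
  df <- expand.grid(query = ids, template = ids, stringsAsFactors = FALSE)
  df$IS_score <- as.vector(scores)
  df <- df[df$query != df$template & !is.na(df$IS_score), , drop = FALSE]
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
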