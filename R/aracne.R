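# ARACNE-style inference: significant MI graph thinned by the data
# processing inequality (DPI).

#' Data-processing-inequality pruning of a significant-MI network
#'
#' Enumerates all triangles of the input network.  For each triangle
#' the minimum-MI edge (i', j') is marked for removal iff
#' I(i', j') <= I2 * (1 - epsilon), where I2 is the second-smallest MI
#' of the triple and epsilon is the tolerance.  All removal decisions
#' are computed from the input snapshot and applied in one batch, so
#' the result does not depend on triangle order.  If the two smallest
#' MI values of a triangle tie exactly, the lexicographically smallest
#' of the tied edges is the one marked.
#'
#' @param mi symmetric MI matrix covering all network genes.
#' @param net undirected igraph whose edges all have defined MI.
#' @param epsilon tolerance in \[0, 1\]; epsilon = 1 disables pruning
#'   for all strictly positive MI values.
#' @return igraph, a subgraph of `net` on the same vertex set.
#' @export
dpi_prune <- function(mi, net, epsilon = 0.15) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  tri <- igraph::triangles(net)
  if (length(tri) == 0L) return(net)
  tri <- matrix(igraph::V(net)$name[as.integer(tri)], nrow = 3L)
  drop_keys <- character(0)
  for (t in seq_len(ncol(tri))) {
    v <- tri[, t]
    pairs <- rbind(c(v[1L], v[2L]), c(v[2L], v[3L]), c(v[1L], v[3L]))
    vals <- mi[pairs]
    keys <- edge_key(pairs[, 1L], pairs[, 2L])
    ord <- order(vals, keys)
    if (vals[ord[1L]] <= vals[ord[2L]] * (1 - epsilon))
      drop_keys <- c(drop_keys, keys[ord[1L]])
  }
  drop_keys <- unique(drop_keys)
  if (length(drop_keys) == 0L) return(net)
  igraph::delete_edges(net, which(graph_edge_keys(net) %in% drop_keys))
}

#' ARACNE-style network inference
#'
#' Two steps: (1) build the graph of gene pairs whose Pearson-estimator
#' MI is significant against the global-shuffle null at the
#' Bonferroni-corrected level (or against a fixed MI threshold);
#' (2) prune indirect edges with the data processing inequality at
#' tolerance `epsilon`.
#'
#' @inheritParams c3net
#' @param epsilon DPI tolerance (default 0.15, the conventional value).
#' @param threshold optional fixed MI threshold; when supplied, the
#'   permutation null is skipped.
#' @param n_null size of the permutation null (the default is larger
#'   than C3Net's because the Bonferroni quantile over all gene pairs
#'   needs finer resolution).
#' @return undirected igraph over all genes of `expr`, a subgraph of
#'   the significant-MI graph; the MI threshold used is attached as the
#'   graph attribute `mi_threshold`.
#' @export
aracne <- function(expr, epsilon = 0.15, alpha = 0.05, threshold = NULL,
                   n_tests = NULL, n_null = 100000L, seed = 1L) {
  check_expr(expr, min_samples = 3L, min_genes = 2L)
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  mi <- pearson_mi_matrix(expr)
  if (is.null(threshold)) {
    threshold <- shuffle_null_threshold(expr, alpha = alpha,
                                        n_tests = n_tests, n_null = n_null,
                                        seed = seed)$threshold
  }
  g <- significant_mi_graph(mi, threshold)
  out <- dpi_prune(mi, g, epsilon)
  out$mi_threshold <- threshold
  out
}
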