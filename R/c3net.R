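# C3Net: conservative causal core network inference.

#' C3Net candidate edges (row-wise maximum MI partner)
#'
#' For every gene, selects the single partner with the largest MI.
#' Ties are broken towards the lexicographically smallest partner id so
#' the candidate set is deterministic.  The union of the per-gene
#' choices (deduplicated as undirected pairs) is the candidate edge set
#' on which C3Net's significance test operates.
#'
#' @param mi symmetric MI matrix with gene ids as dimnames.
#' @return data.frame with columns `from`, `to`, `mi`, one row per
#'   distinct candidate edge.
#' @export
c3net_candidates <- function(mi) {
  stopifnot(is.matrix(mi), nrow(mi) >= 2L)
  genes <- rownames(mi)
  n <- length(genes)
  partner <- character(n)
  value <- numeric(n)
  for (i in seq_len(n)) {
    row <- mi[i, ]
    row[i] <- -Inf
    m <- max(row)
    tied <- genes[which(row == m)]
    partner[i] <- tied[order(tied)][1L]
    value[i] <- m
  }
  key <- edge_key(genes, partner)
  keep <- !duplicated(key)
  data.frame(from = pmin(genes, partner)[keep],
             to = pmax(genes, partner)[keep],
             mi = value[keep],
             stringsAsFactors = FALSE)
}

#' C3Net network inference
#'
#' Conservative causal core inference: each gene nominates its single
#' maximum-MI partner, and a nominated edge is retained only if its MI
#' exceeds the Bonferroni-corrected threshold of the global-shuffle
#' null distribution.  The result is undirected and unweighted, with at
#' most one retained edge per nominating gene (hence <= n edges).
#'
#' @param expr numeric gene x sample matrix.
#' @param alpha significance level before Bonferroni correction.
#' @param n_tests Bonferroni factor for the null threshold; defaults to
#'   the number of gene pairs choose(n, 2).
#' @param n_null size of the permutation null.
#' @param seed integer seed (drives the null permutations).
#' @return undirected igraph over all genes of `expr`; isolated genes
#'   are kept as vertices.  The selected MI threshold is attached as
#'   the graph attribute `mi_threshold`.
#' @export
c3net <- function(expr, alpha = 0.05, n_tests = NULL, n_null = 100000L,
                  seed = 1L) {
  check_expr(expr, min_samples = 3L, min_genes = 2L)
  mi <- pearson_mi_matrix(expr)
  thr <- shuffle_null_threshold(expr, alpha = alpha, n_tests = n_tests,
                                n_null = n_null, seed = seed)$threshold
  cand <- c3net_candidates(mi)
  kept <- cand[cand$mi > thr, , drop = FALSE]
  g <- graph_from_edges(kept, rownames(expr))
  g$mi_threshold <- thr
  g
}
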