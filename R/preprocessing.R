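#' Summarize probe-level expression to gene level by the median
#'
#' Collapses a probe x sample matrix to a gene x sample matrix using the
#' element-wise median over all probes mapping to the same gene.  Probes
#' without an entry in the mapping are dropped.
#'
#' @param probe_matrix numeric matrix, probes as rows (rownames are probe
#'   ids), samples as columns.
#' @param mapping named character vector or 2-column data.frame
#'   (probe_id, gene_id).  Probes absent from the mapping are discarded.
#' @return numeric matrix with one row per mapped gene, same sample order.
#' @examples
#' m <- rbind(p1 = c(1, 3), p2 = c(3, 5))
#' colnames(m) <- c("s1", "s2")
#' summarize_probes_median(m, c(p1 = "geneA", p2 = "geneA"))
#' @export
summarize_probes_median <- function(probe_matrix, mapping) {
  check_expr(probe_matrix)
  if (is.data.frame(mapping)) {
    map <- stats::setNames(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
  } else {
    map <- mapping
  }
  if (length(map) == 0L) {
    warning("empty probe mapping: returning an empty matrix")
    out <- probe_matrix[0L, , drop = FALSE]
    return(out)
  }
  probes <- intersect(rownames(probe_matrix), names(map))
  genes <- map[probes]
  out_genes <- sort(unique(unname(genes)))
  out <- matrix(NA_real_, length(out_genes), ncol(probe_matrix),
                dimnames = list(out_genes, colnames(probe_matrix)))
  for (g in out_genes) {
    rows <- probes[genes == g]
    if (length(rows) == 1L) {
      out[g, ] <- probe_matrix[rows, ]
    } else {
      out[g, ] <- apply(probe_matrix[rows, , drop = FALSE], 2L, stats::median)
    }
  }
  out
}

#' Rank-based copula transform of an expression matrix
#'
#' Replaces each gene's profile by its empirical quantiles
#' rank/(n + 1), with average ranks for ties, so every row lies in (0, 1)
#' and only the within-gene rank order is retained.  This makes the
#' downstream correlation-based mutual-information estimate invariant to
#' monotone distortions of each gene's marginal.
#'
#' @param expr numeric gene x sample matrix with at least 2 samples.
#' @return matrix of the same shape with values in (0, 1).  A constant
#'   row maps to 0.5 everywhere.
#' @examples
#' copula_transform(rbind(g1 = c(10, 30, 20)))
#' @export
copula_transform <- function(expr) {
  check_expr(expr, min_samples = 2L)
  n <- ncol(expr)
  out <- t(apply(expr, 1L, function(x) rank(x, ties.method = "average"))) / (n + 1)
  dimnames(out) <- dimnames(expr)
  out
}
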