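# Comparison of inferred networks against reference interaction
# networks (protein-protein or transcriptional-regulatory surrogates).

#' Edge overlap between a GRN and a reference network
#'
#' Both networks are restricted (induced) to their shared genes before
#' counting: `grn_induced_edges` and `ref_induced_edges` are the edge
#' counts after restriction, `shared_edges` their intersection, and
#' `shared_pct` the percentage of induced GRN edges that are shared,
#' rounded to 3 decimals.
#'
#' @param grn undirected igraph (inferred network).
#' @param ref undirected igraph (reference network).
#' @return one-row data.frame: `shared_gene_count`,
#'   `grn_induced_edges`, `ref_induced_edges`, `shared_edges`,
#'   `shared_pct`.
#' @export
shared_edge_overlap <- function(grn, ref) {
  shared <- intersect(igraph::V(grn)$name, igraph::V(ref)$name)
  if (length(shared) < 2L) stop("need at least 2 shared genes")
  gi <- igraph::induced_subgraph(grn, shared)
  ri <- igraph::induced_subgraph(ref, shared)
  gk <- graph_edge_keys(gi)
  rk <- graph_edge_keys(ri)
  s <- length(intersect(gk, rk))
  data.frame(shared_gene_count = length(shared),
             grn_induced_edges = length(gk),
             ref_induced_edges = length(rk),
             shared_edges = s,
             shared_pct = overlap_pct(s, length(gk), digits = 3L))
}

#' Permutation significance of GRN/reference edge overlap
#'
#' Null model: shuffle the gene labels of the induced GRN within the
#' shared gene set (topology preserved) and recount shared edges.  The
#' p-value uses the add-one estimator p = (1 + #\{null >= observed\}) /
#' (R + 1), so it can never be exactly 0.
#'
#' @inheritParams shared_edge_overlap
#' @param R number of label permutations (>= 100).
#' @param seed integer seed.
#' @return numeric p-value in (0, 1\].
#' @export
overlap_significance <- function(grn, ref, R = 1000L, seed = 1L) {
  stopifnot(R >= 100L)
  shared <- intersect(igraph::V(grn)$name, igraph::V(ref)$name)
  if (length(shared) < 2L) stop("need at least 2 shared genes")
  shared <- sort(shared)
  n <- length(shared)
  gi <- igraph::induced_subgraph(grn, shared)
  ri <- igraph::induced_subgraph(ref, shared)
  # integer pair codes within the shared gene universe
  pair_code <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
  ge <- igraph::ends(gi, igraph::E(gi), names = TRUE)
  ia <- match(ge[, 1L], shared)
  ib <- match(ge[, 2L], shared)
  re <- igraph::ends(ri, igraph::E(ri), names = TRUE)
  ref_codes <- pair_code(match(re[, 1L], shared), match(re[, 2L], shared))
  obs <- sum(pair_code(ia, ib) %in% ref_codes)
  if (obs == 0L) return(1)  # every null count is >= 0 = observed
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(R)) {
    perm <- sample.int(n)
    if (sum(pair_code(perm[ia], perm[ib]) %in% ref_codes) >= obs)
      hits <- hits + 1L
  }
  (1 + hits) / (R + 1)
}

#' Critical Pearson correlation from the t distribution
#'
#' Two-sided significance boundary for a Pearson correlation of a
#' profile of length n: r_crit = t / sqrt(df + t^2) with
#' df = n - 2 and t the upper (1 - alpha/2) Student-t quantile.
#'
#' @param n profile length (>= 4).
#' @param alpha two-sided significance level.
#' @return critical correlation (the boundary is symmetric, +/- r).
#' @examples
#' correlation_boundary(25, 0.05)  # ~0.396
#' @export
correlation_boundary <- function(n, alpha = 0.05) {
  if (n < 4) stop("n must be >= 4")
  df <- n - 2
  t <- stats::qt(1 - alpha / 2, df)
  t / sqrt(df + t^2)
}

#' Sliding-window degree-correlation profile
#'
#' Genes shared by the two networks are ranked by GRN degree in
#' decreasing order (ties broken by gene id).  For window sizes
#' step, 2*step, ... (the last window always covers all shared genes)
#' the Pearson correlation between GRN degrees and reference degrees of
#' the top-ranked genes is computed, together with the two-sided
#' critical correlation from [correlation_boundary()].  A window with
#' zero degree variance yields `NA` with `significant = NA`.
#'
#' @inheritParams shared_edge_overlap
#' @param step window increment in genes (default 25).
#' @param alpha two-sided significance level of the boundary.
#' @param missing_as_zero if `TRUE`, genes of the GRN absent from the
#'   reference are kept with reference degree 0 instead of being
#'   excluded.
#' @return data.frame with columns `window_size`, `r`, `r_crit`,
#'   `significant`.
#' @export
window_degree_correlation <- function(grn, ref, step = 25L, alpha = 0.05,
                                      missing_as_zero = FALSE) {
  if (missing_as_zero) {
    genes <- igraph::V(grn)$name
    ref_deg <- stats::setNames(numeric(length(genes)), genes)
    present <- intersect(genes, igraph::V(ref)$name)
    ref_deg[present] <- igraph::degree(ref)[present]
  } else {
    genes <- intersect(igraph::V(grn)$name, igraph::V(ref)$name)
    ref_deg <- igraph::degree(ref)[genes]
  }
  if (length(genes) < step) stop("fewer shared genes than one window step")
  grn_deg <- igraph::degree(grn)[genes]
  ord <- order(-grn_deg, genes)
  grn_deg <- unname(grn_deg[ord])
  ref_deg <- unname(ref_deg[ord])
  sizes <- seq(step, length(genes), by = step)
  if (sizes[length(sizes)] != length(genes)) sizes <- c(sizes, length(genes))
  rows <- lapply(sizes, function(s) {
    gx <- grn_deg[seq_len(s)]
    rx <- ref_deg[seq_len(s)]
    r <- if (stats::sd(gx) == 0 || stats::sd(rx) == 0) NA_real_ else
      stats::cor(gx, rx)
    rc <- if (s >= 4) correlation_boundary(s, alpha) else NA_real_
    data.frame(window_size = s, r = r, r_crit = rc,
               significant = if (is.na(r) || is.na(rc)) NA else abs(r) > rc)
  })
  do.call(rbind, rows)
}
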