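# Gene-pair enrichment analysis (GPEA) and the degree-centrality
# pathway permutation test.

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-pair enrichment analysis (GPEA)
#'
#' Tests, for each gene set, whether the network contains more edges
#' connecting two genes of the set than expected by chance.  The
#' universe is the intersection of the network's genes and the genes
#' annotated anywhere in the collection.  With N universe genes, a
#' term of k universe genes and a network of d edges inside the
#' universe, the observed within-term edge count is compared to an
#' upper-tail hypergeometric: population N(N-1)/2 gene pairs, of which
#' k(k-1)/2 are within-term, with d draws.
#'
#' @param net undirected igraph.
#' @param sets named list of character vectors (a gene-set collection,
#'   e.g. from [read_gmt()]).
#' @param min_size smallest universe-restricted term size tested
#'   (default 2; a single gene admits no pair).
#' @return data.frame with one row per tested term: `term`, `size`
#'   (universe-restricted), `within_pairs`, `observed_edges`,
#'   `expected_edges`, `p`, `q` (BH across tested terms), sorted by
#'   `p`.
#' @export
gpea <- function(net, sets, min_size = 2L) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- intersect(igraph::V(net)$name, unique(unlist(sets)))
  if (length(universe) < 2L) stop("empty universe: no annotated network genes")
  N <- length(universe)
  n_pairs <- N * (N - 1) / 2
  ed <- igraph::ends(net, igraph::E(net), names = TRUE)
  inside <- ed[, 1L] %in% universe & ed[, 2L] %in% universe
  ed <- ed[inside, , drop = FALSE]
  d <- nrow(ed)
  res <- lapply(names(sets), function(nm) {
    genes <- intersect(unique(sets[[nm]]), universe)
    k <- length(genes)
    if (k < min_size) return(NULL)
    K <- k * (k - 1) / 2
    obs <- sum(ed[, 1L] %in% genes & ed[, 2L] %in% genes)
    p <- if (K == 0) 1 else
      stats::phyper(obs - 1, K, n_pairs - K, d, lower.tail = FALSE)
    data.frame(term = nm, size = k, within_pairs = K,
               observed_edges = obs,
               expected_edges = d * K / n_pairs,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(term = character(0), size = integer(0),
                      within_pairs = numeric(0), observed_edges = integer(0),
                      expected_edges = numeric(0), p = numeric(0),
                      q = numeric(0)))
  res$q <- bh_fdr(res$p)
  res[order(res$p, res$term), , drop = FALSE]
}

#' Degree-centrality pathway permutation test
#'
#' For each gene set, the test statistic delta_obs is the mean network
#' degree of the set's genes present in the network.  The null
#' distribution is obtained by randomizing gene labels, implemented
#' equivalently (and far cheaper) as drawing the same number of degrees
#' without replacement from the network's degree sequence.  The
#' p-value is the fraction of `R` randomizations with delta >=
#' delta_obs, floored at 1/R; q-values are BH across all tested terms.
#'
#' @param net undirected igraph.
#' @param sets named list of character vectors.
#' @param R number of randomizations (>= 100; 10000 matches common
#'   practice).
#' @param seed integer seed.
#' @return data.frame with one row per tested term: `term`, `size`
#'   (genes of the term present in the network), `delta_obs`,
#'   `delta_avg` (mean network degree over all annotated network
#'   genes, identical for every term), `p`, `fdr`; attribute `R`.
#'   Terms with no genes in the network are skipped with a message.
#' @export
degree_pathway_test <- function(net, sets, R = 10000L, seed = 1L) {
  stopifnot(is.list(sets), !is.null(names(sets)), R >= 100L)
  genes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  annotated <- intersect(genes, unique(unlist(sets)))
  delta_avg <- mean(deg[annotated])
  n <- length(genes)
  set.seed(seed)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), genes)
    k <- length(members)
    if (k == 0L) {
      message("term '", nm, "' has no genes in the network; skipped")
      return(NULL)
    }
    delta_obs <- mean(deg[members])
    null <- vapply(seq_len(R),
                   function(i) mean(deg[sample.int(n, k)]), 0)
    p <- max(sum(null >= delta_obs) / R, 1 / R)
    data.frame(term = nm, size = k, delta_obs = delta_obs,
               delta_avg = delta_avg, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(structure(data.frame(term = character(0), size = integer(0),
                                delta_obs = numeric(0), delta_avg = numeric(0),
                                p = numeric(0), fdr = numeric(0)), R = R))
  res$fdr <- bh_fdr(res$p)
  res <- res[order(res$p, res$term), , drop = FALSE]
  attr(res, "R") <- R
  res
}
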