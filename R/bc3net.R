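# BC3Net: bootstrap-aggregated C3Net with a binomial consensus test.

#' Bootstrap ensemble of C3Net networks
#'
#' Draws `B` bootstrap resamples of the samples (with replacement, same
#' size), infers a C3Net network from each, and aggregates edge
#' occurrence counts into a consensus network.  The consensus null edge
#' probability `p0` is the mean ensemble network density: the average
#' number of edges per bootstrap network divided by the number of
#' possible gene pairs.
#'
#' @inheritParams c3net
#' @param B ensemble size (>= 1).
#' @return object of class `consensus_network`: a list with `edges`
#'   (data.frame `from`, `to`, `count`), `B`, `p0`, and `genes`.
#' @export
bootstrap_ensemble <- function(expr, B = 100L, alpha = 0.05, n_tests = NULL,
                               n_null = 100000L, seed = 1L) {
  check_expr(expr, min_samples = 3L, min_genes = 2L)
  if (B < 1L) stop("B must be >= 1")
  seeds <- derive_seeds(seed, B + 1L)
  set.seed(seeds[B + 1L])
  idx <- matrix(sample.int(ncol(expr), ncol(expr) * B, replace = TRUE),
                ncol = B)
  counts <- integer(0)
  sizes <- integer(B)
  for (b in seq_len(B)) {
    g <- c3net(expr[, idx[, b], drop = FALSE], alpha = alpha,
               n_tests = n_tests, n_null = n_null, seed = seeds[b])
    keys <- graph_edge_keys(g)
    sizes[b] <- length(keys)
    tab <- table(keys)
    common <- intersect(names(counts), names(tab))
    counts[common] <- counts[common] + as.integer(tab[common])
    new <- setdiff(names(tab), names(counts))
    counts <- c(counts, stats::setNames(as.integer(tab[new]), new))
  }
  n <- nrow(expr)
  edges <- if (length(counts)) {
    parts <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
    data.frame(from = parts[, 1L], to = parts[, 2L],
               count = unname(counts), stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), count = integer(0))
  }
  structure(list(edges = edges, B = B,
                 p0 = mean(sizes) / (n * (n - 1) / 2),
                 genes = rownames(expr)),
            class = "consensus_network")
}

#' Binomial test on consensus edge counts
#'
#' For each consensus edge seen `k` times in `B` bootstrap networks,
#' computes the one-sided binomial tail p = P(K >= k | B, p0) and
#' retains the edge iff p <= alpha / (number of tested edges)
#' (Bonferroni over the consensus edges).
#'
#' @param consensus a `consensus_network` from [bootstrap_ensemble()].
#' @param alpha significance level before Bonferroni correction.
#' @return undirected, unweighted igraph over the consensus gene set.
#' @export
binomial_edge_test <- function(consensus, alpha = 0.05) {
  stopifnot(inherits(consensus, "consensus_network"))
  edges <- consensus$edges
  if (nrow(edges) == 0L)
    return(graph_from_edges(edges, consensus$genes))
  p0 <- consensus$p0
  if (p0 <= 0 || p0 >= 1)
    stop("consensus null probability p0 must lie strictly in (0, 1)")
  p <- stats::pbinom(edges$count - 1L, consensus$B, p0, lower.tail = FALSE)
  keep <- p <= alpha / nrow(edges)
  graph_from_edges(edges[keep, , drop = FALSE], consensus$genes)
}

#' BC3Net network inference
#'
#' Bagged C3Net: composition of [bootstrap_ensemble()] and
#' [binomial_edge_test()].  Deterministic given the seed.
#'
#' @inheritParams bootstrap_ensemble
#' @param alpha_c3net significance level of each bootstrap C3Net.
#' @param alpha_binomial significance level of the consensus binomial
#'   test.
#' @return undirected igraph over all genes of `expr`.
#' @export
bc3net <- function(expr, B = 100L, alpha_c3net = 0.05,
                   alpha_binomial = 0.05, n_tests = NULL,
                   n_null = 100000L, seed = 1L) {
  cons <- bootstrap_ensemble(expr, B = B, alpha = alpha_c3net,
                             n_tests = n_tests, n_null = n_null, seed = seed)
  binomial_edge_test(cons, alpha = alpha_binomial)
}
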