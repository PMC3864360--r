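# Synthetic ground-truth networks, expression data, gene sets and
# reference networks, so every downstream stage is testable at desk
# scale without external data.

#' Generate a ground-truth network
#'
#' Topologies: `scale_free` (preferential attachment, matching the
#' hub-dominated structure coexpression studies analyse),
#' `erdos_renyi` (G(n, p) with p chosen to hit the requested mean
#' degree), `star`, and `chain`.  Genes are named `g1`, `g2`, ...
#'
#' @param n_genes number of genes (>= 2).
#' @param topology one of `"scale_free"`, `"erdos_renyi"`, `"star"`,
#'   `"chain"`.
#' @param mean_degree target mean degree (scale_free / erdos_renyi
#'   only; must be < n_genes - 1).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return undirected simple igraph with graph attribute `topology`.
#' @export
generate_ground_truth_network <- function(n_genes,
                                          topology = c("scale_free",
                                                       "erdos_renyi",
                                                       "star", "chain"),
                                          mean_degree = 2,
                                          seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_genes >= 2L)
  if (topology %in% c("scale_free", "erdos_renyi") &&
      mean_degree >= n_genes - 1)
    stop("mean_degree must be < n_genes - 1")
  set.seed(seed)
  g <- switch(topology,
    scale_free = igraph::sample_pa(n_genes, m = max(1L, round(mean_degree / 2)),
                                   directed = FALSE),
    erdos_renyi = igraph::sample_gnp(n_genes, p = mean_degree / (n_genes - 1)),
    star = igraph::make_star(n_genes, mode = "undirected", center = 1L),
    chain = igraph::make_ring(n_genes, circular = FALSE))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("g", seq_len(n_genes))
  g$topology <- topology
  g
}

#' Simulate expression data from a ground-truth network
#'
#' Linear Gaussian factor model with one-step propagation along edges.
#' Each true edge e carries an independent standard-normal latent
#' factor f_e.  Gene i loads on its own incident edge factors with
#' weight 1 and, attenuated by `propagation`, on the factors of edges
#' incident to its direct neighbours -- so correlation propagates one
#' step along true edges and decays with path length, the premise the
#' data-processing-inequality pruning relies on.  Loadings are
#' rescaled so gene i's signal variance is s * degree(i)
#' (s = `edge_signal`) on top of independent noise with variance
#' (1 - s) * noise_sd^2, and rows are standardized to unit population
#' variance (correlations are unaffected).
#'
#' Consequences of this construction:
#' * two degree-1 genes joined by an edge (with `noise_sd = 1`) have
#'   population correlation exactly s, whatever `propagation`;
#' * hub genes accumulate variance from several factors, so their edge
#'   correlations are attenuated -- hub edges are harder to infer than
#'   peripheral ones;
#' * two-hop gene pairs are correlated (roughly half the direct-edge
#'   correlation at the default `propagation`), but always less than
#'   the weaker of the two direct edges on the path.
#'
#' @param truth igraph ground-truth network (named vertices).
#' @param n_samples number of samples (>= 3).
#' @param edge_signal target correlation along true edges, strictly in
#'   (0, 1).
#' @param noise_sd noise scale (> 0); 1 keeps the degree-1 edge
#'   correlation exactly at `edge_signal`.
#' @param propagation one-step leakage of edge factors onto the
#'   endpoints' neighbours (>= 0); 0 recovers the pure per-edge factor
#'   model in which non-adjacent genes are uncorrelated.
#' @param seed integer seed.
#' @return numeric matrix, |genes| rows x `n_samples` columns, sample
#'   ids `s1`, `s2`, ...
#' @export
simulate_expression <- function(truth, n_samples, edge_signal = 0.85,
                                noise_sd = 1, propagation = 0.4,
                                seed = 1L) {
  genes <- igraph::V(truth)$name
  if (length(genes) == 0L) stop("empty gene list")
  stopifnot(n_samples >= 3L, edge_signal > 0, edge_signal < 1,
            noise_sd > 0, propagation >= 0)
  set.seed(seed)
  n <- length(genes)
  m <- igraph::gsize(truth)
  s <- edge_signal
  deg <- igraph::degree(truth)
  x <- matrix(0, n, n_samples)
  if (m > 0L) {
    ed <- igraph::ends(truth, igraph::E(truth), names = FALSE)
    inc <- matrix(0, n, m)                    # incidence: genes x edges
    inc[cbind(ed[, 1L], seq_len(m))] <- 1
    inc[cbind(ed[, 2L], seq_len(m))] <- 1
    adj <- igraph::as_adjacency_matrix(truth, sparse = FALSE)
    w <- inc + propagation * (adj %*% inc)    # one-step leakage
    norm <- sqrt(rowSums(w^2))
    scale <- ifelse(norm > 0, sqrt(s * deg) / norm, 0)
    fac <- matrix(stats::rnorm(m * n_samples), m)
    x <- (w * scale) %*% fac
  }
  x <- x + sqrt(1 - s) * noise_sd * matrix(stats::rnorm(n * n_samples), n)
  v <- deg * s + (1 - s) * noise_sd^2
  x <- x / sqrt(v)
  dimnames(x) <- list(genes, paste0("s", seq_len(n_samples)))
  x
}

#' Generate a gene-set collection
#'
#' `n_sets` random sets with sizes uniform in `size_range`, drawn from
#' `genes`.  Optional planted modules are appended verbatim under the
#' names `planted_1`, `planted_2`, ... -- these are the known positives
#' for enrichment tests.
#'
#' @param genes gene universe (character vector).
#' @param n_sets number of random sets.
#' @param size_range length-2 integer vector, sizes within
#'   \[2, length(genes)\], non-inverted.
#' @param planted_modules optional list of character vectors (subsets
#'   of `genes`) inserted verbatim.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
generate_gene_sets <- function(genes, n_sets, size_range = c(5L, 20L),
                               planted_modules = NULL, seed = 1L) {
  stopifnot(length(size_range) == 2L)
  if (size_range[1L] > size_range[2L]) stop("inverted size_range")
  if (size_range[1L] < 2L || size_range[2L] > length(genes))
    stop("size_range must lie within [2, number of genes]")
  set.seed(seed)
  sizes <- seq(size_range[1L], size_range[2L])
  ks <- if (length(sizes) == 1L) rep(sizes, n_sets) else
    sample(sizes, n_sets, replace = TRUE)
  sets <- lapply(ks, function(k) sample(genes, k))
  names(sets) <- sprintf("set_%03d", seq_len(n_sets))
  if (!is.null(planted_modules)) {
    stopifnot(all(unlist(planted_modules) %in% genes))
    planted <- lapply(planted_modules, as.character)
    names(planted) <- paste0("planted_", seq_along(planted))
    sets <- c(sets, planted)
  }
  sets
}

#' Generate a reference network with controlled overlap with the truth
#'
#' Retains round(keep_frac * M) randomly chosen true edges and adds
#' `spurious_edges` random gene pairs that are not true edges.  Stands
#' in for experimentally derived interaction networks whose overlap
#' with the underlying truth is partial.
#'
#' @param truth igraph ground-truth network.
#' @param keep_frac fraction of true edges to retain, in \[0, 1\].
#' @param spurious_edges number of non-true edges to add.
#' @param seed integer seed.
#' @return undirected igraph over the truth's genes.
#' @export
generate_reference_network <- function(truth, keep_frac = 0.5,
                                       spurious_edges = 0L, seed = 1L) {
  stopifnot(keep_frac >= 0, keep_frac <= 1, spurious_edges >= 0)
  genes <- igraph::V(truth)$name
  n <- length(genes)
  true_keys <- graph_edge_keys(truth)
  m <- length(true_keys)
  n_possible <- n * (n - 1) / 2
  if (spurious_edges > n_possible - m)
    stop("spurious_edges exceeds the number of available non-edges")
  set.seed(seed)
  kept <- sample(seq_len(m), round(keep_frac * m))
  edges <- if (length(kept)) {
    do.call(rbind, strsplit(true_keys[kept], "\r", fixed = TRUE))
  } else {
    matrix(character(0), 0L, 2L)
  }
  if (spurious_edges > 0L) {
    # enumerate all pairs for desk-scale universes, rejection-sample otherwise
    if (n_possible <= 2e6) {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keys <- edge_key(genes[idx[, 1L]], genes[idx[, 2L]])
      avail <- which(!(keys %in% true_keys))
      pick <- sample(avail, spurious_edges)
      edges <- rbind(edges, cbind(genes[idx[pick, 1L]], genes[idx[pick, 2L]]))
    } else {
      got <- character(0)
      while (length(got) < spurious_edges) {
        a <- genes[sample.int(n, spurious_edges)]
        b <- genes[sample.int(n, spurious_edges)]
        k <- edge_key(a, b)
        ok <- a != b & !(k %in% true_keys) & !(k %in% got) & !duplicated(k)
        got <- c(got, k[ok])
      }
      got <- got[seq_len(spurious_edges)]
      edges <- rbind(edges, do.call(rbind, strsplit(got, "\r", fixed = TRUE)))
    }
  }
  graph_from_edges(data.frame(from = edges[, 1L], to = edges[, 2L],
                              stringsAsFactors = FALSE), genes)
}
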