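# Centrality and global graph statistics, overlap tables, gene ranks,
# ego subnetworks.

#' Per-gene centrality profile
#'
#' Degree (number of direct neighbours), local transitivity (clustering
#' coefficient: fraction of realised edges among a gene's neighbours)
#' and shortest-path betweenness.  Local transitivity is undefined for
#' degree < 2; such genes are reported with value 0 and
#' `transitivity_defined = FALSE`.
#'
#' @param net undirected igraph.
#' @return data.frame with columns `gene`, `degree`, `betweenness`,
#'   `transitivity`, `transitivity_defined`.
#' @export
centralities <- function(net) {
  deg <- igraph::degree(net)
  tr <- igraph::transitivity(net, type = "local", isolates = "NaN")
  defined <- !is.nan(tr)
  tr[!defined] <- 0
  data.frame(gene = igraph::V(net)$name,
             degree = unname(deg),
             betweenness = unname(igraph::betweenness(net)),
             transitivity = unname(tr),
             transitivity_defined = unname(defined),
             stringsAsFactors = FALSE)
}

#' Global summary statistics of a network
#'
#' Edge density M / (n(n-1)/2), maximum degree, connected components,
#' size of the giant connected component, degree assortativity (Pearson
#' correlation of degrees across edge endpoints; `NaN` when the degree
#' sequence has zero variance) and global transitivity
#' (3 x triangles / connected triples).
#'
#' @param net undirected igraph with at least 2 vertices.
#' @return one-row data.frame with columns `n_genes`, `n_edges`,
#'   `edge_density`, `max_degree`, `n_components`, `gcc_size`,
#'   `assortativity`, `global_transitivity`.
#' @export
global_summary <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("edge density undefined for networks with < 2 genes")
  comp <- igraph::components(net)
  deg <- igraph::degree(net)
  assort <- NaN
  if (igraph::gsize(net) > 0L) {
    ends_deg <- deg[as.vector(igraph::ends(net, igraph::E(net), names = FALSE))]
    if (stats::sd(ends_deg) > 0)  # zero degree variance over endpoints -> NaN flag
      assort <- suppressWarnings(igraph::assortativity_degree(net, directed = FALSE))
  }
  if (is.na(assort)) assort <- NaN
  gt <- igraph::transitivity(net, type = "global")
  if (is.nan(gt)) gt <- NaN
  data.frame(n_genes = n,
             n_edges = igraph::gsize(net),
             edge_density = igraph::gsize(net) / (n * (n - 1) / 2),
             max_degree = if (n > 0) max(deg) else 0L,
             n_components = comp$no,
             gcc_size = max(comp$csize),
             assortativity = assort,
             global_transitivity = gt)
}

#' Row-relative edge-overlap percentage
#'
#' The convention used by the pairwise network-overlap table: the
#' percentage of the row network's edges that are shared, rounded to
#' `digits` decimals.
#'
#' @param shared number of shared edges.
#' @param n_edges edge count of the row network.
#' @param digits decimals to round to (default 2).
#' @return numeric percentage in \[0, 100\]; `NaN` if `n_edges` is 0.
#' @export
overlap_pct <- function(shared, n_edges, digits = 2L) {
  ifelse(n_edges > 0, round(100 * shared / n_edges, digits), NaN)
}

#' Pairwise edge-overlap table between networks
#'
#' Shared edge counts (symmetric) and row-relative percentages
#' (generally asymmetric: shared / row network's edge count).
#'
#' @param nets named list of >= 2 undirected igraphs over a common gene
#'   universe.
#' @return object of class `overlap_table`: list with matrices `shared`
#'   (counts) and `pct` (row-relative percentages, 2 decimals; `NaN`
#'   rows flag empty networks).
#' @export
edge_overlap_table <- function(nets) {
  stopifnot(is.list(nets), length(nets) >= 2L, !is.null(names(nets)))
  keys <- lapply(nets, graph_edge_keys)
  k <- length(nets)
  shared <- matrix(0L, k, k, dimnames = list(names(nets), names(nets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    shared[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  m <- vapply(keys, length, 0L)
  pct <- overlap_pct(shared, matrix(m, k, k), digits = 2L)
  dimnames(pct) <- dimnames(shared)
  structure(list(shared = shared, pct = pct), class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("Shared edge counts:\n")
  print(x$shared)
  cat("Row-relative overlap (%):\n")
  print(x$pct)
  invisible(x)
}

#' Centrality ranks of a single gene
#'
#' Rank of a gene in decreasing order of each centrality measure.
#' Ties share the minimum ("competition") rank.  The raw value is
#' reported alongside each rank.
#'
#' @param profiles data.frame from [centralities()].
#' @param gene gene identifier present in `profiles`.
#' @return data.frame with columns `measure`, `value`, `rank`.
#' @export
rank_of_gene <- function(profiles, gene) {
  i <- match(gene, profiles$gene)
  if (is.na(i)) stop("unknown gene: ", gene)
  measures <- c("degree", "betweenness", "transitivity")
  data.frame(measure = measures,
             value = vapply(measures, function(m) profiles[[m]][i], 0),
             rank = vapply(measures, function(m)
               rank(-profiles[[m]], ties.method = "min")[i], 0),
             row.names = NULL)
}

#' Ego subnetwork around a gene
#'
#' Induced subgraph on all genes within graph distance <= `order` of
#' the focal gene (e.g. order 2 gives the gene, its neighbours and
#' their neighbours).
#'
#' @param net undirected igraph.
#' @param gene focal gene identifier.
#' @param order neighbourhood radius (>= 1).
#' @return igraph; a single-vertex graph if the gene is isolated.
#' @export
ego_subnetwork <- function(net, gene, order = 2L) {
  if (!gene %in% igraph::V(net)$name) stop("unknown gene: ", gene)
  stopifnot(order >= 1L)
  igraph::make_ego_graph(net, order = order, nodes = gene)[[1L]]
}
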