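# Internal helpers shared across modules.

#' @importFrom igraph V E ends gsize vcount
NULL

# Canonical undirected edge key "a|b" with endpoints in sorted order.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Edge keys of an igraph network (character vector, one per edge).
graph_edge_keys <- function(g) {
  if (igraph::gsize(g) == 0L) return(character(0))
  e <- igraph::ends(g, igraph::E(g), names = TRUE)
  edge_key(e[, 1L], e[, 2L])
}

# Build an undirected simple graph over a fixed gene universe from an
# edge matrix/data.frame with columns (from, to).  Self-loops and
# duplicate (a,b)/(b,a) pairs are collapsed.
graph_from_edges <- function(edges, genes) {
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  igraph::V(g)$name <- genes
  if (NROW(edges) > 0L) {
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    if (length(a)) {
      key <- edge_key(a, b)
      dup <- duplicated(key)
      a <- a[!dup]; b <- b[!dup]
      g <- igraph::add_edges(g, rbind(a, b))
    }
  }
  g
}

# Validate an expression matrix: numeric, finite, named rows/cols.
check_expr <- function(expr, min_samples = 1L, min_genes = 1L) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)))
    stop("expression matrix must have gene identifiers as rownames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (nrow(expr) < min_genes)
    stop("need at least ", min_genes, " genes")
  if (ncol(expr) < min_samples)
    stop("need at least ", min_samples, " samples")
  if (!all(is.finite(expr)))
    stop("expression matrix contains non-finite values")
  invisible(expr)
}

# Derive a stream of child seeds from one user-facing seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
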