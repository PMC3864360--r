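# Independent oracles and fixture builders shared across test files.
# The oracles deliberately use naive enumeration, not the package's
# code paths.

# canonical undirected edge labels, independent of package internals
ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")

graph_keys <- function(g) {
  if (igraph::gsize(g) == 0L) return(character(0))
  e <- igraph::ends(g, igraph::E(g), names = TRUE)
  sort(ekey(e[, 1L], e[, 2L]))
}

# exhaustive per-gene row-maximum search (C3Net candidate oracle);
# ties resolved to the lexicographically smallest partner
oracle_candidates <- function(mi) {
  genes <- rownames(mi)
  out <- character(0)
  for (i in seq_along(genes)) {
    best <- NA_character_
    bestv <- -Inf
    for (j in seq_along(genes)) {
      if (j == i) next
      v <- mi[i, j]
      if (v > bestv || (v == bestv && genes[j] < best)) {
        bestv <- v
        best <- genes[j]
      }
    }
    out <- c(out, ekey(genes[i], best))
  }
  sort(unique(out))
}

# naive triple-enumeration DPI oracle: visit every vertex triple of
# the input graph, test Eq.-style removal on complete triangles only,
# remove marked edges in one batch at the end
oracle_dpi <- function(mi, net, eps) {
  genes <- igraph::V(net)$name
  keys <- graph_keys(net)
  marked <- character(0)
  if (length(genes) >= 3L) {
    trip <- utils::combn(sort(genes), 3L)
    for (t in seq_len(ncol(trip))) {
      v <- trip[, t]
      ks <- c(ekey(v[1L], v[2L]), ekey(v[2L], v[3L]), ekey(v[1L], v[3L]))
      if (!all(ks %in% keys)) next
      vals <- c(mi[v[1L], v[2L]], mi[v[2L], v[3L]], mi[v[1L], v[3L]])
      ord <- order(vals, ks)
      if (vals[ord[1L]] <= vals[ord[2L]] * (1 - eps))
        marked <- c(marked, ks[ord[1L]])
    }
  }
  sort(setdiff(keys, marked))
}

# random symmetric MI-like matrix with distinct off-diagonal values
rand_mi <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  m
}

# closed-form upper-tail hypergeometric computed from choose(), not phyper
hyper_tail_oracle <- function(obs, K, N, n_draw) {
  xs <- obs:min(K, n_draw)
  sum(choose(K, xs) * choose(N - K, n_draw - xs)) / choose(N, n_draw)
}

# study-condition fixture: scale-free truth, simulated expression
make_fixture <- function(seed, n_genes = 100L, n_samples = 200L,
                         edge_signal = 0.85) {
  truth <- generate_ground_truth_network(n_genes, "scale_free",
                                         mean_degree = 2, seed = seed)
  expr <- simulate_expression(truth, n_samples, edge_signal = edge_signal,
                              seed = seed + 1L)
  list(truth = truth, expr = expr)
}

# copy of a graph with gene names randomly reassigned to vertices
# (topology preserved, name-structure association destroyed)
relabeled_copy <- function(g, seed) {
  set.seed(seed)
  igraph::set_vertex_attr(g, "name", value = sample(igraph::V(g)$name))
}

# hand-built consensus object for binomial-test unit tests
make_consensus <- function(from, to, count, B, p0, genes) {
  structure(list(edges = data.frame(from = from, to = to, count = count,
                                    stringsAsFactors = FALSE),
                 B = B, p0 = p0, genes = genes),
            class = "consensus_network")
}
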