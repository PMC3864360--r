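# Pearson (Gaussian) mutual-information estimation and its permutation null.

# rho -> MI in nats; |rho| = 1 maps to +Inf.
rho_to_mi <- function(rho) {
  -0.5 * log1p(-pmin(rho^2, 1))
}

#' Mutual-information matrix from the Pearson estimator
#'
#' Estimates mutual information between every pair of genes as
#' I(X, Y) = -1/2 log(1 - rho^2) (natural log), where rho is the Pearson
#' correlation of the two expression profiles.  Perfectly correlated
#' pairs (|rho| = 1) are stored as `Inf`, which outranks every finite MI
#' value and therefore always passes significance thresholds.
#'
#' @param expr numeric gene x sample matrix, >= 2 genes, >= 3 samples.
#' @return symmetric numeric matrix (genes x genes) of MI values in nats;
#'   the diagonal is set to 0 and carries no meaning.  Constant gene
#'   profiles have undefined correlation; their MI is set to 0 with a
#'   warning.
#' @examples
#' x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 1, 3, 2))
#' pearson_mi_matrix(x)
#' @export
pearson_mi_matrix <- function(expr) {
  check_expr(expr, min_samples = 3L, min_genes = 2L)
  rho <- suppressWarnings(stats::cor(t(expr)))
  if (anyNA(rho)) {
    bad <- rownames(expr)[apply(expr, 1L, function(x) stats::sd(x) == 0)]
    warning("constant gene profile(s), MI set to 0: ",
            paste(bad, collapse = ", "))
    rho[is.na(rho)] <- 0
  }
  mi <- rho_to_mi(rho)
  diag(mi) <- 0
  mi
}

#' Global-shuffle null distribution and significance threshold for MI
#'
#' Draws the null distribution of the Pearson-estimator MI under
#' independence by permuting all entries of the expression matrix
#' globally (sample and gene labels at once), recomputing MI for gene
#' pairs of the shuffled matrix, and pooling until `n_null` null values
#' are collected.  The significance threshold is the empirical
#' (1 - alpha/n_tests) quantile of the null values (Bonferroni
#' correction over `n_tests` tests).
#'
#' @param expr numeric gene x sample matrix.
#' @param alpha significance level (default 0.05).
#' @param n_tests Bonferroni correction factor; defaults to the number
#'   of gene pairs choose(n, 2).
#' @param n_null number of null MI values to collect (>= 100).
#' @param seed integer seed; the result is a pure function of the
#'   arguments.
#' @return list with elements `threshold` (MI value), and `null`, an
#'   object of class `mi_null` holding `null_values`, `n_draws`, `seed`.
#'   If the requested quantile exceeds the resolution 1 - 1/n_null, the
#'   null maximum is returned with a warning.
#' @export
shuffle_null_threshold <- function(expr, alpha = 0.05, n_tests = NULL,
                                   n_null = 100000L, seed = 1L) {
  check_expr(expr, min_samples = 3L, min_genes = 2L)
  stopifnot(n_null >= 100L, alpha > 0, alpha <= 1)
  n <- nrow(expr)
  if (is.null(n_tests)) n_tests <- n * (n - 1) / 2
  stopifnot(n_tests >= 1)
  set.seed(seed)
  npairs <- n * (n - 1) / 2
  n_shuffles <- ceiling(n_null / npairs)
  pool <- vector("list", n_shuffles)
  ut <- upper.tri(matrix(0, n, n))
  for (s in seq_len(n_shuffles)) {
    perm <- matrix(sample(as.vector(expr)), n, ncol(expr))
    rho <- suppressWarnings(stats::cor(t(perm)))
    rho[is.na(rho)] <- 0
    pool[[s]] <- rho[ut]
  }
  pool <- unlist(pool)
  null_values <- rho_to_mi(if (length(pool) > n_null) sample(pool, n_null) else pool)
  q <- 1 - alpha / n_tests
  idx <- max(1L, ceiling(q * n_null))
  if (alpha / n_tests < 1 / n_null) {
    warning("requested quantile 1 - alpha/n_tests exceeds the null ",
            "resolution 1 - 1/n_null; using the null maximum")
    idx <- n_null
  }
  srt <- sort(null_values)
  list(threshold = srt[min(idx, length(srt))],
       null = structure(list(null_values = null_values,
                             n_draws = length(null_values),
                             seed = seed),
                        class = "mi_null"))
}

#' Graph of significant mutual-information pairs
#'
#' Connects every gene pair whose MI strictly exceeds the threshold.
#'
#' @param mi symmetric MI matrix with gene ids as dimnames.
#' @param threshold MI significance threshold (>= 0).
#' @return undirected igraph over all genes of `mi`.
#' @export
significant_mi_graph <- function(mi, threshold) {
  stopifnot(is.matrix(mi), threshold >= 0)
  genes <- rownames(mi)
  idx <- which(upper.tri(mi) & mi > threshold, arr.ind = TRUE)
  graph_from_edges(data.frame(from = genes[idx[, 1L]],
                              to = genes[idx[, 2L]]), genes)
}
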