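test_that("Pearson MI estimator follows -1/2 log(1 - rho^2)", {
  x <- c(1, -1, 1, -1)
  z <- c(1, 1, -1, -1)          # exactly uncorrelated with x
  y <- 0.8 * x + 0.6 * z        # sample correlation with x exactly 0.8
  m <- pearson_mi_matrix(rbind(a = x, b = y, c = z, d = x))
  expect_equal(m["a", "c"], 0)                      # rho = 0
  expect_equal(m["a", "b"], -0.5 * log(1 - 0.64))   # ~0.51083
  expect_equal(m["a", "b"], 0.5108256, tolerance = 1e-6)
  expect_identical(m["a", "d"], Inf)                # rho = 1 sentinel
  expect_identical(m, t(m))

  expect_warning(mc <- pearson_mi_matrix(rbind(a = x, k = c(2, 2, 2, 2))),
                 "constant")
  expect_equal(mc["a", "k"], 0)
})

test_that("global-shuffle null threshold is deterministic and calibrated", {
  set.seed(8)
  expr <- matrix(rnorm(50 * 100), 50,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:100)))

  t1 <- shuffle_null_threshold(expr, alpha = 0.05, n_tests = 10,
                               n_null = 10000, seed = 99)
  t2 <- shuffle_null_threshold(expr, alpha = 0.05, n_tests = 10,
                               n_null = 10000, seed = 99)
  expect_identical(t1$threshold, t2$threshold)
  expect_equal(t1$null$n_draws, 10000)

  # alpha = 1, n_tests = 1: the 0th quantile is the null minimum
  t0 <- shuffle_null_threshold(expr, alpha = 1, n_tests = 1,
                               n_null = 2000, seed = 3)
  expect_equal(t0$threshold, min(t0$null$null_values))

  # independent Monte-Carlo oracle: correlations of independent normal
  # vectors of the same length
  set.seed(123)
  r_null <- replicate(50000, stats::cor(rnorm(100), rnorm(100)))
  r_q <- stats::quantile(r_null, 0.995, names = FALSE)
  oracle <- -0.5 * log(1 - r_q^2)
  expect_equal(t1$threshold, oracle, tolerance = 0.1)

  # quantile beyond the null resolution: warn and return the maximum
  expect_warning(
    tm <- shuffle_null_threshold(expr, alpha = 0.05, n_tests = 1e6,
                                 n_null = 1000, seed = 5),
    "resolution")
  expect_equal(tm$threshold, max(tm$null$null_values))
})

test_that("C3Net candidate selection matches the row-max rule", {
  mi <- matrix(0, 3, 3, dimnames = list(c("g1", "g2", "g3"),
                                        c("g1", "g2", "g3")))
  mi["g1", "g2"] <- mi["g2", "g1"] <- 0.9
  mi["g2", "g3"] <- mi["g3", "g2"] <- 0.5
  mi["g1", "g3"] <- mi["g3", "g1"] <- 0.1
  cand <- c3net_candidates(mi)
  expect_setequal(ekey(cand$from, cand$to),
                  c(ekey("g1", "g2"), ekey("g2", "g3")))

  # tie for a row maximum goes to the lexicographically smallest
  # partner: with all MI equal, g2 and g3 both nominate g1, and g1
  # nominates g2 -- so g2-g3 is never a candidate
  tie <- matrix(0.2, 3, 3, dimnames = dimnames(mi))
  diag(tie) <- 0
  cand_tie <- c3net_candidates(tie)
  expect_setequal(ekey(cand_tie$from, cand_tie$to),
                  c(ekey("g1", "g2"), ekey("g1", "g3")))
})

test_that("candidate selection and DPI match exhaustive oracles", {
  for (case in 1:200) {
    n <- 3 + (case %% 6)
    mi <- rand_mi(n, seed = case)
    cand <- c3net_candidates(mi)
    expect_identical(sort(ekey(cand$from, cand$to)), oracle_candidates(mi))

    thr <- stats::runif(1, 0.2, 0.8)
    eps <- sample(c(0, 0.15, 0.5), 1)
    net <- significant_mi_graph(mi, thr)
    pruned <- dpi_prune(mi, net, eps)
    expect_identical(graph_keys(pruned), oracle_dpi(mi, net, eps))
  }
})

test_that("deterministic graph operations commute with gene relabeling", {
  mi <- rand_mi(7, seed = 77)
  perm <- c("g4", "g7", "g1", "g3", "g6", "g2", "g5")
  mi_p <- mi[perm, perm]
  expect_setequal(
    {c <- c3net_candidates(mi); ekey(c$from, c$to)},
    {c <- c3net_candidates(mi_p); ekey(c$from, c$to)})
  net <- significant_mi_graph(mi, 0.4)
  net_p <- significant_mi_graph(mi_p, 0.4)
  expect_setequal(graph_keys(net), graph_keys(net_p))
  expect_setequal(graph_keys(dpi_prune(mi, net, 0.15)),
                  graph_keys(dpi_prune(mi_p, net_p, 0.15)))
})

test_that("C3Net controls family-wise error on edge-free data", {
  # 20 independent-noise replicates; FWER should be ~alpha, so the
  # number of runs with any edge is Binomial(20, ~0.05): reject the
  # calibration only if > 3 runs produce an edge, and require >= 19
  # runs with at most one edge
  edges <- vapply(1:20, function(r) {
    set.seed(5000 + r)
    expr <- matrix(rnorm(30 * 100), 30,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:100)))
    igraph::gsize(c3net(expr, alpha = 0.05, n_null = 20000, seed = 6000 + r))
  }, 0)
  expect_lte(sum(edges > 0), 3)
  expect_gte(sum(edges <= 1), 19)
})

test_that("binomial consensus test retains only improbable edge counts", {
  g2 <- c("g1", "g2", "g3")
  certain <- make_consensus("g1", "g2", count = 100L, B = 100L, p0 = 0.01,
                            genes = g2)
  expect_identical(graph_keys(binomial_edge_test(certain, 0.05)),
                   ekey("g1", "g2"))  # p = 0.01^100, retained anywhere

  rare <- make_consensus("g1", "g2", count = 1L, B = 100L, p0 = 0.05,
                         genes = g2)
  # p = 1 - 0.95^100 ~ 0.994: dropped
  expect_equal(igraph::gsize(binomial_edge_test(rare, 0.05)), 0)

  empty <- make_consensus(character(0), character(0), integer(0),
                          B = 10L, p0 = 0, genes = g2)
  expect_equal(igraph::gsize(binomial_edge_test(empty, 0.05)), 0)
})

test_that("bootstrap ensemble counts and bc3net composition behave", {
  # data where inference is certain: a perfect pair plus a noise gene
  set.seed(21)
  x <- rnorm(60)
  expr <- rbind(g1 = x, g2 = x, g3 = rnorm(60))
  colnames(expr) <- paste0("s", 1:60)

  cons <- suppressWarnings(
    bootstrap_ensemble(expr, B = 20, n_null = 500, seed = 9))
  e <- cons$edges
  expect_equal(e$count[ekey(e$from, e$to) == ekey("g1", "g2")], 20)
  expect_equal(cons$B, 20)
  expect_gt(cons$p0, 0)

  # B = 1: consensus edge set equals C3Net on the single resample
  cons1 <- suppressWarnings(
    bootstrap_ensemble(expr, B = 1, n_null = 500, seed = 9))
  expect_true(all(cons1$edges$count == 1))
  expect_true(ekey("g1", "g2") %in% ekey(cons1$edges$from, cons1$edges$to))

  # strong 2-gene fixture: the true edge appears in nearly every resample
  pair <- generate_ground_truth_network(2, "chain", seed = 1)
  px <- simulate_expression(pair, 200, edge_signal = 0.9, seed = 2)
  pcons <- bootstrap_ensemble(px, B = 100, n_null = 500, seed = 3)
  expect_gte(pcons$edges$count[1], 95)

  # determinism of the full composition
  b1 <- suppressWarnings(bc3net(expr, B = 10, n_null = 500, seed = 4))
  b2 <- suppressWarnings(bc3net(expr, B = 10, n_null = 500, seed = 4))
  expect_identical(graph_keys(b1), graph_keys(b2))
})

test_that("DPI prunes the weakest edge of a triangle within tolerance", {
  genes <- c("x", "y", "z")
  mi <- matrix(0, 3, 3, dimnames = list(genes, genes))
  mi["x", "y"] <- mi["y", "x"] <- 0.5
  mi["y", "z"] <- mi["z", "y"] <- 0.4
  mi["x", "z"] <- mi["z", "x"] <- 0.1
  tri <- significant_mi_graph(mi, 0)

  pruned <- dpi_prune(mi, tri, epsilon = 0)
  expect_setequal(graph_keys(pruned), c(ekey("x", "y"), ekey("y", "z")))

  expect_identical(graph_keys(dpi_prune(mi, tri, epsilon = 1)),
                   graph_keys(tri))  # threshold collapses to 0

  path <- significant_mi_graph(mi, 0.2)  # no triangle left
  expect_identical(graph_keys(dpi_prune(mi, path, 0)), graph_keys(path))

  expect_error(dpi_prune(mi, tri, epsilon = 1.2), "epsilon")
})

test_that("ARACNE on chain data recovers the chain and drops the 2-hop edge", {
  chain <- generate_ground_truth_network(3, "chain", seed = 1)
  expr <- simulate_expression(chain, 1000, edge_signal = 0.85, seed = 13)
  g <- aracne(expr, epsilon = 0.15, n_null = 2000, seed = 14)
  expect_setequal(graph_keys(g), c(ekey("g1", "g2"), ekey("g2", "g3")))

  # the indirect pair is significantly dependent before DPI
  mi <- pearson_mi_matrix(expr)
  expect_gt(mi["g1", "g3"], g$mi_threshold)
})

test_that("ARACNE edge count is non-decreasing in the DPI tolerance", {
  for (seed in c(3, 17)) {
    mi <- rand_mi(12, seed)
    net <- significant_mi_graph(mi, 0.5)
    sizes <- vapply(c(0, 0.15, 1),
                    function(e) igraph::gsize(dpi_prune(mi, net, e)), 0)
    expect_true(all(diff(sizes) >= 0))
    expect_equal(sizes[3], igraph::gsize(net))
  }
})
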