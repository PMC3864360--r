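star4 <- igraph::make_star(5, mode = "undirected", center = 1)
igraph::V(star4)$name <- c("hub", paste0("leaf", 1:4))
triangle <- igraph::make_full_graph(3)
igraph::V(triangle)$name <- c("a", "b", "c")
path3 <- igraph::make_ring(3, circular = FALSE)
igraph::V(path3)$name <- c("g1", "g2", "g3")

test_that("centralities match hand-computed values on canonical graphs", {
  cs <- centralities(star4)
  expect_equal(cs$degree[cs$gene == "hub"], 4)
  expect_true(all(cs$degree[cs$gene != "hub"] == 1))
  expect_true(all(cs$transitivity == 0))
  expect_false(any(cs$transitivity_defined[cs$gene != "hub"]))

  ct <- centralities(triangle)
  expect_true(all(ct$degree == 2))
  expect_true(all(ct$transitivity == 1))
  expect_true(all(ct$transitivity_defined))

  cp <- centralities(path3)
  expect_equal(cp$betweenness[cp$gene == "g2"], 1)
  expect_true(all(cp$betweenness[cp$gene != "g2"] == 0))
})

test_that("global summary computes density, components and assortativity", {
  gt <- global_summary(triangle)
  expect_equal(gt$edge_density, 1)
  expect_equal(gt$global_transitivity, 1)
  expect_equal(gt$n_components, 1)
  expect_true(is.nan(gt$assortativity))  # zero degree variance

  star3 <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star3)$name <- paste0("v", 1:4)
  expect_equal(global_summary(star3)$assortativity, -1)

  two <- igraph::make_graph(~ a - b, c - d)
  gs <- global_summary(two)
  expect_equal(gs$n_components, 2)
  expect_equal(gs$gcc_size, 2)
  expect_equal(gs$edge_density, 2 / 6)

  single <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(single)$name <- "a"
  expect_error(global_summary(single), "undefined")
})

test_that("assortativity equals the edge-endpoint Pearson correlation", {
  # independent oracle: correlation over the 2M-row endpoint-degree
  # table with both orientations
  checked <- 0
  for (seed in 1:100) {
    set.seed(seed)
    g <- igraph::sample_gnp(12, 0.3)
    igraph::V(g)$name <- paste0("g", 1:12)
    if (igraph::gsize(g) < 2) next
    deg <- igraph::degree(g)
    e <- igraph::ends(g, igraph::E(g), names = TRUE)
    j <- deg[c(e[, 1], e[, 2])]
    k <- deg[c(e[, 2], e[, 1])]
    if (stats::sd(j) == 0) next
    oracle <- stats::cor(j, k)
    expect_equal(global_summary(g)$assortativity, oracle, tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("degree handshake holds on generated networks", {
  for (seed in 1:20) {
    g <- generate_ground_truth_network(40, "erdos_renyi", 3, seed = seed)
    expect_equal(sum(igraph::degree(g)), 2 * igraph::gsize(g))
  }
})

test_that("edge-overlap table reports symmetric counts, asymmetric percentages", {
  a <- igraph::make_graph(~ x - y, y - z)
  b <- igraph::make_graph(~ x - y, y - z, x - z, z - w)
  ov <- edge_overlap_table(list(A = a, B = b))
  expect_identical(ov$shared, t(ov$shared))
  expect_equal(ov$pct["A", "B"], 100)       # A is a subnetwork of B
  expect_equal(ov$pct["B", "A"], 50)
  expect_equal(diag(ov$pct), c(A = 100, B = 100))

  emptyg <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(emptyg)$name <- c("x", "y")
  ove <- edge_overlap_table(list(A = a, E = emptyg))
  expect_true(all(is.nan(ove$pct["E", ])))  # empty row flagged
})

test_that("gene ranks use the minimum-rank tie convention", {
  g <- igraph::make_graph(~ h - a, h - b, h - c, h - d, h - e,
                          a - b, a - c, a - x, x - y)
  pr <- centralities(g)
  # degrees: h=5, a=4, b=2, c=2, x=2, d=1, e=1, y=1
  expect_equal(rank_of_gene(pr, "h")$rank[1], 1)
  expect_equal(rank_of_gene(pr, "b")$rank[1],
               rank_of_gene(pr, "c")$rank[1])
  expect_equal(rank_of_gene(pr, "b")$rank[1], 3)
  expect_equal(rank_of_gene(pr, "y")$rank[1], 6)

  reg <- centralities(triangle)
  expect_true(all(vapply(c("a", "b", "c"),
                         function(v) rank_of_gene(reg, v)$rank[1], 0) == 1))
  expect_error(rank_of_gene(pr, "nope"), "unknown gene")
})

test_that("ego subnetworks are induced neighbourhoods", {
  expect_equal(igraph::vcount(ego_subnetwork(star4, "hub", 1)), 5)

  p4 <- igraph::make_ring(4, circular = FALSE)
  igraph::V(p4)$name <- paste0("g", 1:4)
  ego <- ego_subnetwork(p4, "g1", 2)
  expect_setequal(igraph::V(ego)$name, c("g1", "g2", "g3"))
  expect_equal(igraph::gsize(ego), 2)

  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("a", "b")
  expect_equal(igraph::vcount(ego_subnetwork(iso, "a", 1)), 1)

  # breadth-first oracle on a hub-and-spoke fixture
  g <- igraph::make_graph(~ MYC - n1, MYC - n2, MYC - n3, MYC - n4,
                          n1 - m1, n2 - m2, m2 - far)
  e2 <- ego_subnetwork(g, "MYC", 2)
  dist <- igraph::distances(g, v = "MYC")[1, ]
  expect_setequal(igraph::V(e2)$name, names(dist)[dist <= 2])
  expect_false("far" %in% igraph::V(e2)$name)
})

test_that("degree ranks are conserved between C3Net and BC3Net outputs", {
  fx <- make_fixture(seed = 501)
  g1 <- c3net(fx$expr, seed = 601)
  g2 <- bc3net(fx$expr, B = 20, seed = 602)
  rho <- stats::cor(igraph::degree(g1)[igraph::V(g1)$name],
                    igraph::degree(g2)[igraph::V(g1)$name],
                    method = "spearman")
  expect_gt(rho, 0)
})
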