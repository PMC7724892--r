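test_that("exact EPC reproduces hand-enumerated fixtures", {
  # two nodes, one edge, p = 0.5: each node reaches the other half the time
  pair <- igraph::make_graph(~ a - b)
  expect_equal(epcTable(epcExact(pair, 0.5))$epc, c(0.5, 0.5))
  # triangle, p = 0.5: enumeration over 8 subsets gives 10/8 = 1.25
  tri <- igraph::make_ring(3)
  expect_equal(epcTable(epcExact(tri, 0.5))$epc, rep(1.25, 3))
  # p -> 1: component size minus one; p -> 0: zero
  g <- igraph::make_graph(~ a - b, b - c, d)
  hi <- epcTable(epcExact(g, 1 - 1e-9))
  expect_equal(hi$epc[match(c("a", "b", "c", "d"), hi$gene)],
               c(2, 2, 2, 0), tolerance = 1e-6)
  lo <- epcTable(epcExact(g, 1e-9))
  expect_equal(lo$epc, rep(0, 4), tolerance = 1e-6)
  expect_error(epcExact(igraph::make_full_graph(8), 0.5), "20 edges")
})

test_that("Monte Carlo EPC is reproducible and converges to the oracle", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, c - d, d - e)
  s1 <- epcScore(g, p = 0.5, nSamples = 500, seed = 9)
  s2 <- epcScore(g, p = 0.5, nSamples = 500, seed = 9)
  expect_identical(epcTable(s1), epcTable(s2))
  ex <- epcTable(epcExact(g, 0.5))
  mc <- epcTable(s1)
  expect_true(all(abs(mc$epc - ex$epc) <= 3 * mc$se + 1e-9))
  # error shrinks roughly as 1/sqrt(n)
  mcBig <- epcTable(epcScore(g, p = 0.5, nSamples = 8000, seed = 9))
  expect_lt(mean(abs(mcBig$epc - ex$epc)), mean(abs(mc$epc - ex$epc)) + 0.02)
  expect_true(all(mcBig$se < mc$se))
  # isolated node scores zero
  gi <- igraph::make_graph(~ a - b, z)
  expect_equal(epcTable(epcScore(gi, nSamples = 50, seed = 1))$epc[3], 0)
  expect_error(epcScore(g, p = 0), "p must")
})

test_that("exact EPC is monotone under edge addition and label-invariant", {
  set.seed(30)
  for (i in 1:5) {
    nV <- sample(4:6, 1)
    pairs <- t(utils::combn(nV, 2))
    nE <- sample.int(min(8, nrow(pairs) - 1), 1)
    sel <- pairs[sample.int(nrow(pairs), nE), , drop = FALSE]
    g <- igraph::add_edges(igraph::make_empty_graph(nV, directed = FALSE),
                           t(sel))
    base <- epcTable(epcExact(g, 0.5))
    # add one absent edge: no node's EPC may decrease
    absent <- pairs[!apply(pairs, 1, function(pr)
      igraph::are_adjacent(g, pr[1], pr[2])), , drop = FALSE]
    g2 <- igraph::add_edges(g, absent[1, ])
    after <- epcTable(epcExact(g2, 0.5))
    expect_true(all(after$epc >= base$epc - 1e-12))
    # relabelling invariance
    perm <- sample(nV)
    g3 <- igraph::permute(g, perm)
    permuted <- epcTable(epcExact(g3, 0.5))
    expect_equal(sort(permuted$epc), sort(base$epc), tolerance = 1e-12)
  }
})

test_that("hub selection uses EPC with degree and id tie-breaks", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  star <- igraph::set_vertex_attr(star, "name",
                                  value = c("hub", paste0("leaf", 1:5)))
  sc <- epcExact(star, 0.5)
  out <- selectHubs(sc, star, k = 1)
  expect_equal(out$hubs, "hub")
  expect_equal(sort(igraph::V(out$subnetwork)$name),
               sort(c("hub", paste0("leaf", 1:5))))
  expect_true(igraph::V(out$subnetwork)$isHub[
    igraph::V(out$subnetwork)$name == "hub"])
  # tied scores fall back to degree then lexicographic id
  ring <- igraph::make_ring(4)
  ring <- igraph::set_vertex_attr(ring, "name", value = c("d", "b", "a", "c"))
  rsc <- epcExact(ring, 0.5)
  expect_equal(selectHubs(rsc, ring, k = 2)$hubs, c("a", "b"))
  expect_error(selectHubs(rsc, ring, k = 0), "positive")
  expect_error(selectHubs(rsc, ring, k = 9), "exceeds")
})

test_that("gene networks recover planted dependence structure", {
  # mutually independent genes: skeleton is (near-)empty
  set.seed(31)
  x <- matrix(rnorm(8 * 200), 8, 200, dimnames = list(paste0("g", 1:8), NULL))
  net <- buildGeneNetwork(x, rownames(x), nRestarts = 10, seed = 1)
  expect_lte(igraph::ecount(net), 1)
  # 10-gene chain at n = 2000: the true chain is always recovered; the
  # BIC false-positive rate adds an occasional extra edge, so the exact
  # match rate sits near 3/4
  hits <- vapply(1:20, function(i) {
    arcsM <- cbind(paste0("g", 1:9), paste0("g", 2:10))
    d <- simulateDAGData(arcsM, rep(1.5, 9), n = 2000, seed = 3100 + i)
    xm <- t(as.matrix(d))
    net <- buildGeneNetwork(xm, rownames(xm), nRestarts = 20,
                            seed = 3100 + i)
    truthEdges <- apply(arcsM, 1, function(a) paste(sort(a), collapse = "|"))
    gotEdges <- apply(igraph::as_edgelist(net), 1, function(a)
      paste(sort(a), collapse = "|"))
    c(contains = all(truthEdges %in% gotEdges),
      exact = setequal(truthEdges, gotEdges))
  }, logical(2))
  expect_gte(mean(hits["contains", ]), 0.95)
  expect_gte(mean(hits["exact", ]), 0.7)
  # keep list restricts the node set
  net2 <- buildGeneNetwork(x, rownames(x), keepGenes = paste0("g", 1:4),
                           nRestarts = 5, seed = 1, dropIsolated = FALSE)
  expect_true(all(igraph::V(net2)$name %in% paste0("g", 1:4)))
  expect_error(buildGeneNetwork(x, c("g1", "g2")), "fewer than 3")
  expect_error(buildGeneNetwork(x, c("g1", "nope", "g2", "g3")), "absent")
})
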