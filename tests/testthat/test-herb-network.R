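test_that("co-occurrence edges are exact joint counts and isolates are kept", {
  corp <- herbCorpus(list(t1 = c("A", "B"), t2 = c("A", "B"),
                          t3 = c("A", "C"), t4 = "D"))
  net <- buildCooccurrenceNetwork(corp)
  e <- edgeTable(net)
  expect_equal(nrow(e), 2L)
  expect_equal(e$weight[e$from == "A" & e$to == "B"], 2L)
  expect_equal(e$weight[e$from == "A" & e$to == "C"], 1L)
  expect_equal(isolatedHerbs(net), "D")
  expect_equal(sort(networkNodes(net)), c("A", "B", "C"))
})

test_that("edge weights agree with apriori pair counts on random corpora", {
  for (seed in c(7, 8)) {
    corp <- randomCorpus(seed, nHerbs = 15L, nTrans = 40L)
    net <- buildCooccurrenceNetwork(corp)
    cnt <- countItemsets(corp, 2)
    e <- edgeTable(net)
    for (r in seq_len(nrow(e)))
      expect_equal(e$weight[r], itemsetCount(cnt, c(e$from[r], e$to[r])))
    expect_equal(nrow(e), sum(itemsetTable(cnt)$size == 2L))
  }
})

test_that("modularity matches hand values and the naive oracle", {
  # all nodes in one module: Q = 0 at gamma = 1
  corp <- herbCorpus(list(t1 = c("A", "B"), t2 = c("B", "C"),
                          t3 = c("A", "C", "D")))
  net <- buildCooccurrenceNetwork(corp)
  one <- setNames(rep(1L, 4), c("A", "B", "C", "D"))
  expect_equal(networkModularity(net, one), 0)

  # two disjoint edges split by component: Q = 0.5
  net2 <- buildCooccurrenceNetwork(
    herbCorpus(list(p1 = c("A", "B"), p2 = c("C", "D"))))
  expect_equal(networkModularity(net2, c(A = 1, B = 1, C = 2, D = 2)),
               0.5)

  # random weighted graphs and partitions against the double-loop oracle
  for (seed in 1:4) {
    corp <- randomCorpus(seed + 50, nHerbs = 10L, nTrans = 20L)
    net <- buildCooccurrenceNetwork(corp)
    nodes <- networkNodes(net)
    for (gamma in c(0.5, 1, 2)) {
      a <- withr::with_seed(seed, setNames(
        sample.int(3L, length(nodes), replace = TRUE), nodes))
      expect_equal(networkModularity(net, a, gamma),
                   naiveModularity(edgeTable(net), a, gamma))
    }
  }
  expect_error(networkModularity(
    buildCooccurrenceNetwork(herbCorpus(list(p = "A"))), c(A = 1)),
    "no edges")
})

test_that("modularity agrees with igraph on a weighted graph", {
  corp <- randomCorpus(99, nHerbs = 12L, nTrans = 30L)
  net <- buildCooccurrenceNetwork(corp)
  g <- toIgraph(net)
  a <- setNames(rep_len(1:3, length(networkNodes(net))),
                networkNodes(net))
  expect_equal(networkModularity(net, a),
               igraph::modularity(g, a[igraph::V(g)$name],
                                  weights = igraph::E(g)$weight))
})

test_that("Louvain finds the exhaustive-search optimum on small graphs", {
  net <- buildCooccurrenceNetwork(cliqueBridgeCorpus())
  p <- louvainPartition(net, seed = 1)
  a <- moduleAssignment(p)
  # the two cliques are recovered
  expect_equal(length(unique(a[paste0("x", 1:5)])), 1L)
  expect_equal(length(unique(a[paste0("y", 1:5)])), 1L)
  expect_equal(length(moduleSizes(p)), 2L)
  expect_equal(modularityScore(p), exhaustiveBestQ(net, maxLabels = 3L))

  # uniform triangle: the single community (Q = 0) is optimal among all
  # 5 partitions of 3 nodes
  tri <- buildCooccurrenceNetwork(
    herbCorpus(list(p1 = c("A", "B", "C"))))
  pt <- louvainPartition(tri, seed = 1)
  expect_equal(length(moduleSizes(pt)), 1L)
  expect_equal(modularityScore(pt), 0)
  expect_equal(exhaustiveBestQ(tri, maxLabels = 3L), 0)
})

test_that("Louvain is deterministic given the seed and beats baselines", {
  corp <- randomCorpus(61, nHerbs = 18L, nTrans = 50L)
  net <- buildCooccurrenceNetwork(corp)
  p1 <- louvainPartition(net, seed = 5)
  p2 <- louvainPartition(net, seed = 5)
  expect_identical(moduleAssignment(p1), moduleAssignment(p2))
  expect_identical(modularityScore(p1), modularityScore(p2))

  nodes <- networkNodes(net)
  singletons <- setNames(seq_along(nodes), nodes)
  allOne <- setNames(rep(1L, length(nodes)), nodes)
  expect_gte(modularityScore(p1), networkModularity(net, singletons))
  expect_gte(modularityScore(p1), networkModularity(net, allOne))

  # Q is invariant under relabeling
  a <- moduleAssignment(p1)
  shuffled <- setNames(match(a, sample(unique(a))), names(a))
  expect_equal(networkModularity(net, shuffled, 1),
               networkModularity(net, a, 1))
  expect_equal(modularityScore(p1),
               networkModularity(net, a, 1))
})

test_that("planted modules are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:3, function(seed) {
    sim <- generateCorpus(syntheticConfig(
      nHerbs = 90, nPrescriptions = 300, nModules = 3,
      moduleSizes = c(30, 30, 30), pWithin = 0.95,
      herbsPerPrescription = c(4, 8), seed = seed))
    net <- buildCooccurrenceNetwork(sim$corpus)
    p <- louvainPartition(net, seed = seed)
    lab <- plantedModules(sim$truth)[networkNodes(net)]
    mclust::adjustedRandIndex(moduleAssignment(p)[networkNodes(net)], lab)
  }, 0)
  expect_gte(mean(aris), 0.9)
})

test_that("label canonicalization orders by size then smallest member", {
  a <- setNames(c(9L, 9L, 9L, 4L, 4L, 4L, 4L, 4L, 4L, 4L),
                c(paste0("m", 1:3), paste0("z", 1:7)))
  p <- new("ModulePartition", assignment = a, Q = 0.2, resolution = 1,
           seed = NA_integer_)
  cp <- canonicalizeLabels(p)
  ca <- moduleAssignment(cp)
  expect_equal(unname(ca[paste0("z", 1:7)]), rep(1L, 7))  # larger first
  expect_equal(unname(ca[paste0("m", 1:3)]), rep(2L, 3))
  expect_identical(moduleAssignment(canonicalizeLabels(cp)), ca)

  # equal sizes: module holding the lexicographically smallest herb wins
  b <- setNames(c(2L, 2L, 7L, 7L), c("a", "d", "b", "c"))
  cb <- moduleAssignment(canonicalizeLabels(
    new("ModulePartition", assignment = b, Q = 0, resolution = 1,
        seed = NA_integer_)))
  expect_equal(unname(cb[c("a", "d")]), c(1L, 1L))
  expect_equal(unname(cb[c("b", "c")]), c(2L, 2L))
})

test_that("graph exports carry weights and node attributes", {
  corp <- herbCorpus(list(t1 = c("A", "B"), t2 = c("A", "B"),
                          t3 = c("A", "C"), t4 = "D"))
  ann <- makeAnnotations(list(A = c("LR", "KI"), B = "ST",
                              C = character(0), D = "LU"),
                         category = c(17L, 6L, 1L, 2L))
  net <- buildCooccurrenceNetwork(corp)
  p <- louvainPartition(net, seed = 1)

  gml <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(net, gml, partition = p, annotations = ann)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  expect_equal(sum(igraph::E(g)$weight), 3)
  expect_equal(igraph::V(g)$meridians[igraph::V(g)$name == "A"], "LR|KI")

  gexf <- withr::local_tempfile(fileext = ".gexf")
  exportGEXF(net, gexf, partition = p, annotations = ann)
  txt <- readLines(gexf)
  expect_true(any(grepl("defaultedgetype=\"undirected\"", txt)))
  expect_equal(sum(grepl("<node id=", txt)), 4L)
  expect_equal(sum(grepl("<edge id=", txt)), 2L)
  expect_true(any(grepl("weight=\"2\"", txt)))
  expect_true(any(grepl("LR|KI", txt, fixed = TRUE)))
})
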