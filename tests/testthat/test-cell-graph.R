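test_that("pathway activity is the detected fraction of pathway genes", {
  m <- matrix(0, 2, 20, dimnames = list(c("c1", "c2"), sprintf("g%02d", 1:20)))
  m["c1", 1:3] <- 1
  m["c2", ] <- 1
  am <- pathwayActivity(makeBinary(m), list(P1 = colnames(m)))
  expect_equal(am["c1", "P1"], 0.15)
  expect_equal(am["c2", "P1"], 1)
  m0 <- matrix(0, 1, 20, dimnames = list("c1", sprintf("g%02d", 1:20)))
  expect_equal(unname(pathwayActivity(makeBinary(m0),
                                      list(P1 = colnames(m0)))[1, 1]), 0)
  expect_error(pathwayActivity(makeBinary(m), list(P1 = "nope")), "nope")
})

test_that("activity times pathway size recovers an integer detection count", {
  set.seed(2)
  m <- (matrix(runif(30 * 40), 30) < 0.3) * 1
  bm <- makeBinary(m)
  pws <- list(A = geneIds(bm)[1:17], B = geneIds(bm)[18:40])
  am <- pathwayActivity(bm, pws)
  expect_true(all(am >= 0 & am <= 1))
  counts <- sweep(am, 2, lengths(pws), "*")
  expect_equal(counts, round(counts))
})

test_that("union kNN on collinear points connects through the middle", {
  am <- matrix(c(0, 1, 10), ncol = 1,
               dimnames = list(c("a", "b", "c"), "P1"))
  g <- buildCellKnnGraph(am, k = 1)
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(el, c("a-b", "b-c"))  # c's nearest is b (union rule)
})

test_that("identical cells give a deterministic connected graph, one community", {
  am <- matrix(0.5, 6, 2, dimnames = list(sprintf("c%d", 1:6), c("P1", "P2")))
  g <- buildCellKnnGraph(am, k = 2)
  # ties broken by cell index: every cell picks the first cells, so the
  # graph is connected and identical across repeated calls
  expect_equal(igraph::count_components(g), 1)
  g2 <- buildCellKnnGraph(am, k = 2)
  expect_equal(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  expect_true(all(igraph::E(g)$weight > 0))
  out <- detectCellClusters(g, seed = 1)
  expect_true(isCoocSignal(out))
  expect_equal(out$reason, "one_community")
  # a genuinely complete neighbourhood structure keeps unit weights
  am3 <- matrix(0.5, 3, 1, dimnames = list(c("a", "b", "c"), "P1"))
  g3 <- buildCellKnnGraph(am3, k = 2)
  expect_equal(igraph::ecount(g3), 3)
  expect_true(all(igraph::E(g3)$weight == 1))
})

test_that("every node has degree at least k under the union rule", {
  set.seed(8)
  am <- matrix(runif(60 * 3), 60,
               dimnames = list(sprintf("c%02d", 1:60), NULL))
  g <- buildCellKnnGraph(am, k = 5)
  expect_true(all(igraph::degree(g) >= 5))
})

test_that("too few cells signals instead of building a graph", {
  am <- matrix(runif(4), 4, 1, dimnames = list(letters[1:4], "P1"))
  out <- buildCellKnnGraph(am, k = 5)
  expect_true(isCoocSignal(out))
  expect_equal(out$reason, "too_few_cells")
})

test_that("two well-separated blobs give two components and a clean split", {
  fix <- twoBlobActivity(nPerBlob = 50, centers = c(0.9, 0.1), sigma = 0.01,
                         seed = 4)
  g <- buildCellKnnGraph(fix$am, k = 5)
  expect_equal(igraph::count_components(g), 2)
  part <- detectCellClusters(g, seed = 4)
  expect_false(isCoocSignal(part))
  # communities never straddle the two components...
  for (k in unique(part))
    expect_length(unique(fix$blobs[part == k]), 1)
  # ...and after tiny/prominence merging the blobs are recovered exactly
  part <- mergeTinyClusters(part, fix$am)
  part <- mergeByProminence(part, fix$am)
  expect_equal(randIndex(part, fix$blobs), 1)
})

test_that("two disconnected components map to two clusters", {
  am <- matrix(c(rep(0, 12), rep(1, 12)), ncol = 1,
               dimnames = list(sprintf("c%02d", 1:24), "P1"))
  g <- buildCellKnnGraph(am, k = 3)
  part <- detectCellClusters(g, seed = 1)
  expect_equal(max(part), 2)
  expect_equal(length(unique(part[1:12])), 1)
  expect_equal(length(unique(part[13:24])), 1)
})

test_that("a tiny cluster is absorbed into its only large neighbour", {
  am <- matrix(c(rep(0.8, 12), rep(0.78, 3)), ncol = 1,
               dimnames = list(sprintf("c%02d", 1:15), "P1"))
  labels <- setNames(c(rep(1L, 12), rep(2L, 3)), rownames(am))
  out <- mergeTinyClusters(labels, am, minClusterSize = 10)
  expect_equal(max(out), 1)
  expect_equal(length(out), 15)
})

test_that("a tiny cluster joins the nearest non-tiny centroid", {
  am <- matrix(c(rep(0.9, 30), rep(0.1, 30), rep(0.8, 4)), ncol = 1,
               dimnames = list(sprintf("c%02d", 1:64), "P1"))
  labels <- setNames(rep(1:3, c(30, 30, 4)), rownames(am))
  out <- mergeTinyClusters(labels, am, minClusterSize = 10)
  expect_equal(max(out), 2)
  expect_equal(unique(out[61:64]), out[[1]])   # joined the 0.9 cluster
  # labels of cells in non-tiny clusters never change (up to renumbering)
  expect_equal(length(unique(out[1:30])), 1)
  expect_equal(length(unique(out[31:60])), 1)
  expect_false(out[[1]] == out[[31]])
})

test_that("all-tiny partitions raise the all_tiny signal", {
  am <- matrix(runif(9), 9, 1, dimnames = list(letters[1:9], "P1"))
  labels <- setNames(rep(1:2, c(5, 4)), rownames(am))
  out <- mergeTinyClusters(labels, am, minClusterSize = 10)
  expect_true(isCoocSignal(out))
  expect_equal(out$reason, "all_tiny")
})

test_that("two populations split by one pathway are separated end to end", {
  # detection probability contrast of 0.5 on a single planted module
  okSeeds <- 0
  for (s in 1:10) {
    m <- plantedModel(nCells = c(A = 60L, B = 60L),
                      moduleSizes = c(M1 = 30L),
                      detection = matrix(c(0.7, 0.2), 1), p0 = 0.3,
                      nBackground = 100L)
    sim <- simulateBinary(m, seed = s)
    pw <- list(P1 = sim$geneModules$M1)
    am <- pathwayActivity(sim$bm, pw)
    g <- buildCellKnnGraph(am, k = 5)
    part <- detectCellClusters(g, seed = s)
    if (isCoocSignal(part)) next
    part <- mergeTinyClusters(part, am)
    if (isCoocSignal(part)) next
    part <- mergeByProminence(part, am)
    if (isCoocSignal(part)) next
    ari <- adjustedRandIndex(part, sim$cellLabels[names(part)])
    okSeeds <- okSeeds + (ari >= 0.95)
  }
  expect_gte(okSeeds, 9)
})
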