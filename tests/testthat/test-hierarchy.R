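test_that("unstructured data stays a single leaf", {
  bm <- simulateNull(80, 150, p = 0.35, seed = 3)
  tree <- coocCluster(bm, coocParams(seed = 3))
  expect_length(leafNodes(tree), 1)
  root <- treeNodes(tree)[[1]]
  expect_true(root$termination %in%
    c("no_pathways", "one_community", "all_tiny", "merged_to_one"))
  expect_equal(unname(assignCells(tree)), rep(1L, 80))
})

test_that("planted hierarchical structure is recovered", {
  sim <- simulateBinary(plantedPreset("hierarchical"), seed = 3)
  tree <- coocCluster(sim$bm, coocParams(seed = 3))
  lab <- assignCells(tree)
  # leaves partition the root cells
  leafSets <- lapply(treeNodes(tree)[leafNodes(tree) + 1L],
                     function(nd) nd$cellIds)
  expect_equal(anyDuplicated(unlist(leafSets)), 0)
  expect_setequal(unlist(leafSets), cellIds(sim$bm))
  # the planted three types dominate the leaf partition
  ari <- adjustedRandIndex(lab, sim$cellLabels[names(lab)])
  expect_gte(ari, 0.8)
  expect_gte(length(leafNodes(tree)), 3)
  # the major A/B split is found at the root
  expect_gte(length(treeNodes(tree)[[1]]$children), 2)
})

test_that("a run is deterministic given the seed", {
  sim <- simulateBinary(plantedPreset("two-type"), seed = 5)
  t1 <- coocCluster(sim$bm, coocParams(seed = 11))
  t2 <- coocCluster(sim$bm, coocParams(seed = 11))
  expect_equal(treeNodes(t1), treeNodes(t2))
  expect_equal(assignCells(t1), assignCells(t2))
})

test_that("pathway sizes shrink as the hierarchy deepens", {
  sim <- simulateBinary(plantedPreset("hierarchical"), seed = 3)
  tree <- coocCluster(sim$bm, coocParams(seed = 3))
  nodes <- treeNodes(tree)
  maxAtDepth <- tapply(
    vapply(nodes, function(nd)
      if (length(nd$pathways)) max(lengths(nd$pathways)) else NA_integer_,
      numeric(1)),
    vapply(nodes, function(nd) nd$depth, integer(1)),
    max, na.rm = TRUE)
  if (length(maxAtDepth) >= 2)
    expect_true(all(diff(maxAtDepth) <= 0))
})

test_that("cells dropped by a node's filter still reach exactly one leaf", {
  sim <- simulateBinary(plantedPreset("two-type"), seed = 7)
  v <- as.matrix(binValues(sim$bm))
  # cripple one cell: detections only on 5 background genes
  v["T1_c001", ] <- 0
  v["T1_c001", grep("^BG", colnames(v))[1:5]] <- 1
  bm <- BinaryMatrix(v)
  f <- filterMatrix(bm)
  expect_false("T1_c001" %in% cellIds(f))   # the filter drops it
  tree <- coocCluster(bm, coocParams(seed = 7))
  lab <- assignCells(tree)
  expect_equal(sum(names(lab) == "T1_c001"), 1)
  expect_true(lab[["T1_c001"]] >= 1)
  # totality: every cell has exactly one label
  expect_setequal(names(lab), rownames(v))
})

test_that("single-leaf trees label every cell identically", {
  bm <- simulateNull(40, 80, p = 0.5, seed = 1)
  tree <- coocCluster(bm, coocParams(seed = 1))
  expect_length(unique(assignCells(tree)), 1)
})

test_that("node records are consistent: BFS ids, parents, reasons", {
  sim <- simulateBinary(plantedPreset("hierarchical"), seed = 3)
  tree <- coocCluster(sim$bm, coocParams(seed = 3))
  nodes <- treeNodes(tree)
  ids <- vapply(nodes, function(nd) nd$id, integer(1))
  expect_equal(ids, seq_along(nodes) - 1L)
  for (nd in nodes) {
    if (length(nd$children)) {
      expect_equal(nd$termination, "none")
      for (k in nd$children)
        expect_equal(nodes[[k + 1L]]$parent, nd$id)
    } else {
      expect_true(nd$termination != "none")
    }
  }
})

test_that("the exported tree JSON is stable and complete", {
  sim <- simulateBinary(plantedPreset("two-type"), seed = 5)
  tree <- coocCluster(sim$bm, coocParams(seed = 5))
  f <- tempfile(fileext = ".json")
  exportTreeJSON(tree, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$schema_version, 1L)
  expect_equal(parsed$n_cells, 400L)
  expect_length(parsed$nodes, length(treeNodes(tree)))
  expect_equal(parsed$params$knnK, 5L)
  term <- vapply(parsed$nodes, function(x) x$termination, character(1))
  expect_true(all(nchar(term) > 0))
})

test_that("recursion guards convert small or deep nodes into leaves", {
  sim <- simulateBinary(plantedPreset("two-type"), seed = 9)
  tree <- coocCluster(sim$bm, coocParams(seed = 9, maxDepth = 0))
  expect_length(treeNodes(tree), 1)
  expect_equal(treeNodes(tree)[[1]]$termination, "max_depth")
  bmTiny <- sim$bm[1:15, ]
  treeTiny <- coocCluster(bmTiny, coocParams(seed = 9, minNodeSize = 20))
  expect_equal(treeNodes(treeTiny)[[1]]$termination, "too_few_cells")
})
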