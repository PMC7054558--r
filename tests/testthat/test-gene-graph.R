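test_that("chi-square score matches hand-computed contingency examples", {
  expect_equal(chiSquareScore(10, 0, 0, 10), 1)
  expect_equal(chiSquareScore(5, 5, 5, 5), 0)
  expect_equal(chiSquareScore(0, 10, 10, 0), -1)
  expect_equal(chiSquareScore(5, 1, 2, 12), 3364 / 7644)
  expect_error(chiSquareScore(-1, 0, 0, 1), "non-negative")
})

test_that("zero marginals give score 0 instead of dividing by zero", {
  expect_equal(chiSquareScore(10, 0, 5, 0), 0)  # gene 2 detected everywhere
  expect_equal(chiSquareScore(0, 0, 0, 20), 0)  # gene 1 detected nowhere
  expect_equal(chiSquareScore(0, 0, 0, 0), 0)
})

test_that("score is symmetric in the genes and flips under complement", {
  # swapping the two genes exchanges B and C
  for (abc in list(c(7, 3, 1, 9), c(2, 8, 5, 5), c(0, 4, 4, 12))) {
    expect_equal(chiSquareScore(abc[1], abc[2], abc[3], abc[4]),
                 chiSquareScore(abc[1], abc[3], abc[2], abc[4]))
  }
  # complementing one gene turns perfect co-occurrence into exclusion
  expect_equal(chiSquareScore(10, 0, 0, 10),
               -chiSquareScore(0, 10, 10, 0))
})

test_that("pairwise scores equal brute-force contingency counting", {
  set.seed(11)
  m <- (matrix(runif(50 * 8), 50) < 0.4) * 1
  bm <- makeBinary(m)
  expect_equal(pairwiseScores(bm), bruteScores(binValues(bm)))
  # identical columns score +1, complementary columns -1
  m2 <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), d = c(0, 0, 1, 1))
  S <- pairwiseScores(makeBinary(m2, genes = colnames(m2)))
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "d"], -1)
})

test_that("threshold rule: mean plus sd of scores under the best random", {
  out <- scoreThreshold(c(0.1, 0.2, 0.3, 0.9), bestRandom = 0.5)
  expect_equal(out$threshold, 0.3)  # mean 0.2 + sample sd 0.1
  expect_equal(out$nBelow, 3L)
  # population-sd convention is switchable
  out2 <- scoreThreshold(c(0.1, 0.2, 0.3, 0.9), 0.5, sampleSd = FALSE)
  expect_equal(out2$threshold, 0.2 + 0.1 * sqrt(2 / 3))
})

test_that("gene permutation preserves each gene's detection count", {
  set.seed(3)
  m <- (matrix(runif(40 * 15), 40) < 0.3) * 1
  X <- binValues(makeBinary(m))
  for (i in 1:5) {
    Xp <- coocclust:::.permuteGenes(X)
    expect_equal(Matrix::colSums(Xp), Matrix::colSums(X))
    expect_equal(dim(Xp), dim(X))
    expect_true(all(Xp@x == 1))
  }
})

test_that("permutation-invariant input yields a degenerate threshold", {
  allOn <- makeBinary(matrix(1, 30, 10))
  out <- permutationThreshold(allOn, seed = 1)
  expect_true(isCoocSignal(out))
  expect_equal(out$reason, "degenerate_threshold")
})

test_that("threshold separates planted within-module from background pairs", {
  fix <- twoModuleMatrix(nPerGroup = 150, moduleSize = 30, pHigh = 0.9,
                         pLow = 0.05, seed = 5)
  thr <- permutationThreshold(fix$bm, seed = 5)
  expect_false(isCoocSignal(thr))
  S <- pairwiseScores(fix$bm)
  within1 <- S[fix$modules$M1, fix$modules$M1]
  within2 <- S[fix$modules$M2, fix$modules$M2]
  w <- c(within1[upper.tri(within1)], within2[upper.tri(within2)])
  cross <- S[fix$modules$M1, fix$modules$M2]
  expect_gt(mean(w > thr$threshold), 0.95)
  # mutually exclusive cross-module pairs never become graph edges
  expect_true(all(cross < 0))
  g <- buildGeneGraph(S, thr$threshold)
  adj <- igraph::as_adjacency_matrix(g)
  expect_equal(sum(adj[fix$modules$M1, fix$modules$M2]), 0)
})

test_that("Jaccard weighting uses closed neighbourhoods", {
  # two genes connected only to each other keep weight 1
  S <- matrix(0, 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
  S["u", "v"] <- S["v", "u"] <- 0.9
  g <- buildGeneGraph(S, threshold = 0.5)
  expect_equal(igraph::E(g)$weight, 1)
  # closed neighbourhoods {u,v,x,y} and {u,v,x,z}: 3 common of 5 -> 0.6
  genes <- c("u", "v", "x", "y", "z")
  S2 <- matrix(0, 5, 5, dimnames = list(genes, genes))
  edge <- function(a, b) S2[a, b] <<- S2[b, a] <<- 0.9
  edge("u", "v"); edge("u", "x"); edge("u", "y"); edge("v", "x"); edge("v", "z")
  g2 <- buildGeneGraph(S2, threshold = 0.5)
  e <- igraph::get_edge_ids(g2, c("u", "v"))
  expect_equal(igraph::E(g2)$weight[e], 0.6)
})

test_that("a threshold above every score signals an empty gene graph", {
  S <- bruteScores(matrix(c(1, 0, 1, 0, 1, 1, 0, 0, 1), 3))
  out <- buildGeneGraph(S, threshold = 2)
  expect_true(isCoocSignal(out))
  expect_equal(out$reason, "no_gene_graph")
})

test_that("disconnected cliques become pathways, filtered by size", {
  cliqueScores <- function(sizes) {
    p <- sum(sizes)
    S <- matrix(0, p, p)
    off <- 0
    for (s in sizes) { S[off + 1:s, off + 1:s] <- 0.9; off <- off + s }
    diag(S) <- 0
    dimnames(S) <- list(sprintf("g%02d", 1:p), sprintf("g%02d", 1:p))
    S
  }
  g <- buildGeneGraph(cliqueScores(c(25, 25)), threshold = 0.5)
  pw <- detectGenePathways(g, minPathwaySize = 20, seed = 1)
  expect_length(pw, 2)
  expect_equal(sort(unname(lengths(pw))), c(25L, 25L))
  expect_length(intersect(pw[[1]], pw[[2]]), 0)
  g2 <- buildGeneGraph(cliqueScores(c(25, 15)), threshold = 0.5)
  pw2 <- detectGenePathways(g2, minPathwaySize = 20, seed = 1)
  expect_length(pw2, 1)
  expect_length(pw2[[1]], 25)
  # all communities below the size threshold -> everything discarded
  pw3 <- detectGenePathways(g2, minPathwaySize = 30, seed = 1)
  expect_length(pw3, 0)
})

test_that("planted modules are recovered as pathways", {
  fix <- twoModuleMatrix(nPerGroup = 150, moduleSize = 30, pHigh = 0.9,
                         pLow = 0.05, seed = 5)
  thr <- permutationThreshold(fix$bm, seed = 5)
  g <- buildGeneGraph(pairwiseScores(fix$bm), thr$threshold)
  pw <- detectGenePathways(g, minPathwaySize = 20, seed = 5)
  expect_length(pw, 2)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  best <- sapply(fix$modules, function(mod)
    max(sapply(pw, jac, b = mod)))
  expect_true(all(best >= 0.9))
})

test_that("pathways at a node are disjoint and respect the size floor", {
  fix <- twoModuleMatrix(nPerGroup = 100, moduleSize = 25, nBackground = 40,
                         seed = 9)
  thr <- permutationThreshold(fix$bm, seed = 9)
  g <- buildGeneGraph(pairwiseScores(fix$bm), thr$threshold)
  pw <- detectGenePathways(g, minPathwaySize = 20, seed = 9)
  expect_true(all(lengths(pw) >= 20))
  expect_equal(anyDuplicated(unlist(pw)), 0)
})
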