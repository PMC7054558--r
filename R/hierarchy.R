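# per-node RNG seed derived from the run seed; kept below 2^31 - 1
.nodeSeed <- function(seed, nodeId, offset = 0L) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(nodeId) + offset) %%
               2147483647)
}

# run the full single-node pipeline on the node's submatrix.
# Returns list(children = list of cell-id vectors, pathways = named list)
# or list(termination = <reason>, pathways = named list discovered so far).
.processNode <- function(bm, params, nodeId) {
  p <- params
  if (nCells(bm) < p@minNodeSize || nCells(bm) <= p@knnK)
    return(list(termination = "too_few_cells", pathways = list()))

  f <- filterMatrix(bm, p@minCellsPerGene, p@minGenesPerCell,
                    iterate = p@iterateFilter)
  if (isCoocSignal(f))
    return(list(termination = "too_few_cells", pathways = list()))
  if (nGenes(f) < 2 || nCells(f) <= p@knnK)
    return(list(termination = "too_few_cells", pathways = list()))

  thr <- permutationThreshold(f, nPerm = p@nPerm,
                              seed = .nodeSeed(p@seed, nodeId),
                              sampleSd = p@sampleSd)
  if (isCoocSignal(thr))
    return(list(termination = "no_pathways", pathways = list()))
  g <- buildGeneGraph(pairwiseScores(f), thr$threshold)
  pathways <- detectGenePathways(g, minPathwaySize = p@minPathwaySize,
                                 seed = .nodeSeed(p@seed, nodeId, 1L))
  if (!length(pathways))
    return(list(termination = "no_pathways", pathways = list()))

  amF <- pathwayActivity(f, pathways)
  cg <- buildCellKnnGraph(amF, k = p@knnK, union = p@unionKnn)
  if (isCoocSignal(cg))
    return(list(termination = "too_few_cells", pathways = pathways))
  part <- detectCellClusters(cg, seed = .nodeSeed(p@seed, nodeId, 2L))
  if (isCoocSignal(part))
    return(list(termination = "one_community", pathways = pathways))
  part <- mergeTinyClusters(part, amF, minClusterSize = p@tinyCluster)
  if (isCoocSignal(part))
    return(list(termination = "all_tiny", pathways = pathways))
  if (max(part) == 1L)
    return(list(termination = "one_community", pathways = pathways))
  part <- mergeByProminence(part, amF, snrThr = p@snrThr,
                            diffThr = p@diffThr, ratioThr = p@ratioThr)
  if (isCoocSignal(part))
    return(list(termination = "merged_to_one", pathways = pathways))

  children <- split(names(part), part)
  # cells dropped by the per-node filter still need a child
  dropped <- setdiff(cellIds(bm), cellIds(f))
  if (length(dropped)) {
    if (p@assignFiltered == "centroid") {
      amAll <- pathwayActivity(bm, pathways)
      cen <- .clusterCentroids(amF, part)
      for (cid in dropped) {
        d2 <- rowSums(sweep(cen, 2, amAll[cid, ])^2)
        k <- as.integer(rownames(cen))[which.min(d2)]
        children[[as.character(k)]] <- c(children[[as.character(k)]], cid)
      }
    } else {
      return(list(children = unname(children), pathways = pathways,
                  unassigned = dropped))
    }
  }
  list(children = unname(children), pathways = pathways)
}

#' Divisive co-occurrence clustering of a dropout pattern
#'
#' Runs the full iterative algorithm. Starting from a root node holding all
#' cells, each node is processed by the per-node pipeline: detection
#' filtering of genes and cells; pairwise signed chi-square co-occurrence
#' scores; a permutation-derived edge threshold; Louvain communities of the
#' Jaccard-weighted gene graph ("gene pathways", minimum size 20); the
#' pathway-activity embedding; Louvain communities of the Jaccard-weighted
#' kNN cell graph; absorption of tiny clusters; and merging of cluster
#' pairs without a prominently differential pathway. Nodes whose pipeline
#' yields at least two surviving clusters are split into children and the
#' children are processed in turn (breadth-first); all other nodes become
#' leaves with a recorded termination reason. The leaves are the reported
#' cell types.
#'
#' Cells removed by a node's detection filter remain members of the node;
#' when the node subdivides they are assigned to the child with the nearest
#' pathway-activity centroid (see \code{\linkS4class{CoocParams}}).
#'
#' Every random choice (permutations, Louvain) draws from a stream derived
#' from \code{params@seed} and the node id, so a run is fully reproducible.
#'
#' @param bm a \code{\linkS4class{BinaryMatrix}} (typically
#'   \code{binarizeCounts(readCounts(...))}).
#' @param params a \code{\linkS4class{CoocParams}}; see
#'   \code{\link{coocParams}}.
#' @return a \code{\linkS4class{CoocTree}}.
#' @examples
#' bm <- simulateNull(60, 120, p = 0.4, seed = 1)
#' tree <- coocCluster(bm, coocParams(seed = 1))
#' table(assignCells(tree))
#' @export
coocCluster <- function(bm, params = coocParams()) {
  stopifnot(is(bm, "BinaryMatrix"))
  if (nCells(bm) == 0 || nGenes(bm) == 0)
    stop("cannot cluster an empty matrix")
  nodes <- list()
  queue <- list(list(id = 0L, parent = NA_integer_, depth = 0L,
                     cellIds = cellIds(bm)))
  nextId <- 1L
  while (length(queue)) {
    nd <- queue[[1]]; queue <- queue[-1]
    sub <- bm[nd$cellIds, ]
    res <- if (nd$depth >= params@maxDepth)
      list(termination = "max_depth", pathways = list())
    else .processNode(sub, params, nd$id)
    node <- list(id = nd$id, parent = nd$parent, depth = nd$depth,
                 cellIds = nd$cellIds, pathways = res$pathways,
                 children = integer(), termination = "none")
    if (is.null(res$children)) {
      node$termination <- res$termination
    } else {
      kidIds <- integer(length(res$children))
      for (j in seq_along(res$children)) {
        kidIds[j] <- nextId
        queue[[length(queue) + 1L]] <- list(
          id = nextId, parent = nd$id, depth = nd$depth + 1L,
          cellIds = res$children[[j]])
        nextId <- nextId + 1L
      }
      node$children <- kidIds
      if (!is.null(res$unassigned)) node$unassigned <- res$unassigned
    }
    nodes[[nd$id + 1L]] <- node
  }
  new("CoocTree", nodes = nodes, params = params, cellIds = cellIds(bm))
}

#' Export a clustering hierarchy as JSON
#'
#' Writes the tree in a stable, versioned schema: a top-level object with
#' \code{schema_version} (currently 1), \code{n_cells}, \code{params} and a
#' \code{nodes} array, each node carrying \code{id}, \code{parent},
#' \code{depth}, \code{n_cells}, \code{cell_ids}, \code{children},
#' \code{termination} and the per-node pathway gene lists.
#'
#' @param tree a \code{\linkS4class{CoocTree}}.
#' @param path output file; created or overwritten.
#' @param cellIds include per-node cell id lists (default \code{TRUE}; can
#'   be large).
#' @return \code{path}, invisibly.
#' @export
exportTreeJSON <- function(tree, path, cellIds = TRUE) {
  p <- tree@params
  params <- list(
    minCellsPerGene = p@minCellsPerGene, minGenesPerCell = p@minGenesPerCell,
    nPerm = p@nPerm, minPathwaySize = p@minPathwaySize, knnK = p@knnK,
    tinyCluster = p@tinyCluster, snrThr = p@snrThr, diffThr = p@diffThr,
    ratioThr = p@ratioThr, seed = p@seed)
  nodes <- lapply(tree@nodes, function(nd) {
    out <- list(id = nd$id, parent = nd$parent, depth = nd$depth,
                n_cells = length(nd$cellIds), children = I(nd$children),
                termination = nd$termination,
                pathways = lapply(nd$pathways, I))
    if (cellIds) out$cell_ids <- I(nd$cellIds)
    out
  })
  jsonlite::write_json(
    list(schema_version = 1L, n_cells = length(tree@cellIds),
         params = params, nodes = nodes),
    path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}
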