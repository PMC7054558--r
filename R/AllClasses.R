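#' @import methods
#' @importFrom Matrix colSums rowSums t crossprod
NULL

setClassUnion("integerOrNA", c("integer", "logical"))

#' Binary dropout-pattern matrix
#'
#' The central data object: a sparse cells x genes 0/1 matrix recording, for
#' every cell and gene, whether the gene was detected (count > 0) in that
#' cell. This "dropout pattern" is the only input the co-occurrence
#' clustering algorithm consumes; quantitative expression is discarded at
#' binarization and never recovered.
#'
#' @slot values a \code{\link[Matrix]{dgCMatrix-class}} with entries in
#'   \{0, 1\}; rows are cells, columns are genes, and dimnames carry the cell
#'   barcodes and gene identifiers.
#' @slot provenance a list describing how this matrix was derived from a
#'   parent matrix (e.g. the cell and gene indices retained by
#'   \code{\link{filterMatrix}}); empty for a freshly binarized matrix.
#'
#' @seealso \code{\link{binarizeCounts}}, \code{\link{filterMatrix}}
#' @exportClass BinaryMatrix
setClass("BinaryMatrix",
  slots = c(values = "dgCMatrix", provenance = "list"))

setValidity("BinaryMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (length(v@x) && (any(v@x != 1)))
    msgs <- c(msgs, "entries must be 0 or 1")
  dn <- dimnames(v)
  if (is.null(dn[[1]]) || is.null(dn[[2]]))
    msgs <- c(msgs, "cell and gene identifiers (dimnames) are required")
  else {
    if (anyDuplicated(dn[[1]])) msgs <- c(msgs, "duplicated cell identifiers")
    if (anyDuplicated(dn[[2]])) msgs <- c(msgs, "duplicated gene identifiers")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a BinaryMatrix
#'
#' Low-level constructor; most users obtain a \code{BinaryMatrix} from
#' \code{\link{binarizeCounts}} or \code{\link{simulateBinary}}.
#'
#' @param values a cells x genes matrix (dense or sparse) with entries in
#'   \{0, 1\}.
#' @param cellIds,geneIds optional identifier vectors; taken from
#'   \code{dimnames(values)} when missing.
#' @param provenance optional list recording the subset lineage.
#' @return a \code{\linkS4class{BinaryMatrix}}.
#' @export
BinaryMatrix <- function(values, cellIds = NULL, geneIds = NULL,
                         provenance = list()) {
  m <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  m <- Matrix::drop0(m)
  if (length(m@x) && any(m@x < 0))
    stop("binary matrix cannot contain negative entries")
  if (!is.null(cellIds)) rownames(m) <- cellIds
  if (!is.null(geneIds)) colnames(m) <- geneIds
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("cell%d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("gene%d", seq_len(ncol(m)))
  new("BinaryMatrix", values = m, provenance = provenance)
}

#' Run parameters for co-occurrence clustering
#'
#' Holds every tunable threshold of the algorithm. The defaults are the
#' values used throughout the original analyses: detection filters of 10
#' cells per gene and 10 genes per cell, 10 permutations for the gene-graph
#' edge threshold, a minimum gene-pathway size of 20, k = 5 nearest
#' neighbours for the cell graph, a tiny-cluster threshold of 10 cells, and
#' prominence thresholds of 1.5 (SNR), 0.5 (mean difference) and 2 (mean
#' ratio).
#'
#' @slot minCellsPerGene,minGenesPerCell detection filters applied at every
#'   hierarchy node.
#' @slot nPerm number of per-gene reshuffled datasets for the edge threshold.
#' @slot minPathwaySize gene communities smaller than this are discarded.
#' @slot knnK neighbourhood size of the cell k-nearest-neighbour graph.
#' @slot tinyCluster cell communities smaller than this are absorbed into
#'   the nearest non-tiny cluster.
#' @slot snrThr,diffThr,ratioThr prominence thresholds for cluster merging.
#' @slot seed master random seed; every per-node RNG stream derives from it.
#' @slot iterateFilter iterate the gene/cell filter to a fixed point
#'   (\code{TRUE}, default) or apply a single gene-then-cell pass.
#' @slot unionKnn use the union rule when symmetrising the kNN graph
#'   (default) rather than mutual kNN.
#' @slot sampleSd use the sample (n - 1) standard deviation in the
#'   permutation threshold (default) rather than the population one.
#' @slot maxDepth,minNodeSize recursion guards; nodes at \code{maxDepth} or
#'   with fewer than \code{minNodeSize} cells become leaves.
#' @slot assignFiltered \code{"centroid"} (default) assigns cells dropped by
#'   a node's filter to the child with the nearest pathway-activity
#'   centroid; \code{"unassigned"} leaves them at the node.
#' @seealso \code{\link{coocParams}}, \code{\link{coocCluster}}
#' @exportClass CoocParams
setClass("CoocParams",
  slots = c(
    minCellsPerGene = "integer", minGenesPerCell = "integer",
    nPerm = "integer", minPathwaySize = "integer",
    knnK = "integer", tinyCluster = "integer",
    snrThr = "numeric", diffThr = "numeric", ratioThr = "numeric",
    seed = "integer", iterateFilter = "logical", unionKnn = "logical",
    sampleSd = "logical", maxDepth = "numeric", minNodeSize = "integer",
    assignFiltered = "character"))

setValidity("CoocParams", function(object) {
  msgs <- character()
  for (s in c("minCellsPerGene", "minGenesPerCell", "nPerm",
              "minPathwaySize", "knnK", "tinyCluster", "snrThr",
              "diffThr", "ratioThr", "minNodeSize"))
    if (slot(object, s) < 0)
      msgs <- c(msgs, sprintf("'%s' must be >= 0", s))
  if (object@nPerm < 1) msgs <- c(msgs, "'nPerm' must be >= 1")
  if (object@knnK < 1) msgs <- c(msgs, "'knnK' must be >= 1")
  if (!object@assignFiltered %in% c("centroid", "unassigned"))
    msgs <- c(msgs, "'assignFiltered' must be \"centroid\" or \"unassigned\"")
  if (length(msgs)) msgs else TRUE
})

#' Create a parameter set
#'
#' @param minCellsPerGene,minGenesPerCell,nPerm,minPathwaySize,knnK,tinyCluster
#'   integer thresholds; see \code{\linkS4class{CoocParams}}.
#' @param snrThr,diffThr,ratioThr prominence thresholds (strict inequalities).
#' @param seed master random seed.
#' @param iterateFilter,unionKnn,sampleSd algorithmic switches.
#' @param maxDepth maximum hierarchy depth (\code{Inf} = unlimited).
#' @param minNodeSize smallest node that is still examined for subdivision;
#'   defaults to twice the tiny-cluster threshold.
#' @param assignFiltered how per-node filtered-out cells receive leaf labels.
#' @return a \code{\linkS4class{CoocParams}} object.
#' @examples
#' coocParams(seed = 1)
#' @export
coocParams <- function(minCellsPerGene = 10, minGenesPerCell = 10,
                       nPerm = 10, minPathwaySize = 20, knnK = 5,
                       tinyCluster = 10, snrThr = 1.5, diffThr = 0.5,
                       ratioThr = 2, seed = 0, iterateFilter = TRUE,
                       unionKnn = TRUE, sampleSd = TRUE, maxDepth = Inf,
                       minNodeSize = 2 * tinyCluster,
                       assignFiltered = c("centroid", "unassigned")) {
  new("CoocParams",
      minCellsPerGene = as.integer(minCellsPerGene),
      minGenesPerCell = as.integer(minGenesPerCell),
      nPerm = as.integer(nPerm), minPathwaySize = as.integer(minPathwaySize),
      knnK = as.integer(knnK), tinyCluster = as.integer(tinyCluster),
      snrThr = as.numeric(snrThr), diffThr = as.numeric(diffThr),
      ratioThr = as.numeric(ratioThr), seed = as.integer(seed),
      iterateFilter = isTRUE(iterateFilter), unionKnn = isTRUE(unionKnn),
      sampleSd = isTRUE(sampleSd), maxDepth = as.numeric(maxDepth),
      minNodeSize = as.integer(minNodeSize),
      assignFiltered = match.arg(assignFiltered))
}

#' Divisive co-occurrence clustering hierarchy
#'
#' Result of \code{\link{coocCluster}}: a tree whose root contains every
#' cell, whose internal nodes record the gene pathways that split them, and
#' whose leaves are the reported cell types. Nodes are numbered in
#' breadth-first creation order starting at 0 (the root).
#'
#' Each element of \code{nodes} is a list with entries \code{id},
#' \code{parent}, \code{depth}, \code{cellIds}, \code{pathways} (named list
#' of gene-id vectors discovered at the node), \code{children} (integer node
#' ids) and \code{termination} (one of \code{"none"} for internal nodes, or
#' \code{"no_pathways"}, \code{"one_community"}, \code{"all_tiny"},
#' \code{"merged_to_one"}, \code{"too_few_cells"}, \code{"max_depth"} for
#' leaves).
#'
#' @slot nodes list of node records (see Details).
#' @slot params the \code{\linkS4class{CoocParams}} used for the run.
#' @slot cellIds cell identifiers of the root.
#' @seealso \code{\link{assignCells}}, \code{\link{leafNodes}},
#'   \code{\link{genePathways}}
#' @exportClass CoocTree
setClass("CoocTree",
  slots = c(nodes = "list", params = "CoocParams", cellIds = "character"))

setValidity("CoocTree", function(object) {
  if (!length(object@nodes)) return("tree must contain at least a root node")
  root <- object@nodes[[1]]
  if (!setequal(root$cellIds, object@cellIds))
    return("root node must contain every cell")
  for (nd in object@nodes) {
    if (length(nd$children)) {
      kids <- c(unlist(lapply(object@nodes[nd$children + 1L],
                              function(x) x$cellIds)), nd$unassigned)
      if (!setequal(kids, nd$cellIds) || anyDuplicated(kids))
        return(sprintf("children of node %d do not partition it", nd$id))
      if (!identical(nd$termination, "none"))
        return(sprintf("internal node %d carries a termination reason", nd$id))
    } else if (identical(nd$termination, "none")) {
      return(sprintf("leaf node %d lacks a termination reason", nd$id))
    }
  }
  TRUE
})

#' Planted binary dropout model
#'
#' Generative model for synthetic dropout patterns: cells belong to planted
#' types, genes belong to disjoint modules (plus a background pool), and
#' entry (c, g) is Bernoulli with probability
#' \code{clip(d_c * P[module(g), type(c)], 0, 1)}, where \code{d_c} is a
#' per-cell log-normal depth factor (optionally scaled per type) and
#' background genes use the flat rate \code{p0}.
#'
#' @slot nCells named integer, cells per planted type.
#' @slot moduleSizes named integer, genes per module (may be empty).
#' @slot detection modules x types matrix of detection probabilities.
#' @slot p0 background detection rate.
#' @slot nBackground number of background genes.
#' @slot depthSigma standard deviation (log scale) of the per-cell depth
#'   factor; 0 disables depth variation.
#' @slot depthFactor named numeric, a fixed per-type multiplier on the depth
#'   factor (models low-coverage subpopulations).
#' @seealso \code{\link{plantedModel}}, \code{\link{simulateBinary}}
#' @exportClass PlantedModel
setClass("PlantedModel",
  slots = c(nCells = "integer", moduleSizes = "integer",
            detection = "matrix", p0 = "numeric", nBackground = "integer",
            depthSigma = "numeric", depthFactor = "numeric"))

setValidity("PlantedModel", function(object) {
  msgs <- character()
  if (!length(object@nCells) || any(object@nCells < 1))
    msgs <- c(msgs, "each type needs at least one cell")
  if (length(object@moduleSizes) &&
      (nrow(object@detection) != length(object@moduleSizes) ||
       ncol(object@detection) != length(object@nCells)))
    msgs <- c(msgs, "'detection' must be modules x types")
  if (any(object@detection < 0) || any(object@detection > 1))
    msgs <- c(msgs, "detection probabilities must lie in [0, 1]")
  if (object@p0 < 0 || object@p0 > 1)
    msgs <- c(msgs, "'p0' must lie in [0, 1]")
  if (object@nBackground < 0) msgs <- c(msgs, "'nBackground' must be >= 0")
  if (object@depthSigma < 0) msgs <- c(msgs, "'depthSigma' must be >= 0")
  if (length(object@depthFactor) != length(object@nCells) ||
      any(object@depthFactor < 0))
    msgs <- c(msgs, "'depthFactor' must be one non-negative value per type")
  if (length(msgs)) msgs else TRUE
})
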