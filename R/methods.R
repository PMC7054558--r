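#' @rdname BinaryMatrix-class
setMethod("cellIds", "BinaryMatrix", function(x) rownames(x@values))

#' @rdname BinaryMatrix-class
setMethod("geneIds", "BinaryMatrix", function(x) colnames(x@values))

#' @rdname BinaryMatrix-class
setMethod("nCells", "BinaryMatrix", function(x) nrow(x@values))

#' @rdname BinaryMatrix-class
setMethod("nGenes", "BinaryMatrix", function(x) ncol(x@values))

#' @rdname BinaryMatrix-class
setMethod("binValues", "BinaryMatrix", function(x) x@values)

#' @rdname BinaryMatrix-class
setMethod("provenance", "BinaryMatrix", function(x) x@provenance)

setMethod("dim", "BinaryMatrix", function(x) dim(x@values))

#' @rdname BinaryMatrix-class
#' @param i,j cell and gene indices (integer, logical or character).
#' @param drop ignored; subsetting always returns a \code{BinaryMatrix}.
#' @param ... ignored.
setMethod("[", "BinaryMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nCells(x))
  if (missing(j)) j <- seq_len(nGenes(x))
  new("BinaryMatrix", values = x@values[i, j, drop = FALSE],
      provenance = list(parentCells = cellIds(x)[seq_len(nCells(x))][i],
                        parentGenes = geneIds(x)[seq_len(nGenes(x))][j]))
})

setMethod("show", "BinaryMatrix", function(object) {
  v <- object@values
  cat(sprintf("BinaryMatrix: %d cells x %d genes (%.2f%% zeros)\n",
              nrow(v), ncol(v), 100 * (1 - length(v@x) / prod(dim(v)))))
  invisible(NULL)
})

setMethod("show", "CoocParams", function(object) {
  cat("CoocParams\n")
  cat(sprintf("  filters: >=%d cells/gene, >=%d genes/cell\n",
              object@minCellsPerGene, object@minGenesPerCell))
  cat(sprintf("  gene graph: %d permutations, min pathway size %d\n",
              object@nPerm, object@minPathwaySize))
  cat(sprintf("  cell graph: k = %d, tiny cluster < %d\n",
              object@knnK, object@tinyCluster))
  cat(sprintf("  prominence: SNR > %g and (diff > %g or ratio > %g)\n",
              object@snrThr, object@diffThr, object@ratioThr))
  cat(sprintf("  seed: %d\n", object@seed))
  invisible(NULL)
})

#' @rdname CoocTree-class
#' @param x,object a \code{CoocTree}.
setMethod("treeNodes", "CoocTree", function(x) x@nodes)

setMethod("leafNodes", "CoocTree", function(x) {
  ids <- vapply(x@nodes, function(nd) nd$id, integer(1))
  ids[vapply(x@nodes, function(nd) length(nd$children) == 0L, logical(1))]
})

setMethod("genePathways", "CoocTree", function(x) {
  out <- list()
  for (nd in x@nodes) {
    if (!length(nd$pathways)) next
    pw <- nd$pathways
    names(pw) <- sprintf("node%d.%s", nd$id, names(pw))
    out <- c(out, pw)
  }
  out
})

setMethod("assignCells", "CoocTree", function(x) {
  leaves <- leafNodes(x)
  labels <- integer(length(x@cellIds))
  names(labels) <- x@cellIds
  for (k in seq_along(leaves)) {
    nd <- x@nodes[[leaves[k] + 1L]]
    labels[nd$cellIds] <- k
  }
  labels
})

setMethod("show", "CoocTree", function(object) {
  leaves <- leafNodes(object)
  cat(sprintf("CoocTree: %d cells, %d nodes, %d leaf cell types\n",
              length(object@cellIds), length(object@nodes), length(leaves)))
  npw <- length(genePathways(object))
  cat(sprintf("  gene pathways discovered: %d\n", npw))
  for (nd in object@nodes) {
    pad <- strrep("  ", nd$depth + 1L)
    tail <- if (length(nd$children))
      sprintf("-> children %s", paste(nd$children, collapse = ","))
    else sprintf("[leaf: %s]", nd$termination)
    cat(sprintf("%snode %d (%d cells, %d pathways) %s\n",
                pad, nd$id, length(nd$cellIds), length(nd$pathways), tail))
  }
  invisible(NULL)
})

setMethod("show", "PlantedModel", function(object) {
  cat(sprintf("PlantedModel: %d types (%s cells), %d modules, %d background genes @ p0 = %g\n",
              length(object@nCells), paste(object@nCells, collapse = "+"),
              length(object@moduleSizes), object@nBackground, object@p0))
  invisible(NULL)
})
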