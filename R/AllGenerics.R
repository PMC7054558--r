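#' @rdname BinaryMatrix-class
#' @param object,x a \code{\linkS4class{BinaryMatrix}}.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname BinaryMatrix-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname BinaryMatrix-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname BinaryMatrix-class
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname BinaryMatrix-class
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @rdname BinaryMatrix-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname CoocTree-class
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' Leaf nodes of a clustering hierarchy
#'
#' @param x a \code{\linkS4class{CoocTree}}.
#' @return integer vector of leaf node ids, in creation (BFS) order.
#' @export
setGeneric("leafNodes", function(x) standardGeneric("leafNodes"))

#' Gene pathways discovered across a hierarchy
#'
#' @param x a \code{\linkS4class{CoocTree}}.
#' @return named list of gene-id vectors; names are
#'   \code{"node<id>.P<j>"}.
#' @export
setGeneric("genePathways", function(x) standardGeneric("genePathways"))

#' Final cell-type labels from a hierarchy
#'
#' Maps every root cell to the single leaf that contains it. Leaves are
#' labelled 1..L in creation order.
#'
#' @param x a \code{\linkS4class{CoocTree}}.
#' @return named integer vector (names are cell ids).
#' @export
setGeneric("assignCells", function(x) standardGeneric("assignCells"))
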