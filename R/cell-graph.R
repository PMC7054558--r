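#' Pathway activity: percentage of detected pathway genes per cell
#'
#' For each gene pathway, the fraction of its genes detected in each cell.
#' These fractions form the low-dimensional "pathway activity" embedding of
#' the cells (one dimension per pathway) on which the cell-cell graph is
#' built.
#'
#' @param bm a \code{\linkS4class{BinaryMatrix}}.
#' @param pathways named list of gene-id vectors; every gene must be present
#'   in \code{bm}.
#' @return numeric cells x pathways matrix with entries in \code{[0, 1]};
#'   rownames are cell ids, colnames pathway names.
#' @export
pathwayActivity <- function(bm, pathways) {
  stopifnot(is(bm, "BinaryMatrix"), is.list(pathways), length(pathways) > 0)
  X <- binValues(bm)
  missing <- setdiff(unique(unlist(pathways)), colnames(X))
  if (length(missing))
    stop(sprintf("pathway gene(s) absent from matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  am <- vapply(pathways, function(genes)
    as.numeric(Matrix::rowSums(X[, genes, drop = FALSE])) / length(genes),
    numeric(nrow(X)))
  if (nrow(X) == 1L) am <- matrix(am, nrow = 1L)
  dimnames(am) <- list(rownames(X), names(pathways))
  am
}

#' k-nearest-neighbour cell graph with Jaccard weights
#'
#' Connects cells by Euclidean distance in pathway-activity space: an edge
#' is drawn when either cell is among the other's k nearest neighbours
#' (union rule; self excluded), then each edge is weighted by the Jaccard
#' index of the two cells' closed neighbourhoods in the unweighted kNN
#' graph, exactly as for the gene graph. Distance ties are broken by cell
#' index order, so identical cells yield a deterministic graph.
#'
#' @param am activity matrix from \code{\link{pathwayActivity}}.
#' @param k neighbourhood size (default 5).
#' @param union use the union rule (default); \code{FALSE} gives mutual kNN.
#' @return a weighted undirected \code{\link[igraph]{igraph}} on the cells,
#'   or a \code{\link{coocSignal}} with reason \code{"too_few_cells"} when
#'   the matrix has no more than \code{k} cells.
#' @export
buildCellKnnGraph <- function(am, k = 5, union = TRUE) {
  stopifnot(is.matrix(am), k >= 1)
  n <- nrow(am)
  if (n <= k) return(coocSignal("too_few_cells"))
  D <- as.matrix(stats::dist(am))
  adj <- matrix(FALSE, n, n)
  idx <- seq_len(n)
  for (i in idx) {
    d <- D[i, ]
    d[i] <- Inf
    nn <- order(d, idx)[seq_len(k)]   # stable tie-break by cell index
    adj[i, nn] <- TRUE
  }
  adj <- if (union) adj | t(adj) else adj & t(adj)
  dimnames(adj) <- list(rownames(am), rownames(am))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  .jaccardWeight(g)
}

#' Detect cell clusters by community detection
#'
#' Louvain community detection on the weighted cell-cell graph.
#'
#' @param g weighted cell graph from \code{\link{buildCellKnnGraph}}.
#' @param seed RNG seed.
#' @return named integer vector of cluster labels (1..K, names are cell
#'   ids), or a \code{\link{coocSignal}} with reason \code{"one_community"}
#'   when only one community is found (the hierarchy node then ends).
#' @export
detectCellClusters <- function(g, seed = 0) {
  if (isCoocSignal(g)) return(g)
  stopifnot(igraph::is_igraph(g), igraph::vcount(g) > 0)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  labels <- as.integer(igraph::membership(cl))
  names(labels) <- igraph::V(g)$name
  labels <- .compactLabels(labels)
  if (max(labels) == 1L)
    return(coocSignal("one_community", partition = labels))
  labels
}

# renumber labels to 1..K preserving order of first appearance
.compactLabels <- function(labels) {
  out <- match(labels, unique(labels))
  names(out) <- names(labels)
  out
}

# centroid (mean activity vector) of each cluster, clusters x pathways
.clusterCentroids <- function(am, labels) {
  ks <- sort(unique(labels))
  cen <- vapply(ks, function(k)
    colMeans(am[labels == k, , drop = FALSE]), numeric(ncol(am)))
  cen <- t(matrix(cen, nrow = ncol(am)))  # robust to a single pathway
  dimnames(cen) <- list(ks, colnames(am))
  cen
}

#' Absorb tiny cell clusters
#'
#' Clusters smaller than \code{minClusterSize} (default 10) are tiny; each
#' is reassigned wholesale to the non-tiny cluster whose activity centroid
#' is nearest in Euclidean distance. Tiny clusters are processed
#' largest-first and non-tiny centroids are fixed during the pass, so tiny
#' clusters cannot attract one another and the result does not depend on
#' processing order. Labels of cells in non-tiny clusters never change.
#'
#' @param labels named integer partition from
#'   \code{\link{detectCellClusters}}.
#' @param am activity matrix aligned with \code{labels} (same cells, same
#'   order).
#' @param minClusterSize tiny-cluster threshold (default 10).
#' @return compacted partition in which every cluster has at least
#'   \code{minClusterSize} cells, or a \code{\link{coocSignal}} with reason
#'   \code{"all_tiny"} when no cluster reaches the threshold.
#' @export
mergeTinyClusters <- function(labels, am, minClusterSize = 10) {
  stopifnot(is.matrix(am), length(labels) == nrow(am))
  sizes <- table(labels)
  tiny <- as.integer(names(sizes)[sizes < minClusterSize])
  if (length(tiny) == length(sizes))
    return(coocSignal("all_tiny"))
  if (length(tiny)) {
    big <- as.integer(names(sizes)[sizes >= minClusterSize])
    cen <- .clusterCentroids(am, labels)[as.character(big), , drop = FALSE]
    tiny <- tiny[order(-sizes[as.character(tiny)], tiny)]
    for (tk in tiny) {
      tc <- colMeans(am[labels == tk, , drop = FALSE])
      d2 <- rowSums(sweep(cen, 2, tc)^2)
      labels[labels == tk] <- big[which.min(d2)]
    }
  }
  .compactLabels(labels)
}
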