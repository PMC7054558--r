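#' Signed chi-square co-occurrence score for one gene pair
#'
#' For two binarized genes, with \code{A} cells detecting both, \code{B}
#' detecting only the first, \code{C} only the second and \code{D} neither,
#' the score is
#' \deqn{sign(AD - BC) (AD - BC)^2 / ((A+B)(A+C)(B+D)(C+D)).}
#' Positive values indicate co-detection, negative values mutual exclusion,
#' and the score is bounded in \code{[-1, 1]}. Note the statistic deliberately
#' omits the total-cell factor N of the classical Pearson chi-square, so it
#' is a scale-free association ratio rather than a test statistic.
#'
#' When any marginal \code{(A+B)}, \code{(A+C)}, \code{(B+D)} or \code{(C+D)}
#' is zero one of the genes is detected in all cells or in none; such a gene
#' cannot co-vary and the score is defined as 0.
#'
#' @param A,B,C,D non-negative contingency counts (vectorized).
#' @return numeric score(s) in \code{[-1, 1]}.
#' @examples
#' chiSquareScore(10, 0, 0, 10)  #  1: perfect co-occurrence
#' chiSquareScore(0, 10, 10, 0)  # -1: perfect mutual exclusion
#' chiSquareScore(5, 5, 5, 5)    #  0: independence
#' @export
chiSquareScore <- function(A, B, C, D) {
  if (any(A < 0) || any(B < 0) || any(C < 0) || any(D < 0))
    stop("contingency counts must be non-negative")
  A <- as.numeric(A); B <- as.numeric(B)
  C <- as.numeric(C); D <- as.numeric(D)
  num <- A * D - B * C
  den <- (A + B) * (A + C) * (B + D) * (C + D)
  out <- ifelse(den == 0, 0, sign(num) * num^2 / den)
  out
}

# score matrix from a raw 0/1 dgCMatrix (cells x genes); diagonal set to 0
.scoreMatrix <- function(X) {
  N <- nrow(X)
  A <- as.matrix(Matrix::crossprod(X))      # |both detected|
  ng <- Matrix::colSums(X)
  # B[i, j] = cells detecting gene i only = ng[i] - A[i, j]
  B <- matrix(ng, nrow = length(ng), ncol = length(ng)) - A
  C <- t(B)
  D <- N - A - B - C
  num <- A * D - B * C
  den <- (A + B) * (A + C) * (B + D) * (C + D)
  S <- ifelse(den == 0, 0, sign(num) * num^2 / den)
  diag(S) <- 0
  dimnames(S) <- list(colnames(X), colnames(X))
  S
}

#' All pairwise gene co-occurrence scores
#'
#' Computes \code{\link{chiSquareScore}} for every gene pair of a binary
#' matrix. The contingency counts are obtained from the cross-product of the
#' sparse matrix with itself (A), the per-gene detection totals (B, C) and
#' the cell count (D), which agrees entrywise with brute-force per-pair
#' counting.
#'
#' @param bm a \code{\linkS4class{BinaryMatrix}} with at least two genes.
#' @return a symmetric genes x genes numeric matrix of signed scores with a
#'   zero diagonal (the diagonal is meaningless and excluded downstream).
#' @export
pairwiseScores <- function(bm) {
  stopifnot(is(bm, "BinaryMatrix"))
  if (nGenes(bm) < 2) stop("need at least two genes")
  .scoreMatrix(binValues(bm))
}

# upper-triangle values (i < j) of a square matrix
.upperTri <- function(S) S[upper.tri(S)]

# reshuffle each gene's detections across cells independently,
# preserving per-gene detection counts
.permuteGenes <- function(X) {
  n <- nrow(X)
  d <- diff(X@p)
  newi <- integer(length(X@x))
  pos <- 0L
  for (k in seq_along(d)) {
    if (d[k] > 0L) {
      newi[(pos + 1L):(pos + d[k])] <- sort.int(sample.int(n, d[k])) - 1L
      pos <- pos + d[k]
    }
  }
  methods::new("dgCMatrix", i = newi, p = X@p, x = rep(1, length(X@x)),
               Dim = X@Dim, Dimnames = X@Dimnames)
}

#' Permutation-derived edge threshold for the gene graph
#'
#' Builds \code{nPerm} randomized datasets by reshuffling each gene's
#' detections across cells independently (per-gene detection counts are
#' preserved), and records the highest pairwise score observed in any of
#' them (\code{bestRandom}). Among the real-data scores strictly below
#' \code{bestRandom}, the threshold is their mean plus one standard
#' deviation (sample, n - 1, by default).
#'
#' @param bm a filtered \code{\linkS4class{BinaryMatrix}}.
#' @param nPerm number of permuted datasets (default 10).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param sampleSd use the sample standard deviation (default) rather than
#'   the population one.
#' @return a list with elements \code{threshold}, \code{bestRandom} and
#'   \code{nBelow} (number of real scores under \code{bestRandom}), or a
#'   \code{\link{coocSignal}} with reason \code{"degenerate_threshold"} when
#'   fewer than two real scores fall below the best random score (e.g. on
#'   permutation-invariant input); the caller then treats the node as having
#'   no pathways.
#' @export
permutationThreshold <- function(bm, nPerm = 10, seed = 0, sampleSd = TRUE) {
  stopifnot(is(bm, "BinaryMatrix"), nPerm >= 1)
  X <- binValues(bm)
  if (ncol(X) < 2) return(coocSignal("degenerate_threshold"))
  set.seed(seed)
  bestRandom <- -Inf
  for (i in seq_len(nPerm)) {
    Sp <- .scoreMatrix(.permuteGenes(X))
    bestRandom <- max(bestRandom, max(.upperTri(Sp)))
  }
  real <- .upperTri(.scoreMatrix(X))
  scoreThreshold(real, bestRandom, sampleSd = sampleSd)
}

#' Threshold rule given real scores and the best random score
#'
#' The rule underlying \code{\link{permutationThreshold}}, exposed for
#' direct use: among the real scores strictly below \code{bestRandom}, the
#' threshold is their mean plus one standard deviation.
#'
#' @param scores numeric vector of real-data pairwise scores (each pair
#'   once).
#' @param bestRandom the highest score observed in the permuted datasets.
#' @param sampleSd sample (n - 1) or population standard deviation.
#' @return as \code{\link{permutationThreshold}}.
#' @examples
#' scoreThreshold(c(0.1, 0.2, 0.3, 0.9), bestRandom = 0.5)$threshold  # 0.3
#' @export
scoreThreshold <- function(scores, bestRandom, sampleSd = TRUE) {
  eligible <- scores[scores < bestRandom]
  if (length(eligible) < 2)
    return(coocSignal("degenerate_threshold", bestRandom = bestRandom))
  s <- stats::sd(eligible)
  if (!sampleSd)
    s <- s * sqrt((length(eligible) - 1) / length(eligible))
  list(threshold = mean(eligible) + s, bestRandom = bestRandom,
       nBelow = length(eligible))
}

# Jaccard similarity of closed neighbourhoods for every edge of an
# unweighted igraph; returns the graph with an edge 'weight' attribute,
# zero-weight edges removed. Closed neighbourhoods (node included) keep a
# two-node component at weight 1 instead of deleting it.
.jaccardWeight <- function(g) {
  M <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  Matrix::diag(M) <- 1
  common <- M %*% M                       # |N[u] closed-cap N[v]|
  deg <- Matrix::rowSums(M)
  el <- igraph::as_edgelist(g, names = FALSE)
  cm <- common[el]
  w <- cm / (deg[el[, 1]] + deg[el[, 2]] - cm)
  igraph::E(g)$weight <- as.numeric(w)
  igraph::delete_edges(g, which(igraph::E(g)$weight == 0))
}

#' Build the Jaccard-weighted gene-gene graph
#'
#' Draws an unweighted edge between every gene pair whose signed score is
#' positive and strictly exceeds the threshold; mutual-exclusion (negative)
#' pairs never create edges, since pathways are sets of significantly
#' co-detected genes. Each surviving edge is then weighted by the Jaccard
#' index of the two genes' closed neighbourhoods in the unweighted graph.
#'
#' @param scores symmetric score matrix from \code{\link{pairwiseScores}}.
#' @param threshold finite score threshold, typically
#'   \code{permutationThreshold(bm)$threshold}.
#' @return a weighted undirected \code{\link[igraph]{igraph}} whose vertices
#'   are all genes (isolated genes retained), or a \code{\link{coocSignal}}
#'   with reason \code{"no_gene_graph"} when no pair passes the threshold.
#' @export
buildGeneGraph <- function(scores, threshold) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores),
            is.finite(threshold))
  # only positive (co-detection) associations create edges: pathways are
  # sets of significantly co-detected genes, so mutual-exclusion pairs are
  # excluded even when the permutation threshold comes out negative
  adj <- scores > threshold & scores > 0
  diag(adj) <- FALSE
  if (!any(adj)) return(coocSignal("no_gene_graph"))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  .jaccardWeight(g)
}

#' Detect gene pathways by community detection
#'
#' Runs Louvain community detection (weighted modularity, resolution 1) on
#' the Jaccard-weighted gene graph. Isolated genes are ignored. Communities
#' smaller than \code{minPathwaySize} are discarded; if every community is
#' below the size threshold the result is empty and the hierarchy node ends
#' without dividing.
#'
#' @param g weighted gene graph from \code{\link{buildGeneGraph}}.
#' @param minPathwaySize minimum community size to keep (default 20).
#' @param seed RNG seed for the (randomized) Louvain algorithm.
#' @return named list of gene-id vectors (\code{P1}, \code{P2}, ... ordered
#'   by decreasing size); possibly empty.
#' @export
detectGenePathways <- function(g, minPathwaySize = 20, seed = 0) {
  if (isCoocSignal(g)) return(list())
  stopifnot(igraph::is_igraph(g))
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (igraph::vcount(g) == 0) return(list())
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  comms <- split(igraph::V(g)$name, igraph::membership(cl))
  comms <- comms[lengths(comms) >= minPathwaySize]
  if (!length(comms)) return(list())
  comms <- comms[order(-lengths(comms),
                       vapply(comms, `[`, character(1), 1L))]
  names(comms) <- sprintf("P%d", seq_along(comms))
  comms
}
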