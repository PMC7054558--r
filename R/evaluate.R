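#' Rand index between two partitions
#'
#' The fraction of cell pairs on which two partitions agree: pairs placed
#' together in both or apart in both. 1 means identical partitions (up to
#' label permutation).
#'
#' @param a,b label vectors over the same cells, in the same order.
#' @return numeric in \code{[0, 1]}.
#' @seealso \code{\link{adjustedRandIndex}}
#' @examples
#' randIndex(c(1, 1, 2, 2), c(1, 1, 1, 2))  # 0.5
#' @export
randIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (anyNA(a) || anyNA(b)) stop("labels must not contain NA")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  suma <- sum(choose(rowSums(tab), 2))
  sumb <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  (tot + 2 * sumij - suma - sumb) / tot
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected Rand index: 0 expected for random
#' partitions, 1 for identical ones.
#'
#' @inheritParams randIndex
#' @return numeric, at most 1.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (anyNA(a) || anyNA(b)) stop("labels must not contain NA")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  suma <- sum(choose(rowSums(tab), 2))
  sumb <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- suma * sumb / tot
  maxidx <- (suma + sumb) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

#' One-sided hypergeometric enrichment p-value
#'
#' Probability of observing at least the actual overlap between a gene
#' pathway and a reference gene set, when \code{length(pathway)} genes are
#' drawn from the universe without replacement. Unadjusted by default,
#' matching the convention of reporting raw enrichment p-values per
#' pathway-term pair.
#'
#' @param pathway,term character vectors of gene ids, both subsets of
#'   \code{universe}.
#' @param universe character vector defining the gene universe (e.g. all
#'   genes surviving the root detection filter).
#' @return one-sided p-value \eqn{P(X \ge |pathway \cap term|)}.
#' @examples
#' u <- paste0("g", 1:10)
#' hypergeometricEnrichment(u[1:5], u[1:4], u)  # 6/252
#' @export
hypergeometricEnrichment <- function(pathway, term, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  pathway <- unique(pathway); term <- unique(term)
  if (length(setdiff(pathway, universe)))
    stop("pathway contains genes outside the universe")
  if (length(setdiff(term, universe)))
    stop("term contains genes outside the universe")
  q <- length(intersect(pathway, term))
  stats::phyper(q - 1, m = length(term),
                n = length(universe) - length(term),
                k = length(pathway), lower.tail = FALSE)
}

#' Enrichment table for a pathway collection
#'
#' Tests every pathway against every reference gene set with
#' \code{\link{hypergeometricEnrichment}}. Reference genes outside the
#' universe are dropped before testing.
#'
#' @param pathways named list of gene-id vectors (e.g.
#'   \code{\link{genePathways}} output).
#' @param sets named list of reference gene sets (e.g. \code{\link{readGMT}}
#'   output).
#' @param universe gene universe; defaults to the union of all pathway
#'   genes.
#' @param adjust apply Benjamini-Hochberg adjustment across all tests
#'   (off by default; raw p-values are the reported convention).
#' @return data frame with columns \code{pathway}, \code{set},
#'   \code{overlap}, \code{pathwaySize}, \code{setSize}, \code{p} and, when
#'   \code{adjust} is \code{TRUE}, \code{padj}.
#' @export
enrichPathways <- function(pathways, sets, universe = NULL, adjust = FALSE) {
  if (is.null(universe)) universe <- unique(unlist(pathways))
  grid <- expand.grid(pathway = names(pathways), set = names(sets),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    pw <- intersect(pathways[[grid$pathway[r]]], universe)
    tm <- intersect(sets[[grid$set[r]]], universe)
    data.frame(pathway = grid$pathway[r], set = grid$set[r],
               overlap = length(intersect(pw, tm)),
               pathwaySize = length(pw), setSize = length(tm),
               p = hypergeometricEnrichment(pw, tm, universe))
  })
  out <- do.call(rbind, rows)
  if (adjust) out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Mean pathway activity per cluster
#'
#' Summarises an activity matrix by cluster: entry (k, p) is the mean
#' activity of pathway p over the cells of cluster k. Used to compare
#' pathway behaviour across groups (e.g. tissue types) or datasets.
#'
#' @param am activity matrix (cells x pathways).
#' @param labels cluster labels aligned with the rows of \code{am}.
#' @return clusters x pathways numeric matrix; rownames are cluster labels.
#' @export
pathwayActivitySummary <- function(am, labels) {
  stopifnot(is.matrix(am), length(labels) == nrow(am))
  if (anyNA(labels)) stop("labels must not contain NA")
  ks <- sort(unique(labels))
  out <- vapply(ks, function(k)
    colMeans(am[labels == k, , drop = FALSE]), numeric(ncol(am)))
  out <- t(matrix(out, nrow = ncol(am)))  # robust to a single pathway
  dimnames(out) <- list(as.character(ks), colnames(am))
  out
}
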