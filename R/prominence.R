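#' Per-pathway prominence metrics for a cluster pair
#'
#' For two cell clusters and each gene pathway, three descriptive metrics of
#' the pathway's percentage of detection: the absolute difference of the
#' cluster means, the ratio of the larger to the smaller mean, and the
#' signal-to-noise ratio (mean difference divided by the sum of the two
#' within-cluster standard deviations).
#'
#' Degenerate cases: with both standard deviations zero the SNR is
#' \code{Inf} when the means differ and 0 when they agree; with the smaller
#' mean zero the ratio is \code{Inf} when the other mean is positive and 1
#' when both are zero (zero activity against an active pathway is maximal
#' contrast). A cluster of a single cell contributes a standard deviation of
#' 0.
#'
#' @param am activity matrix (cells x pathways).
#' @param labels partition aligned with the rows of \code{am}.
#' @param c1,c2 the two cluster labels to compare.
#' @return data frame with one row per pathway and columns \code{pathway},
#'   \code{meanDiff}, \code{meanRatio}, \code{snr}.
#' @export
clusterProminence <- function(am, labels, c1, c2) {
  stopifnot(is.matrix(am), length(labels) == nrow(am))
  a1 <- am[labels == c1, , drop = FALSE]
  a2 <- am[labels == c2, , drop = FALSE]
  if (!nrow(a1) || !nrow(a2)) stop("empty cluster")
  mu1 <- colMeans(a1); mu2 <- colMeans(a2)
  sd1 <- apply(a1, 2, stats::sd); sd2 <- apply(a2, 2, stats::sd)
  sd1[is.na(sd1)] <- 0; sd2[is.na(sd2)] <- 0
  .prominenceMetrics(mu1, mu2, sd1, sd2,
                     colnames(am) %||% sprintf("P%d", seq_along(mu1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.prominenceMetrics <- function(mu1, mu2, sd1, sd2, pathway) {
  diff <- abs(mu1 - mu2)
  lo <- pmin(mu1, mu2); hi <- pmax(mu1, mu2)
  ratio <- ifelse(lo == 0, ifelse(hi > 0, Inf, 1), hi / lo)
  s <- sd1 + sd2
  snr <- ifelse(s == 0, ifelse(diff > 0, Inf, 0), diff / s)
  data.frame(pathway = pathway, meanDiff = diff, meanRatio = ratio,
             snr = snr, row.names = NULL)
}

#' Are two clusters prominently different?
#'
#' Two clusters are prominently different when (1) the maximum SNR over the
#' gene pathways exceeds \code{snrThr} and (2) either the maximum mean
#' difference exceeds \code{diffThr} or the maximum mean ratio exceeds
#' \code{ratioThr}. All inequalities are strict; the defaults 1.5, 0.5 and 2
#' are the values used for every dataset in the original analyses.
#'
#' @param metrics data frame from \code{\link{clusterProminence}}.
#' @param snrThr,diffThr,ratioThr prominence thresholds.
#' @return logical scalar.
#' @export
pairProminent <- function(metrics, snrThr = 1.5, diffThr = 0.5,
                          ratioThr = 2) {
  stopifnot(nrow(metrics) >= 1)
  max(metrics$snr) > snrThr &&
    (max(metrics$meanDiff) > diffThr || max(metrics$meanRatio) > ratioThr)
}

#' Merge cell clusters lacking a prominently differential pathway
#'
#' Repeatedly merges the pair of clusters that is not prominently different
#' (see \code{\link{pairProminent}}) with the smallest maximum-pathway SNR,
#' recomputing the metrics after every merge, until every remaining pair is
#' prominently different in at least one pathway. The weakest-separated
#' pair is merged first so the procedure is deterministic; ties fall back
#' to the smallest cluster labels. A single-pass variant that merges all
#' non-prominent pairs of the initial partition at once is available via
#' \code{singlePass}.
#'
#' @param labels named integer partition.
#' @param am activity matrix aligned with \code{labels}.
#' @param snrThr,diffThr,ratioThr prominence thresholds (defaults 1.5, 0.5,
#'   2).
#' @param singlePass merge all initially non-prominent pairs in one sweep
#'   instead of iterating.
#' @return compacted partition in which every pair of clusters is
#'   prominently different, with a \code{"mergeLog"} attribute (data frame:
#'   step, the two labels merged, and the pair's max SNR / mean difference /
#'   mean ratio at merge time); or a \code{\link{coocSignal}} with reason
#'   \code{"merged_to_one"} carrying the collapsed partition when merging
#'   leaves a single cluster.
#' @export
mergeByProminence <- function(labels, am, snrThr = 1.5, diffThr = 0.5,
                              ratioThr = 2, singlePass = FALSE) {
  stopifnot(is.matrix(am), length(labels) == nrow(am))
  startK <- length(unique(labels))
  log <- list()
  if (singlePass) {
    ks <- sort(unique(labels))
    parent <- stats::setNames(ks, ks)
    find <- function(k) { while (parent[[as.character(k)]] != k)
      k <- parent[[as.character(k)]]; k }
    if (length(ks) > 1)
      for (i in seq_len(length(ks) - 1)) for (j in (i + 1):length(ks)) {
        m <- clusterProminence(am, labels, ks[i], ks[j])
        if (!pairProminent(m, snrThr, diffThr, ratioThr))
          parent[[as.character(find(ks[j]))]] <- find(ks[i])
      }
    labels <- vapply(labels, find, numeric(1))
  } else {
    repeat {
      ks <- sort(unique(labels))
      if (length(ks) < 2) break
      worst <- NULL
      for (i in seq_len(length(ks) - 1)) for (j in (i + 1):length(ks)) {
        m <- clusterProminence(am, labels, ks[i], ks[j])
        if (!pairProminent(m, snrThr, diffThr, ratioThr)) {
          key <- max(m$snr)
          if (is.null(worst) || key < worst$key)
            worst <- list(key = key, i = ks[i], j = ks[j], m = m)
        }
      }
      if (is.null(worst)) break
      labels[labels == worst$j] <- worst$i
      log[[length(log) + 1L]] <- data.frame(
        step = length(log) + 1L, from = worst$j, into = worst$i,
        maxSnr = max(worst$m$snr), maxDiff = max(worst$m$meanDiff),
        maxRatio = max(worst$m$meanRatio))
    }
  }
  out <- .compactLabels(labels)
  attr(out, "mergeLog") <- if (length(log)) do.call(rbind, log) else
    data.frame(step = integer(), from = integer(), into = integer(),
               maxSnr = numeric(), maxDiff = numeric(), maxRatio = numeric())
  if (startK > 1 && max(out) == 1L)
    return(coocSignal("merged_to_one", partition = out))
  out
}
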