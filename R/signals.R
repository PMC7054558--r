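#' Algorithmic stop signals
#'
#' Several pipeline stages can find that a hierarchy node cannot be divided
#' any further: the gene graph may be empty, community detection may return
#' a single cluster, all cell clusters may be tiny, or prominence merging
#' may collapse everything into one cluster. Rather than throwing an error,
#' those stages return a lightweight sentinel of class \code{"coocSignal"}
#' carrying a \code{reason}; \code{\link{coocCluster}} converts the reason
#' into the leaf's termination label.
#'
#' @param reason character scalar, e.g. \code{"no_pathways"},
#'   \code{"one_community"}, \code{"all_tiny"}, \code{"merged_to_one"},
#'   \code{"too_few_cells"}, \code{"unfilterable"},
#'   \code{"degenerate_threshold"}, \code{"no_gene_graph"}.
#' @param ... additional payload stored on the signal (e.g. the collapsed
#'   partition).
#' @return an object of class \code{"coocSignal"}.
#' @export
coocSignal <- function(reason, ...) {
  structure(list(reason = reason, ...), class = "coocSignal")
}

#' @rdname coocSignal
#' @param x any object.
#' @export
isCoocSignal <- function(x) inherits(x, "coocSignal")

#' @export
print.coocSignal <- function(x, ...) {
  cat(sprintf("<coocSignal: %s>\n", x$reason))
  invisible(x)
}
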