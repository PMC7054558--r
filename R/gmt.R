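#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (e.g. gene pathways).
#' @param path output file.
#' @param description description field written for every set (second GMT
#'   column).
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(sets, path, description = "coocclust") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export gene pathways as a long table
#'
#' @param tree a \code{\linkS4class{CoocTree}}.
#' @return data frame with columns \code{gene}, \code{pathway}, \code{node}.
#' @export
pathwayTable <- function(tree) {
  rows <- list()
  for (nd in treeNodes(tree))
    for (nm in names(nd$pathways))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = nd$pathways[[nm]], pathway = sprintf("node%d.%s", nd$id, nm),
        node = nd$id)
  if (!length(rows))
    return(data.frame(gene = character(), pathway = character(),
                      node = integer()))
  do.call(rbind, rows)
}
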