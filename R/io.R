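#' Read an scRNA-seq count matrix
#'
#' Reads either a 10X Genomics MTX directory (\code{matrix.mtx} plus
#' \code{genes.tsv}/\code{features.tsv} and \code{barcodes.tsv}, optionally
#' gzipped) or a dense CSV/TSV table with one header row and one index
#' column. Whatever the on-disk orientation, the returned matrix follows the
#' package-wide convention of cells in rows and genes in columns; the 10X
#' genes x cells layout is transposed on read.
#'
#' Duplicated gene symbols in 10X feature files are disambiguated by
#' appending the feature-file row index, so that gene identifiers are unique
#' graph nodes downstream.
#'
#' @param path file (CSV/TSV) or directory (MTX) to read.
#' @param format \code{"auto"} (directory implies \code{"mtx10x"}, file
#'   extension decides otherwise), \code{"mtx10x"}, \code{"csv"} or
#'   \code{"tsv"}.
#' @param orientation layout of the file as stored; \code{"auto"} means
#'   genes x cells for MTX (the 10X convention) and cells x genes for
#'   CSV/TSV.
#' @return a sparse \code{\link[Matrix]{dgCMatrix-class}} of non-negative
#'   integer counts, cells x genes, with barcodes as rownames and gene ids
#'   as colnames.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(row.names = c("c1", "c2"), g1 = c(0L, 2L),
#'                      g2 = c(5L, 0L)), f)
#' readCounts(f)
#' @export
readCounts <- function(path,
                       format = c("auto", "mtx10x", "csv", "tsv"),
                       orientation = c("auto", "cells_by_genes",
                                       "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop(sprintf("'%s' does not exist", path))
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx10x"
      else if (grepl("\\.csv(\\.gz)?$", path)) "csv" else "tsv"
  }
  if (format == "mtx10x") {
    counts <- .read10x(path)
    if (orientation == "cells_by_genes") {
      # non-standard layout explicitly requested: keep as stored
      counts <- Matrix::t(counts)
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m))
      stop("count table contains non-numeric entries")
    counts <- as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                 "CsparseMatrix")
    if (orientation == "genes_by_cells") counts <- Matrix::t(counts)
  }
  .validateCounts(counts)
  counts
}

.find10xFile <- function(dir, stems) {
  for (stem in stems)
    for (ext in c("", ".gz")) {
      f <- file.path(dir, paste0(stem, ext))
      if (file.exists(f)) return(f)
    }
  stop(sprintf("no %s file found in '%s'", stems[1], dir))
}

.read10x <- function(dir) {
  mtx <- .find10xFile(dir, c("matrix.mtx"))
  feats <- .find10xFile(dir, c("genes.tsv", "features.tsv"))
  bars <- .find10xFile(dir, c("barcodes.tsv"))
  con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else mtx
  m <- Matrix::readMM(con)  # genes x cells per 10X convention
  # pattern matrices (all-1 binary MTX) come back without numeric values
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  ft <- utils::read.table(feats, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  symbols <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
  dup <- duplicated(symbols) | duplicated(symbols, fromLast = TRUE)
  symbols[dup] <- sprintf("%s.%d", symbols[dup], which(dup))
  barcodes <- utils::read.table(bars, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(symbols) || ncol(m) != length(barcodes))
    stop("matrix dimensions disagree with feature/barcode files")
  dimnames(m) <- list(symbols, barcodes)
  Matrix::t(m)
}

.validateCounts <- function(counts) {
  x <- counts@x
  if (length(x)) {
    bad <- which(x < 0 | x != round(x))
    if (length(bad)) {
      ij <- .nonzeroIndex(counts)
      stop(sprintf(
        "count matrix entry (%s, %s) = %g is not a non-negative integer",
        rownames(counts)[ij[bad[1], 1]], colnames(counts)[ij[bad[1], 2]],
        x[bad[1]]))
    }
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated cell identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicated gene identifiers")
  invisible(counts)
}

.nonzeroIndex <- function(m) {
  # (row, col) of each stored entry of a CsparseMatrix, in @x order
  cbind(m@i + 1L, rep(seq_len(ncol(m)), diff(m@p)))
}

#' Binarize a count matrix into its dropout pattern
#'
#' Every non-zero count becomes 1 regardless of expression level; zeros
#' (dropouts) stay 0. No normalization, transformation or imputation is
#' applied — the sparsity pattern of the input is preserved exactly.
#'
#' @param counts a cells x genes count matrix (dense or sparse) with
#'   non-negative entries, e.g. from \code{\link{readCounts}}.
#' @return a \code{\linkS4class{BinaryMatrix}}.
#' @examples
#' binarizeCounts(matrix(c(0, 5, 2, 0), 2, 2))
#' @export
binarizeCounts <- function(counts) {
  m <- as(as(as(Matrix::Matrix(counts, sparse = TRUE), "dMatrix"),
             "generalMatrix"), "CsparseMatrix")
  m <- Matrix::drop0(m)
  if (length(m@x) && any(m@x < 0))
    stop("count matrix contains negative entries")
  m@x[] <- 1
  BinaryMatrix(m, provenance = list(source = "binarize"))
}

#' Fraction of zero entries
#'
#' @param x a count matrix, sparse matrix or \code{BinaryMatrix}.
#' @return the fraction of entries equal to zero, in \code{[0, 1]}.
#' @export
dropoutRate <- function(x) {
  if (is(x, "BinaryMatrix")) x <- binValues(x)
  if (is(x, "sparseMatrix")) {
    x <- Matrix::drop0(x)
    return(1 - length(x@x) / prod(dim(x)))
  }
  mean(x == 0)
}

#' Filter genes and cells by detection
#'
#' Removes genes detected in too few cells and cells in which too few genes
#' are detected (default threshold 10 for both, applied at every hierarchy
#' node). "Too few" means strictly fewer than the threshold: a gene detected
#' in exactly \code{minCellsPerGene} cells is kept. Because removing genes
#' can push cells below their threshold and vice versa, the two filters are
#' alternated until a fixed point by default, so the returned matrix
#' satisfies both conditions jointly.
#'
#' @param bm a \code{\linkS4class{BinaryMatrix}}.
#' @param minCellsPerGene keep genes detected in at least this many cells.
#' @param minGenesPerCell keep cells detecting at least this many genes.
#' @param iterate iterate to a fixed point (default) or do a single
#'   gene-then-cell pass.
#' @return a filtered \code{BinaryMatrix} whose provenance records the
#'   retained cell and gene indices, or a \code{\link{coocSignal}} with
#'   reason \code{"unfilterable"} when no cells or genes survive (the caller
#'   treats such a node as a leaf).
#' @export
filterMatrix <- function(bm, minCellsPerGene = 10, minGenesPerCell = 10,
                         iterate = TRUE) {
  stopifnot(is(bm, "BinaryMatrix"),
            minCellsPerGene >= 0, minGenesPerCell >= 0)
  v <- binValues(bm)
  keepCells <- seq_len(nrow(v))
  keepGenes <- seq_len(ncol(v))
  repeat {
    sub <- v[keepCells, keepGenes, drop = FALSE]
    gOk <- Matrix::colSums(sub) >= minCellsPerGene
    sub2 <- sub[, gOk, drop = FALSE]
    cOk <- Matrix::rowSums(sub2) >= minGenesPerCell
    changed <- !all(gOk) || !all(cOk)
    keepGenes <- keepGenes[gOk]
    keepCells <- keepCells[cOk]
    if (!length(keepGenes) || !length(keepCells))
      return(coocSignal("unfilterable"))
    if (!changed || !iterate) break
  }
  new("BinaryMatrix",
      values = v[keepCells, keepGenes, drop = FALSE],
      provenance = list(source = "filter",
                        cells = keepCells, genes = keepGenes,
                        parentCells = rownames(v), parentGenes = colnames(v)))
}
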