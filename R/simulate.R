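#' Define a planted dropout model
#'
#' @param nCells named integer vector: cells per planted type (names become
#'   type labels; unnamed vectors get \code{T1, T2, ...}).
#' @param moduleSizes named integer vector: genes per module (possibly
#'   empty; unnamed vectors get \code{M1, M2, ...}).
#' @param detection modules x types matrix of detection probabilities in
#'   \code{[0, 1]}.
#' @param p0 background detection rate (default 0.05).
#' @param nBackground number of background genes (default 0).
#' @param depthSigma log-scale standard deviation of the per-cell
#'   log-normal depth factor (default 0: all cells at depth 1).
#' @param depthFactor optional per-type multiplier on the depth factor
#'   (default 1 for every type); models low-coverage subpopulations.
#' @return a \code{\linkS4class{PlantedModel}}.
#' @seealso \code{\link{simulateBinary}}, \code{\link{plantedPreset}}
#' @export
plantedModel <- function(nCells, moduleSizes = integer(),
                         detection = matrix(numeric(), 0,
                                            length(nCells)),
                         p0 = 0.05, nBackground = 0, depthSigma = 0,
                         depthFactor = rep(1, length(nCells))) {
  nCells <- setNames(as.integer(nCells),
                     names(nCells) %||% sprintf("T%d", seq_along(nCells)))
  moduleSizes <- setNames(
    as.integer(moduleSizes),
    names(moduleSizes) %||% sprintf("M%d", seq_along(moduleSizes)))
  detection <- as.matrix(detection)
  dimnames(detection) <- list(names(moduleSizes), names(nCells))
  depthFactor <- as.numeric(depthFactor)
  names(depthFactor) <- names(nCells)
  new("PlantedModel", nCells = nCells, moduleSizes = moduleSizes,
      detection = detection, p0 = as.numeric(p0),
      nBackground = as.integer(nBackground),
      depthSigma = as.numeric(depthSigma), depthFactor = depthFactor)
}

#' Simulate a binary dropout matrix from a planted model
#'
#' Entry (c, g) is Bernoulli with probability
#' \code{clip(d_c * P[module(g), type(c)], 0, 1)}; background genes use the
#' flat rate \code{p0} (also depth-scaled). The per-cell depth factor is
#' \code{depthFactor[type] * exp(rnorm(1, 0, depthSigma))}, mimicking the
#' way sequencing depth modulates every gene's detection probability at
#' once.
#'
#' @param model a \code{\linkS4class{PlantedModel}}.
#' @param seed RNG seed.
#' @return list with elements \code{bm}
#'   (\code{\linkS4class{BinaryMatrix}}), \code{cellLabels} (named integer,
#'   planted type per cell), \code{geneModules} (named list of gene ids per
#'   module) and \code{depth} (named numeric, per-cell depth factor).
#' @examples
#' m <- plantedPreset("two-type")
#' sim <- simulateBinary(m, seed = 1)
#' sim$bm
#' @export
simulateBinary <- function(model, seed = 0) {
  stopifnot(is(model, "PlantedModel"))
  set.seed(seed)
  types <- names(model@nCells)
  nTot <- sum(model@nCells)
  cellType <- rep(seq_along(types), model@nCells)
  cellIds <- unlist(lapply(seq_along(types), function(t)
    sprintf("%s_c%03d", types[t], seq_len(model@nCells[t]))))
  depth <- model@depthFactor[cellType] *
    exp(stats::rnorm(nTot, 0, model@depthSigma))

  mods <- model@moduleSizes
  geneModules <- list()
  geneProb <- matrix(NA_real_, nrow = length(mods) + 1L,
                     ncol = length(types))
  if (length(mods)) geneProb[seq_along(mods), ] <- model@detection
  geneProb[length(mods) + 1L, ] <- model@p0
  geneModule <- integer(0)
  geneIds <- character(0)
  for (m in seq_along(mods)) {
    ids <- sprintf("%s_g%03d", names(mods)[m], seq_len(mods[m]))
    geneModules[[names(mods)[m]]] <- ids
    geneIds <- c(geneIds, ids)
    geneModule <- c(geneModule, rep(m, mods[m]))
  }
  if (model@nBackground > 0) {
    geneIds <- c(geneIds, sprintf("BG_g%04d", seq_len(model@nBackground)))
    geneModule <- c(geneModule, rep(length(mods) + 1L, model@nBackground))
  }
  if (!length(geneIds)) stop("model defines no genes")

  # P for each (cell, gene), depth-scaled and clipped to [0, 1]
  P <- geneProb[geneModule, cellType, drop = FALSE]  # genes x cells
  P <- pmin(pmax(t(P) * depth, 0), 1)                # cells x genes
  draws <- matrix(stats::runif(nTot * length(geneIds)), nTot)
  m <- Matrix::Matrix((draws < P) * 1, sparse = TRUE)
  dimnames(m) <- list(cellIds, geneIds)
  list(bm = BinaryMatrix(m, provenance = list(source = "simulateBinary")),
       cellLabels = stats::setNames(cellType, cellIds),
       geneModules = geneModules,
       depth = stats::setNames(depth, cellIds))
}

#' Simulate an unstructured (null) dropout matrix
#'
#' i.i.d. Bernoulli(p) entries with no planted structure; used to check
#' that the pipeline does not invent clusters.
#'
#' @param nCells,nGenes matrix dimensions.
#' @param p detection probability in \code{[0, 1]}.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{BinaryMatrix}}.
#' @export
simulateNull <- function(nCells, nGenes, p, seed = 0) {
  stopifnot(p >= 0, p <= 1, nCells >= 1, nGenes >= 1)
  set.seed(seed)
  m <- Matrix::Matrix(
    (stats::runif(nCells * nGenes) < p) * 1, nrow = nCells, sparse = TRUE)
  dimnames(m) <- list(sprintf("cell%04d", seq_len(nCells)),
                      sprintf("gene%04d", seq_len(nGenes)))
  BinaryMatrix(m, provenance = list(source = "simulateNull"))
}

#' Preset planted models
#'
#' Four ready-made study designs:
#' \describe{
#'   \item{two-type}{two cell types (200 cells each) separated by two
#'     30-gene modules at detection 0.8 vs 0.05, 500 background genes at
#'     0.05, mild log-normal depth variation (sigma 0.15).}
#'   \item{hierarchical}{two major types, one split into two subtypes: 40-
#'     and 40-gene modules mark the major types and a 25-gene module marks
#'     one subtype (0.8 vs 0.05 contrast), 150 cells per leaf type, 600
#'     background genes at 0.05, no depth variation.}
#'   \item{null}{one type, no modules: 200 cells x 300 background genes at
#'     detection 0.3.}
#'   \item{low-depth}{like two-type, but the first type contains a
#'     subpopulation whose depth factor is halved, emulating low-coverage
#'     cells that share a type's expressed genes but detect fewer of them.}
#' }
#'
#' @param preset one of \code{"two-type"}, \code{"hierarchical"},
#'   \code{"null"}, \code{"low-depth"}.
#' @return a \code{\linkS4class{PlantedModel}}.
#' @export
plantedPreset <- function(preset = c("two-type", "hierarchical", "null",
                                     "low-depth")) {
  switch(match.arg(preset),
    "two-type" = plantedModel(
      nCells = c(T1 = 200L, T2 = 200L),
      moduleSizes = c(M1 = 30L, M2 = 30L),
      detection = rbind(c(0.8, 0.05), c(0.05, 0.8)),
      p0 = 0.05, nBackground = 500L, depthSigma = 0.15),
    "hierarchical" = plantedModel(
      nCells = c(A1 = 150L, A2 = 150L, B = 150L),
      moduleSizes = c(M1 = 40L, M2 = 40L, M3 = 25L),
      detection = rbind(c(0.8, 0.8, 0.05),    # M1: major type A
                        c(0.05, 0.05, 0.8),   # M2: major type B
                        c(0.8, 0.05, 0.05)),  # M3: subtype A1 only
      p0 = 0.05, nBackground = 600L, depthSigma = 0),
    "null" = plantedModel(
      nCells = c(T1 = 200L), moduleSizes = integer(),
      detection = matrix(numeric(), 0, 1),
      p0 = 0.3, nBackground = 300L, depthSigma = 0),
    "low-depth" = plantedModel(
      nCells = c(T1 = 170L, T1low = 30L, T2 = 200L),
      moduleSizes = c(M1 = 30L, M2 = 30L),
      detection = rbind(c(0.8, 0.8, 0.05), c(0.05, 0.05, 0.8)),
      p0 = 0.05, nBackground = 500L, depthSigma = 0.15,
      depthFactor = c(1, 0.5, 1)))
}

#' Write a simulated dataset as a 10X-style MTX directory
#'
#' Writes \code{matrix.mtx} (genes x cells, the 10X convention),
#' \code{genes.tsv}, \code{barcodes.tsv}, plus \code{labels.tsv} (barcode,
#' planted type) and \code{modules.gmt} when planted truth is available.
#'
#' @param sim result of \code{\link{simulateBinary}}, or a bare
#'   \code{\linkS4class{BinaryMatrix}}.
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
writeSimulated <- function(sim, dir) {
  if (is(sim, "BinaryMatrix")) sim <- list(bm = sim)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- binValues(sim$bm)
  Matrix::writeMM(Matrix::t(v), file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = colnames(v), symbol = colnames(v)),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(rownames(v), file.path(dir, "barcodes.tsv"))
  if (!is.null(sim$cellLabels))
    utils::write.table(
      data.frame(barcode = names(sim$cellLabels), label = sim$cellLabels),
      file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  if (!is.null(sim$geneModules) && length(sim$geneModules))
    writeGMT(sim$geneModules, file.path(dir, "modules.gmt"),
             description = "planted module")
  invisible(dir)
}
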