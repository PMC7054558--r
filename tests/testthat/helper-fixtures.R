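# small builders and independent oracles shared across tests

# BinaryMatrix from a plain 0/1 matrix (cells x genes)
makeBinary <- function(m, cells = NULL, genes = NULL) {
  if (is.null(rownames(m)) && is.null(cells))
    cells <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(colnames(m)) && is.null(genes))
    genes <- sprintf("g%02d", seq_len(ncol(m)))
  BinaryMatrix(m, cellIds = cells, geneIds = genes)
}

# brute-force pairwise co-occurrence scores: explicit per-pair contingency
# counting, independent of the cross-product implementation
bruteScores <- function(m) {
  m <- as.matrix(m)
  p <- ncol(m)
  S <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    x <- m[, i] > 0; y <- m[, j] > 0
    A <- sum(x & y); B <- sum(x & !y); C <- sum(!x & y); D <- sum(!x & !y)
    num <- A * D - B * C
    den <- (A + B) * (A + C) * (B + D) * (C + D)
    S[i, j] <- S[j, i] <- if (den == 0) 0 else sign(num) * num^2 / den
  }
  S
}

# brute-force Rand index by enumerating every pair of elements
bruteRand <- function(a, b) {
  n <- length(a)
  agree <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / tot
}

# two planted gene modules over two cell groups: module m genes detected at
# pHigh in group m cells and pLow elsewhere; optional flat background genes
twoModuleMatrix <- function(nPerGroup = 150, moduleSize = 30, pHigh = 0.9,
                            pLow = 0.05, nBackground = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * nPerGroup
  grp <- rep(1:2, each = nPerGroup)
  p <- cbind(
    matrix(ifelse(grp == 1, pHigh, pLow), n, moduleSize),
    matrix(ifelse(grp == 2, pHigh, pLow), n, moduleSize),
    matrix(pLow, n, nBackground))
  m <- (matrix(runif(length(p)), nrow(p)) < p) * 1
  colnames(m) <- c(sprintf("m1_%02d", seq_len(moduleSize)),
                   sprintf("m2_%02d", seq_len(moduleSize)),
                   if (nBackground) sprintf("bg_%02d", seq_len(nBackground)))
  rownames(m) <- sprintf("c%03d", seq_len(n))
  list(bm = makeBinary(m), groups = grp,
       modules = list(M1 = colnames(m)[seq_len(moduleSize)],
                      M2 = colnames(m)[moduleSize + seq_len(moduleSize)]))
}

# two tight Gaussian blobs in a one-pathway activity space
twoBlobActivity <- function(nPerBlob = 50, centers = c(0.1, 0.9),
                            sigma = 0.01, seed = 1) {
  set.seed(seed)
  a <- c(rnorm(nPerBlob, centers[1], sigma), rnorm(nPerBlob, centers[2], sigma))
  am <- matrix(pmin(pmax(a, 0), 1), ncol = 1,
               dimnames = list(sprintf("c%03d", seq_len(2 * nPerBlob)), "P1"))
  list(am = am, blobs = rep(1:2, each = nPerBlob))
}

# activity values with exact sample mean and sd: half the cells at mu - d,
# half at mu + d, with d chosen so the sample (n - 1) sd equals sdev
activityWith <- function(mu, sdev, n = 16) {
  d <- sdev * sqrt((n - 1) / n)
  c(rep(mu - d, n / 2), rep(mu + d, n / 2))
}

# write a minimal 10X-style MTX directory by hand (plain text)
writeMiniMtx <- function(dir, entries, nGenes, nCells,
                         genes = sprintf("G%d", seq_len(nGenes)),
                         barcodes = sprintf("BC%d", seq_len(nCells))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c("%%MatrixMarket matrix coordinate integer general",
           sprintf("%d %d %d", nGenes, nCells, nrow(entries)))
  writeLines(c(hdr, apply(entries, 1, paste, collapse = " ")),
             file.path(dir, "matrix.mtx"))
  writeLines(paste(sprintf("ENSG%04d", seq_len(nGenes)), genes, sep = "\t"),
             file.path(dir, "genes.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}
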