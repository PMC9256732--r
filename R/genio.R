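## Genotype and phenotype input: dosage matrices, PLINK binary triples,
## MAF filtering, design-matrix construction, phenotype/weight/covariate
## tables.

.alleleFrequency <- function(g) {
  # counted-allele frequency per marker over non-missing entries
  nobs <- colSums(!is.na(g))
  cnt <- colSums(g, na.rm = TRUE)
  p <- ifelse(nobs > 0, cnt / (2 * nobs), 0)
  as.numeric(p)
}

.defaultMarkers <- function(ids, chrom = "1") {
  data.frame(chrom = rep(chrom, length.out = length(ids)),
             id = ids, pos = seq_along(ids),
             A1 = "A", A2 = "B", stringsAsFactors = FALSE)
}

#' Construct a GenotypeData object
#'
#' @param genotypes individuals x markers matrix with entries 0/1/2/NA.
#' @param sampleIds character identifiers (default row names or S1..Sn).
#' @param markers marker map data.frame with columns chrom, id, pos, A1,
#'   A2; a minimal map is built from column names when omitted.
#' @return a [GenotypeData-class] with allele frequencies computed from
#'   the non-missing entries.
#' @examples
#' g <- genotypeData(matrix(c(0, 1, 2, 1, 1, 1), nrow = 3))
#' alleleFreq(g)
#' @export
genotypeData <- function(genotypes, sampleIds = NULL, markers = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (is.null(sampleIds)) {
    sampleIds <- rownames(genotypes)
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(genotypes)))
  }
  if (is.null(markers)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- paste0("M", seq_len(ncol(genotypes)))
    markers <- .defaultMarkers(ids)
  }
  dimnames(genotypes) <- NULL
  new("GenotypeData", genotypes = genotypes,
      sampleIds = as.character(sampleIds), markers = markers,
      p = .alleleFrequency(genotypes))
}

#' Read a dosage matrix
#'
#' Tab-separated text: header row of marker ids, first column the sample
#' id, remaining columns integer allele counts (0/1/2) with \code{NA}
#' for missing.
#'
#' @param path file path.
#' @return a [GenotypeData-class].
#' @seealso [writeDosage()]
#' @export
readDosage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (ncol(dt) < 2) stop("malformed dosage file (need id + markers): ", path)
  ids <- as.character(dt[[1]])
  g <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(g)) stop("non-numeric genotype values in ", path)
  bad <- matrix(!(g %in% c(0, 1, 2)), nrow = nrow(g)) & !is.na(g)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype value at sample ", ids[idx[1]],
         ", marker ", colnames(dt)[-1][idx[2]])
  }
  mk <- colnames(dt)[-1]
  if (anyDuplicated(mk)) stop("duplicate marker id in ", path)
  genotypeData(g, sampleIds = ids, markers = .defaultMarkers(mk))
}

#' Write a dosage matrix
#'
#' @param g a [GenotypeData-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDosage <- function(g, path) {
  m <- genotypes(g)
  df <- data.frame(id = g@sampleIds, m, check.names = FALSE)
  colnames(df) <- c("id", markerInfo(g)$id)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

## PLINK 1.9 binary triple ---------------------------------------------
## .bed is SNP-major: magic bytes 0x6c 0x1b 0x01, then per marker
## ceiling(nInd/4) bytes; each byte packs 4 individuals, 2 bits each,
## low bits first: 00 = A1/A1 (dosage 2 of the counted allele A1),
## 01 = missing, 10 = het (1), 11 = A2/A2 (0).

.bed2dosage <- c(2, NA, 1, 0)   # indexed by 2-bit code + 1
.dosage2bed <- function(d) {
  out <- integer(length(d))
  out[is.na(d)] <- 1L
  out[!is.na(d) & d == 2] <- 0L
  out[!is.na(d) & d == 1] <- 2L
  out[!is.na(d) & d == 0] <- 3L
  out
}

#' Read a PLINK 1.9 binary triple
#'
#' Reads \code{prefix.bed} (SNP-major), \code{prefix.bim} and
#' \code{prefix.fam}. The counted allele is A1, so dosages are copies of
#' A1 (allele orientation only flips the sign of estimated effects).
#'
#' @param prefix path prefix without extension.
#' @return a [GenotypeData-class].
#' @seealso [writePlink()]
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)
  bimd <- data.table::fread(bim, header = FALSE, data.table = FALSE)
  if (ncol(bimd) != 6) stop("malformed .bim (expect 6 columns): ", bim)
  markers <- data.frame(chrom = as.character(bimd[[1]]), id = bimd[[2]],
                        pos = as.integer(bimd[[4]]),
                        A1 = as.character(bimd[[5]]),
                        A2 = as.character(bimd[[6]]),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(markers$id)) stop("duplicate marker id in ", bim)
  famd <- data.table::fread(fam, header = FALSE, data.table = FALSE)
  ids <- as.character(famd[[2]])
  nInd <- length(ids); nSnp <- nrow(markers)
  bpm <- ceiling(nInd / 4)                     # bytes per marker
  raw <- readBin(bed, "raw", n = 3 + nSnp * bpm)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  if (length(raw) != 3 + nSnp * bpm)
    stop("truncated .bed file: ", bed)
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit fields: 4 individuals per byte, low bits first
  codes <- matrix(0L, nrow = 4 * bpm, ncol = nSnp)
  b <- matrix(body, nrow = bpm)
  codes[seq(1, 4 * bpm, by = 4), ] <- b %% 4L
  codes[seq(2, 4 * bpm, by = 4), ] <- (b %/% 4L) %% 4L
  codes[seq(3, 4 * bpm, by = 4), ] <- (b %/% 16L) %% 4L
  codes[seq(4, 4 * bpm, by = 4), ] <- (b %/% 64L) %% 4L
  g <- matrix(.bed2dosage[codes[seq_len(nInd), , drop = FALSE] + 1L],
              nrow = nInd)
  genotypeData(g, sampleIds = ids, markers = markers)
}

#' Write a PLINK 1.9 binary triple
#'
#' @param g a [GenotypeData-class].
#' @param prefix output path prefix.
#' @return invisibly, \code{prefix}.
#' @export
writePlink <- function(g, prefix) {
  m <- genotypes(g); nInd <- nrow(m); nSnp <- ncol(m)
  mk <- markerInfo(g)
  data.table::fwrite(
    data.frame(mk$chrom, mk$id, 0, mk$pos, mk$A1, mk$A2),
    paste0(prefix, ".bim"), sep = "\t", col.names = FALSE, quote = FALSE)
  data.table::fwrite(
    data.frame(g@sampleIds, g@sampleIds, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", col.names = FALSE, quote = FALSE)
  bpm <- ceiling(nInd / 4)
  codes <- matrix(1L, nrow = 4 * bpm, ncol = nSnp)  # pad = missing code
  codes[seq_len(nInd), ] <- matrix(.dosage2bed(m), nrow = nInd)
  packed <- codes[seq(1, 4 * bpm, by = 4), , drop = FALSE] +
    4L  * codes[seq(2, 4 * bpm, by = 4), , drop = FALSE] +
    16L * codes[seq(3, 4 * bpm, by = 4), , drop = FALSE] +
    64L * codes[seq(4, 4 * bpm, by = 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(packed), con)
  invisible(prefix)
}

#' Load genotypes from a named format
#'
#' @param path file path (dosage) or prefix (PLINK).
#' @param format one of \code{"plink-bed"}, \code{"dosage-tsv"}.
#' @return a [GenotypeData-class].
#' @export
loadGenotypes <- function(path, format = c("dosage-tsv", "plink-bed")) {
  format <- match.arg(format)
  switch(format,
         "dosage-tsv" = readDosage(path),
         "plink-bed"  = readPlink(sub("\\.bed$", "", path)))
}

#' Remove low minor-allele-frequency markers
#'
#' Markers with min(p_j, 1 - p_j) below the threshold are excluded from
#' the analysis; the default threshold is 0.002.
#'
#' @param g a [GenotypeData-class].
#' @param threshold MAF threshold in [0, 0.5].
#' @return list with elements \code{genotypes} (filtered
#'   [GenotypeData-class]) and \code{keptIndex} (positions of survivors
#'   in the input, increasing).
#' @export
filterMAF <- function(g, threshold = 0.002) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  maf <- pmin(g@p, 1 - g@p)
  keep <- which(maf >= threshold)
  if (!length(keep))
    stop("all markers removed by the MAF filter (threshold ", threshold, ")")
  out <- new("GenotypeData",
             genotypes = g@genotypes[, keep, drop = FALSE],
             sampleIds = g@sampleIds,
             markers = g@markers[keep, , drop = FALSE],
             p = g@p[keep])
  list(genotypes = out, keptIndex = as.integer(keep))
}

#' Build the scaled, centred design matrix
#'
#' v_ij = (v*_ij - 2 p_j) / sqrt(2 p_j (1 - p_j)), with missing
#' genotypes imputed to the column mean 2 p_j before scaling (so they
#' scale to 0 and the right-hand-side algebra stays exact). Markers with
#' p_j of 0 or 1 cannot be scaled; apply [filterMAF()] first.
#'
#' @param g a [GenotypeData-class] (typically the \code{genotypes}
#'   element returned by [filterMAF()]).
#' @param keptIndex positions of these markers in the original panel
#'   (defaults to 1..nMarkers).
#' @param p allele frequencies to scale with; defaults to the observed
#'   frequencies of \code{g} (supply training frequencies when scaling a
#'   validation set).
#' @return a [ScaledDesign-class].
#' @export
scaleCenter <- function(g, keptIndex = seq_len(nMarkers(g)), p = NULL) {
  if (is.null(p)) p <- g@p
  mono <- which(p <= 0 | p >= 1)
  if (length(mono))
    stop("cannot scale monomorphic marker(s): ",
         paste(head(g@markers$id[mono], 5), collapse = ", "),
         " (p is 0 or 1); filter first")
  V <- g@genotypes
  if (anyNA(V)) {
    imp <- rep(2 * p, each = nrow(V))
    V[is.na(V)] <- imp[is.na(V)]
  }
  V <- sweep(V, 2, 2 * p, "-")
  V <- sweep(V, 2, sqrt(2 * p * (1 - p)), "/")
  new("ScaledDesign", V = V, keptIndex = as.integer(keptIndex),
      p = p, markers = g@markers, sampleIds = g@sampleIds)
}

#' Construct phenotype records directly
#'
#' @param y phenotype vector.
#' @param w non-negative weights (default all 1).
#' @param X fixed-effect covariates (an intercept column is appended; a
#'   NULL X gives an intercept-only model).
#' @param h2Guess user heritability guess in [0, 1].
#' @param sampleIds identifiers.
#' @return a [TraitData-class] with sigma_t^2 computed by
#'   [weightedTraitVariance()].
#' @export
traitData <- function(y, w = rep(1, length(y)), X = NULL, h2Guess = 0.5,
                      sampleIds = paste0("S", seq_along(y))) {
  Xfull <- cbind(intercept = rep(1, length(y)),
                 if (!is.null(X)) as.matrix(X))
  y2 <- y
  w[is.na(y)] <- 0          # missing record => zero weight
  y2[is.na(y)] <- 0
  st2 <- weightedTraitVariance(y2, w, h2Guess)
  new("TraitData", y = as.numeric(y2), w = as.numeric(w), X = Xfull,
      h2Guess = h2Guess, sigmaT2 = st2,
      sampleIds = as.character(sampleIds))
}

#' Load phenotypes, weights and covariates from a table
#'
#' Tab-separated with header. Records are aligned to the genotype row
#' order; a missing trait value sets that record's weight to 0; when no
#' weight column is named all weights are 1; an intercept column is
#' always appended to the fixed-effect matrix.
#'
#' @param path file path.
#' @param genotypes the [GenotypeData-class] or [ScaledDesign-class]
#'   whose sample order the records must follow.
#' @param idColumn name of the sample-id column (default first column).
#' @param traitColumn name of the phenotype column.
#' @param weightColumn optional name of the weight column.
#' @param covariateColumns optional character vector of covariate column
#'   names.
#' @param h2Guess heritability guess in [0, 1].
#' @return a [TraitData-class].
#' @export
loadPhenotypes <- function(path, genotypes, idColumn = NULL, traitColumn,
                           weightColumn = NULL, covariateColumns = NULL,
                           h2Guess = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (is.null(idColumn)) idColumn <- colnames(dt)[1]
  ids <- as.character(dt[[idColumn]])
  want <- genotypes@sampleIds
  idx <- match(want, ids)
  if (anyNA(idx))
    stop("genotyped samples missing from phenotype table: ",
         paste(head(want[is.na(idx)], 5), collapse = ", "))
  y <- dt[[traitColumn]][idx]
  if (!is.numeric(y)) stop("non-numeric phenotype column: ", traitColumn)
  w <- if (is.null(weightColumn)) rep(1, length(y))
       else as.numeric(dt[[weightColumn]][idx])
  X <- if (is.null(covariateColumns)) NULL
       else as.matrix(dt[idx, covariateColumns, drop = FALSE])
  traitData(y, w = w, X = X, h2Guess = h2Guess, sampleIds = want)
}
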