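## Quantitative-trait simulator: independent-site genotypes, QTN
## effects drawn from the three non-null mixture components, true
## breeding values and phenotypes at a target heritability.

#' Simulate genotypes
#'
#' Per-marker allele frequencies are drawn uniformly in
#' \code{mafRange} and genotypes independently as Binomial(2, p_j) per
#' individual (independent sites, no linkage disequilibrium). An
#' optional two-subpopulation mode shifts each marker's frequency in
#' opposite directions for the two groups, mimicking crude breed
#' structure.
#'
#' @param nInd number of individuals.
#' @param nSnp number of markers.
#' @param mafRange frequency bounds, a sub-interval of (0, 0.5].
#' @param nChrom number of chromosome labels to spread markers over.
#' @param spacingBp base-pair spacing between adjacent markers.
#' @param subpopShift if positive, individuals are split into two
#'   groups whose marker frequencies are shifted by +/- this amount
#'   (clamped to [0.01, 0.99]).
#' @return a [GenotypeData-class].
#' @export
simulateGenotypes <- function(nInd, nSnp, mafRange = c(0.05, 0.5),
                              nChrom = 1L, spacingBp = 5000L,
                              subpopShift = 0) {
  stopifnot(mafRange[1] > 0, mafRange[2] <= 0.5,
            mafRange[1] <= mafRange[2])
  p <- runif(nSnp, mafRange[1], mafRange[2])
  if (subpopShift > 0) {
    half <- nInd %/% 2
    p1 <- pmin(pmax(p + subpopShift, 0.01), 0.99)
    p2 <- pmin(pmax(p - subpopShift, 0.01), 0.99)
    g <- rbind(
      matrix(rbinom(half * nSnp, 2, rep(p1, each = half)), nrow = half),
      matrix(rbinom((nInd - half) * nSnp, 2, rep(p2, each = nInd - half)),
             nrow = nInd - half))
  } else {
    g <- matrix(rbinom(nInd * nSnp, 2, rep(p, each = nInd)), nrow = nInd)
  }
  perChrom <- ceiling(nSnp / nChrom)
  chrom <- as.character(rep(seq_len(nChrom), each = perChrom)[seq_len(nSnp)])
  within <- (seq_len(nSnp) - 1L) %% perChrom
  markers <- data.frame(chrom = chrom,
                        id = sprintf("snp%06d", seq_len(nSnp)),
                        pos = as.integer(within) * as.integer(spacingBp) + 1L,
                        A1 = "A", A2 = "B", stringsAsFactors = FALSE)
  genotypeData(g, markers = markers)
}

#' Simulate QTN effects
#'
#' Causal-variant positions are sampled without replacement and their
#' effects drawn from the three non-null normal components: by default
#' 15, 500 and 3485 effects with variances 0.01, 0.001 and 0.0001 times
#' sigma_g^2 = 625 (large, moderate, small). All other markers have
#' effect exactly 0.
#'
#' @param nSnp total markers.
#' @param qtnCounts markers per non-null component, largest variance
#'   first.
#' @param sigmaG2 additive genetic variance.
#' @param qtnVariances component variances as multiples of sigmaG2.
#' @return list with \code{epsilon} (length-nSnp effect vector),
#'   \code{qtnIndex} (positions of causal variants) and \code{group}
#'   (component of each causal variant, 1 = largest variance).
#' @export
simulateQtnEffects <- function(nSnp, qtnCounts = c(15, 500, 3485),
                               sigmaG2 = 625,
                               qtnVariances = c(0.01, 0.001, 1e-4)) {
  stopifnot(length(qtnCounts) == length(qtnVariances))
  nQtn <- sum(qtnCounts)
  if (nQtn > nSnp)
    stop("QTN counts (", nQtn, ") exceed the number of markers (",
         nSnp, ")")
  eps <- numeric(nSnp)
  qtnIndex <- if (nQtn > 0) sort(sample.int(nSnp, nQtn)) else integer(0)
  group <- rep(seq_along(qtnCounts), qtnCounts)
  if (nQtn > 0) {
    group <- sample(group)   # random interleaving of effect sizes
    eps[qtnIndex] <- rnorm(nQtn, 0, sqrt(sigmaG2 * qtnVariances[group]))
  }
  list(epsilon = eps, qtnIndex = qtnIndex, group = group)
}

#' Simulate phenotypes from genotypes and QTN effects
#'
#' TBV_i = sum_j v*_ij epsilon_j on the raw 0/1/2 coding; environmental
#' noise with variance var(TBV) (1 - h2) / h2 is added so the realised
#' heritability targets h2. An optional two-level group offset (e.g. a
#' breed effect) can be added; it is excluded from the TBV.
#'
#' @param genotypes a [GenotypeData-class].
#' @param epsilon per-marker QTN effects.
#' @param h2 target heritability in (0, 1).
#' @param groupOffset scalar offset added to the second half of the
#'   individuals (default 0 = no fixed-effect structure).
#' @return list with \code{y}, \code{tbv} and \code{realizedH2}
#'   (var(tbv)/var(y)).
#' @export
simulatePhenotypes <- function(genotypes, epsilon, h2, groupOffset = 0) {
  stopifnot(h2 > 0, h2 < 1)
  g <- genotypes(genotypes)
  g[is.na(g)] <- 0
  tbv <- as.numeric(g %*% epsilon)
  vt <- var(tbv)
  if (vt == 0) stop("all QTN effects are zero: var(TBV) = 0")
  noise <- rnorm(length(tbv), 0, sqrt(vt * (1 - h2) / h2))
  y <- tbv + noise
  if (groupOffset != 0) {
    half <- length(y) %/% 2
    y <- y + groupOffset * (seq_along(y) > half)
  }
  list(y = y, tbv = tbv, realizedH2 = var(tbv) / var(y))
}

#' Simulate a complete analysis-ready data set
#'
#' Convenience wrapper: genotypes, QTN effects, phenotypes, MAF filter
#' and design matrix in one call.
#'
#' @inheritParams simulateGenotypes
#' @param qtnCounts,sigmaG2,qtnVariances see [simulateQtnEffects()].
#' @param h2 target heritability.
#' @param h2Guess heritability guess handed to the trait container.
#' @param mafThreshold MAF filter applied before scaling.
#' @param seed integer seed.
#' @param groupOffset see [simulatePhenotypes()].
#' @return list with \code{genotypes} ([GenotypeData-class], unfiltered),
#'   \code{design} ([ScaledDesign-class] of the MAF-filtered panel),
#'   \code{trait} ([TraitData-class]), \code{truth} (epsilon, qtnIndex,
#'   group, tbv, realizedH2) and \code{keptIndex}.
#' @export
simulateDataset <- function(nInd, nSnp, qtnCounts = c(15, 500, 3485),
                            sigmaG2 = 625,
                            qtnVariances = c(0.01, 0.001, 1e-4),
                            h2 = 0.3, h2Guess = 0.5,
                            mafRange = c(0.05, 0.5),
                            mafThreshold = 0.002, nChrom = 1L,
                            spacingBp = 5000L, groupOffset = 0,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  geno <- simulateGenotypes(nInd, nSnp, mafRange = mafRange,
                            nChrom = nChrom, spacingBp = spacingBp)
  qtn <- simulateQtnEffects(nSnp, qtnCounts = qtnCounts,
                            sigmaG2 = sigmaG2,
                            qtnVariances = qtnVariances)
  ph <- simulatePhenotypes(geno, qtn$epsilon, h2,
                           groupOffset = groupOffset)
  flt <- filterMAF(geno, mafThreshold)
  design <- scaleCenter(flt$genotypes, keptIndex = flt$keptIndex)
  trait <- traitData(ph$y, h2Guess = h2Guess,
                     sampleIds = geno@sampleIds)
  list(genotypes = geno, design = design, trait = trait,
       truth = c(qtn, ph[c("tbv", "realizedH2")]),
       keptIndex = flt$keptIndex)
}

#' Write a simulated data set to disk
#'
#' Writes a PLINK triple (or dosage matrix), a phenotype table and a
#' truth table (marker id, effect, component group).
#'
#' @param sim result of [simulateDataset()].
#' @param prefix output path prefix.
#' @param format \code{"plink-bed"} or \code{"dosage-tsv"}.
#' @return invisibly, \code{prefix}.
#' @export
writeSimulation <- function(sim, prefix,
                            format = c("plink-bed", "dosage-tsv")) {
  format <- match.arg(format)
  if (format == "plink-bed") writePlink(sim$genotypes, prefix)
  else writeDosage(sim$genotypes, paste0(prefix, ".dosage.tsv"))
  data.table::fwrite(
    data.frame(id = sim$genotypes@sampleIds, trait = sim$trait@y,
               tbv = sim$truth$tbv),
    paste0(prefix, ".pheno.tsv"), sep = "\t", quote = FALSE)
  mk <- markerInfo(sim$genotypes)
  grp <- integer(nrow(mk))
  grp[sim$truth$qtnIndex] <- sim$truth$group
  data.table::fwrite(
    data.frame(id = mk$id, epsilon = sim$truth$epsilon, group = grp),
    paste0(prefix, ".truth.tsv"), sep = "\t", quote = FALSE)
  invisible(prefix)
}
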