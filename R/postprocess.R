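## Posterior summaries: breeding-value prediction, accuracy/bias,
## across-chain convergence, 50-kb window fine-mapping, component
## counts.

#' Predict breeding values for new individuals
#'
#' EBV = V_new g_mean, the marker term only (fixed effects excluded),
#' with the new genotypes scaled and centred using the training allele
#' frequencies.
#'
#' @param newGenotypes a [GenotypeData-class] of the individuals to
#'   predict, covering all training markers, or a [ScaledDesign-class]
#'   already on the training scale.
#' @param gMean posterior-mean marker effects (training marker order),
#'   or a [ChainFit-class].
#' @param design the training [ScaledDesign-class] (supplies marker ids
#'   and allele frequencies); required when \code{newGenotypes} is raw.
#' @return named numeric vector of EBVs.
#' @export
predictEbv <- function(newGenotypes, gMean, design = NULL) {
  if (is(gMean, "ChainFit")) gMean <- markerEffects(gMean)
  if (is(newGenotypes, "ScaledDesign")) {
    V <- designMatrix(newGenotypes)
    ids <- newGenotypes@sampleIds
  } else {
    if (is.null(design))
      stop("supply the training design to scale raw genotypes")
    idx <- match(markerInfo(design)$id, markerInfo(newGenotypes)$id)
    if (anyNA(idx))
      stop("markers missing from the new genotypes: ",
           paste(head(markerInfo(design)$id[is.na(idx)], 5),
                 collapse = ", "))
    sub <- new("GenotypeData",
               genotypes = genotypes(newGenotypes)[, idx, drop = FALSE],
               sampleIds = newGenotypes@sampleIds,
               markers = markerInfo(newGenotypes)[idx, , drop = FALSE],
               p = newGenotypes@p[idx])
    scaled <- scaleCenter(sub, p = alleleFreq(design))
    V <- designMatrix(scaled)
    ids <- newGenotypes@sampleIds
  }
  if (ncol(V) != length(gMean))
    stop("marker count mismatch between genotypes and effects")
  setNames(as.numeric(V %*% gMean), ids)
}

#' Prediction accuracy and bias
#'
#' Accuracy is the Pearson correlation between the true values and the
#' EBVs; bias is the slope of the least-squares regression of truth on
#' EBV, where a coefficient of 1 means no bias (the expectation of the
#' true value given the prediction equals the prediction).
#'
#' @param truth true breeding values (or phenotypes).
#' @param ebv predicted values.
#' @return named numeric vector \code{c(accuracy, bias)}.
#' @export
accuracyBias <- function(truth, ebv) {
  stopifnot(length(truth) == length(ebv), length(truth) >= 3)
  if (!all(is.finite(truth)) || !all(is.finite(ebv)))
    stop("non-finite values in truth or ebv")
  if (var(truth) == 0 || var(ebv) == 0)
    stop("zero variance: accuracy/bias undefined")
  c(accuracy = cor(truth, ebv),
    bias = as.numeric(coef(lm(truth ~ ebv))[2]))
}

#' Mean across-chain correlation of SNP effects
#'
#' Convergence diagnostic: the mean of the Pearson correlations between
#' posterior-mean SNP effects over all unordered chain pairs (choose(nC,
#' 2) values; 10 for 5 chains).
#'
#' @param effectSets list of per-chain effect vectors, or a list of
#'   [ChainFit-class] objects.
#' @return mean pairwise correlation.
#' @export
chainCorrelation <- function(effectSets) {
  effectSets <- lapply(effectSets, function(x)
    if (is(x, "ChainFit")) markerEffects(x) else x)
  nC <- length(effectSets)
  stopifnot(nC >= 2)
  if (any(vapply(effectSets, sd, numeric(1)) == 0))
    stop("constant effect vector: correlation undefined")
  M <- do.call(cbind, effectSets)
  cm <- cor(M)
  mean(cm[upper.tri(cm)])
}

#' Correlation with an infinitely long chain
#'
#' Modelling each chain's estimates as truth plus independent sampling
#' error, the correlation between the average SNP effects of n_C chains
#' and those of an infinitely long chain is
#' sqrt(n_C r / (n_C r - r + 1)), where r is the pairwise between-chain
#' correlation. Monotone increasing in both arguments.
#'
#' @param nC number of chains (>= 1).
#' @param r pairwise between-chain correlation in (0, 1].
#' @return the long-run correlation.
#' @examples
#' longrunCorrelation(5, 0.8)   # 0.97 to two decimals
#' @export
longrunCorrelation <- function(nC, r) {
  stopifnot(nC >= 1)
  if (r <= 0) stop("r must be positive")
  if (r > 1) stop("r must not exceed 1")
  sqrt(nC * r / (nC * r - r + 1))
}

#' Average effects and inclusion probabilities over chains
#'
#' Simple unweighted means of the per-chain posterior summaries.
#'
#' @param fits list of [ChainFit-class] objects over the same markers.
#' @return list with \code{gMean}, \code{pp}, \code{componentFreq},
#'   \code{h2} (mean posterior-mean heritability) and
#'   \code{chainCorrelation}.
#' @export
combineChains <- function(fits) {
  stopifnot(length(fits) >= 1)
  gM <- rowMeans(sapply(fits, markerEffects))
  pp <- rowMeans(sapply(fits, inclusionProb))
  cf <- Reduce(`+`, lapply(fits, function(f) f@componentFreq)) /
    length(fits)
  list(gMean = gM, pp = pp, componentFreq = cf,
       h2 = mean(vapply(fits, heritability, numeric(1))),
       chainCorrelation = if (length(fits) >= 2)
         chainCorrelation(fits) else NA_real_)
}

#' Sum posterior inclusion probabilities in genomic windows
#'
#' Per chromosome, non-overlapping fixed-grid windows of
#' \code{windowBp} base pairs anchored at position 0, on 0-based
#' half-open intervals (1-based marker position pos falls in window
#' floor((pos - 1) / windowBp)). Empty windows are omitted; the total
#' sum_pp over windows equals the total pp over markers exactly.
#'
#' @param markers data.frame with columns \code{chrom}, \code{pos}
#'   (1-based) and \code{pp}.
#' @param windowBp window width in base pairs (default 50,000).
#' @param threshold windows with sum_pp above this are flagged as
#'   likely containing a causal variant (default 0.9).
#' @return data.frame (BED-like) with columns chrom, start, end
#'   (0-based half-open), sumPP, nMarkers, flagged; ordered by
#'   chromosome and start.
#' @export
windowPP <- function(markers, windowBp = 50000L, threshold = 0.9) {
  stopifnot(all(c("chrom", "pos", "pp") %in% colnames(markers)),
            all(markers$pos >= 1))
  win <- (markers$pos - 1L) %/% as.integer(windowBp)
  key <- paste(markers$chrom, win, sep = "\r")
  agg <- rowsum(cbind(pp = markers$pp, n = 1), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  w <- as.integer(vapply(parts, `[`, character(1), 2))
  out <- data.frame(chrom = chrom,
                    start = w * as.integer(windowBp),
                    end = (w + 1L) * as.integer(windowBp),
                    sumPP = as.numeric(agg[, "pp"]),
                    nMarkers = as.integer(agg[, "n"]),
                    stringsAsFactors = FALSE)
  out$flagged <- out$sumPP > threshold
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Per-iteration and mean mixture-component counts
#'
#' Tabulates the per-outer-cycle counts of markers per mixture
#' component (per class for BayesRC) and their post burn-in means.
#'
#' @param fit a [ChainFit-class] (or list of them, averaged).
#' @return list with \code{perIteration} (cycles x class x component
#'   array) and \code{meanCounts} (class x component matrix of post
#'   burn-in means).
#' @export
summarizeComponents <- function(fit) {
  if (is.list(fit)) {
    parts <- lapply(fit, summarizeComponents)
    return(list(
      perIteration = parts[[1]]$perIteration,
      meanCounts = Reduce(`+`, lapply(parts, `[[`, "meanCounts")) /
        length(parts)))
  }
  bt <- fit@betaTrace
  keep <- fit@traces$retained
  mean3 <- apply(bt[keep, , , drop = FALSE], c(2, 3), mean)
  list(perIteration = bt, meanCounts = mean3)
}
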