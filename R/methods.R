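#' Accessors for genotype containers
#'
#' @param x a [GenotypeData-class] or [ScaledDesign-class] object.
#' @return \code{nMarkers}/\code{nSamples} return integer counts;
#'   \code{markerInfo} the marker map data.frame; \code{alleleFreq} the
#'   counted-allele frequencies; \code{genotypes} the raw 0/1/2 matrix;
#'   \code{designMatrix} the scaled/centred matrix V.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@genotypes))
#' @rdname accessors
#' @export
setMethod("nMarkers", "ScaledDesign", function(x) ncol(x@V))
#' @rdname accessors
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@genotypes))
#' @rdname accessors
#' @export
setMethod("nSamples", "ScaledDesign", function(x) nrow(x@V))
#' @rdname accessors
#' @export
setMethod("markerInfo", "GenotypeData", function(x) x@markers)
#' @rdname accessors
#' @export
setMethod("markerInfo", "ScaledDesign", function(x) x@markers)
#' @rdname accessors
#' @export
setMethod("alleleFreq", "GenotypeData", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("alleleFreq", "ScaledDesign", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypeData", function(x) x@genotypes)
#' @rdname accessors
#' @export
setMethod("designMatrix", "ScaledDesign", function(x) x@V)

#' Accessors for fitted chains
#'
#' @param x a [ChainFit-class] or [MultiTraitFit-class] object.
#' @return \code{markerEffects}: posterior-mean SNP effects;
#'   \code{inclusionProb}: per-marker posterior inclusion probability;
#'   \code{varianceTraces}: per-outer-cycle variance trace data.frame;
#'   \code{heritability}: posterior mean of sigma_g^2/(sigma_g^2+sigma_e^2)
#'   over retained cycles.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setMethod("markerEffects", "ChainFit", function(x) x@gMean)
#' @rdname fit-accessors
#' @export
setMethod("inclusionProb", "ChainFit", function(x) x@pp)
#' @rdname fit-accessors
#' @export
setMethod("inclusionProb", "MultiTraitFit", function(x) x@jpp)
#' @rdname fit-accessors
#' @export
setMethod("varianceTraces", "ChainFit", function(x) x@traces)
#' @rdname fit-accessors
#' @export
setMethod("heritability", "ChainFit", function(x) {
  tr <- x@traces
  keep <- tr$retained
  mean(tr$h2[keep])
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nSamples(object), "individuals x",
      nMarkers(object), "markers\n")
  nmiss <- sum(is.na(object@genotypes))
  cat("  missing genotypes:", nmiss, "\n")
  if (length(object@p))
    cat("  allele freq range: [",
        format(min(object@p), digits = 4), ", ",
        format(max(object@p), digits = 4), "]\n", sep = "")
})

setMethod("show", "ScaledDesign", function(object) {
  cat("ScaledDesign:", nSamples(object), "individuals x",
      nMarkers(object), "retained markers\n")
})

setMethod("show", "TraitData", function(object) {
  nw <- sum(object@w != 0)
  cat("TraitData:", length(object@y), "records (", nw, "with non-zero",
      "weight )\n")
  cat("  fixed effects:", ncol(object@X),
      " | sigma_t^2 =", format(object@sigmaT2, digits = 5),
      " | h2 guess =", object@h2Guess, "\n")
})

setMethod("show", "MixturePrior", function(object) {
  cat("MixturePrior:", length(object@alloc), "components, alloc = (",
      paste(format(object@alloc), collapse = ", "), ")\n")
  cat("  classes:", object@nClasses, "\n")
})

setMethod("show", "BlockPlan", function(object) {
  cat("BlockPlan: block size n =", object@blockSize,
      "| blocks =", object@nBlocks,
      "| outer cycles m =", object@nOuter, "\n")
  cat("  chain length m x n =", object@chainLength,
      "| schedule rate s_r =", object@scheduleRate, "\n")
})

setMethod("show", "ChainFit", function(object) {
  cat("ChainFit:", length(object@gMean), "markers,",
      object@nRetained, "retained samples per marker\n")
  cat("  posterior-mean h2 =", format(heritability(object), digits = 4),
      "| markers in model (last cycle) =",
      tail(object@traces$nm, 1), "\n")
})

setMethod("show", "MultiTraitFit", function(object) {
  cat("MultiTraitFit:", length(object@perTrait), "traits,",
      length(object@jpp), "markers\n")
  cat("  mean P(J=1) =", format(mean(object@jpp), digits = 4), "\n")
})
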