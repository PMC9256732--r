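#' @import methods
#' @importFrom stats rnorm runif rchisq rgamma rbinom var cor sd prcomp
#'   coef lm setNames
#' @importFrom utils head tail
NULL

#' Raw genotype container
#'
#' Holds per-individual, per-marker allele counts on the 0/1/2 coding
#' (counted allele = PLINK A1), a marker map, and per-marker observed
#' allele frequencies of the counted allele computed over non-missing
#' entries only.
#'
#' @slot genotypes numeric matrix, individuals x markers, entries in
#'   \{0, 1, 2, NA\}.
#' @slot sampleIds character vector of individual identifiers.
#' @slot markers data.frame with columns \code{chrom}, \code{id},
#'   \code{pos} (1-based base-pair position), \code{A1}, \code{A2}.
#' @slot p numeric vector of observed counted-allele frequencies.
#'
#' @seealso [readDosage()], [readPlink()], [filterMAF()], [scaleCenter()]
#' @export
setClass("GenotypeData",
  representation(
    genotypes = "matrix",
    sampleIds = "character",
    markers   = "data.frame",
    p         = "numeric"
  )
)

setValidity("GenotypeData", function(object) {
  g <- object@genotypes
  msg <- character()
  if (nrow(g) != length(object@sampleIds))
    msg <- c(msg, "number of rows must equal length(sampleIds)")
  if (ncol(g) != nrow(object@markers))
    msg <- c(msg, "number of columns must equal nrow(markers)")
  if (ncol(g) != length(object@p))
    msg <- c(msg, "length(p) must equal the number of markers")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    msg <- c(msg, "non-missing genotypes must be 0, 1 or 2")
  if (length(object@p) && (any(object@p < 0) || any(object@p > 1)))
    msg <- c(msg, "allele frequencies must lie in [0, 1]")
  if (anyDuplicated(object@markers$id))
    msg <- c(msg, "marker ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Scaled and centred genotype design matrix
#'
#' The design matrix V of the mixed model y = Xu + Vg + Za + e, with
#' columns v_ij = (v*_ij - 2 p_j) / sqrt(2 p_j (1 - p_j)). Missing
#' genotypes are imputed to the column mean 2 p_j before scaling, so they
#' scale to exactly 0. Training allele frequencies are retained so that
#' validation individuals can be scaled consistently.
#'
#' @slot V numeric matrix of scaled genotypes.
#' @slot keptIndex integer positions of retained markers in the source
#'   [GenotypeData-class].
#' @slot p training allele frequencies of the retained markers.
#' @slot markers marker map of the retained markers.
#' @slot sampleIds individual identifiers (row order of V).
#'
#' @export
setClass("ScaledDesign",
  representation(
    V         = "matrix",
    keptIndex = "integer",
    p         = "numeric",
    markers   = "data.frame",
    sampleIds = "character"
  )
)

setValidity("ScaledDesign", function(object) {
  msg <- character()
  if (ncol(object@V) != length(object@keptIndex))
    msg <- c(msg, "keptIndex must index the columns of V")
  if (is.unsorted(object@keptIndex, strictly = TRUE))
    msg <- c(msg, "keptIndex must be strictly increasing")
  if (ncol(object@V) != length(object@p))
    msg <- c(msg, "length(p) must equal the number of retained markers")
  if (length(msg)) msg else TRUE
})

#' Phenotype records for one trait
#'
#' Phenotypes aligned to the genotype row order, per-record non-negative
#' weights (the diagonal of W; a zero weight drops the record from all
#' variance computations, which is also how missing trait values are
#' encoded), the fixed-effect incidence matrix X (an intercept column is
#' always present), a user heritability guess, and the weighted
#' phenotypic variance sigma_t^2 used to initialise the variance
#' components.
#'
#' @slot y numeric phenotype vector.
#' @slot w numeric non-negative weights.
#' @slot X numeric fixed-effect incidence matrix.
#' @slot h2Guess heritability guess in [0, 1].
#' @slot sigmaT2 weighted phenotypic variance (see
#'   [weightedTraitVariance()]).
#' @slot sampleIds individual identifiers.
#'
#' @export
setClass("TraitData",
  representation(
    y        = "numeric",
    w        = "numeric",
    X        = "matrix",
    h2Guess  = "numeric",
    sigmaT2  = "numeric",
    sampleIds = "character"
  )
)

setValidity("TraitData", function(object) {
  msg <- character()
  n <- length(object@y)
  if (length(object@w) != n) msg <- c(msg, "length(w) must equal length(y)")
  if (nrow(object@X) != n) msg <- c(msg, "nrow(X) must equal length(y)")
  if (any(object@w < 0)) msg <- c(msg, "weights must be non-negative")
  if (object@h2Guess < 0 || object@h2Guess > 1)
    msg <- c(msg, "h2Guess must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Normal-mixture prior on SNP effects
#'
#' The spike-and-slab prior: g_j ~ sum_k pi_k N(0, a_k sigma_g^2) with
#' allocation scalars a = (0, 1e-4, 1e-3, 1e-2) by default (any number of
#' components >= 2 is allowed; the first must be the zero spike). With
#' more than one marker class the mixing proportions pi are estimated
#' separately per class (BayesRC); one class is plain BayesR.
#'
#' @slot alloc strictly increasing allocation scalars, alloc[1] = 0.
#' @slot alpha Dirichlet concentration, one row per class.
#' @slot snpClass integer class label per marker (all 1 for BayesR).
#' @slot nClasses number of marker classes.
#'
#' @export
setClass("MixturePrior",
  representation(
    alloc    = "numeric",
    alpha    = "matrix",
    snpClass = "integer",
    nClasses = "integer"
  )
)

setValidity("MixturePrior", function(object) {
  msg <- character()
  if (object@alloc[1] != 0)
    msg <- c(msg, "alloc[1] must be 0 (the spike)")
  if (is.unsorted(object@alloc, strictly = TRUE))
    msg <- c(msg, "alloc must be strictly increasing")
  if (any(object@alpha <= 0))
    msg <- c(msg, "alpha must be positive")
  if (ncol(object@alpha) != length(object@alloc))
    msg <- c(msg, "alpha must have one column per mixture component")
  if (nrow(object@alpha) != object@nClasses)
    msg <- c(msg, "alpha must have one row per class")
  if (length(object@snpClass) &&
      (any(object@snpClass < 1L) || any(object@snpClass > object@nClasses)))
    msg <- c(msg, "snpClass labels must lie in 1..nClasses")
  if (length(msg)) msg else TRUE
})

#' Block decomposition and sampling schedule
#'
#' Markers are partitioned into sequential blocks of size n (the last
#' block may be smaller but still receives n inner cycles, so every
#' marker is sampled m x n times). The schedule rate s_r controls how
#' often the auxiliary quantities (fixed effects, polygenic effects,
#' sigma_e^2) are re-sampled: after every s_r-th block.
#'
#' @slot blockSize inner-cycle count n (= nominal markers per block).
#' @slot nBlocks number of blocks, ceiling(n_M / n).
#' @slot bounds integer matrix (nBlocks x 2) of 1-based inclusive
#'   first/last marker indices per block.
#' @slot nOuter outer cycles m.
#' @slot chainLength samples per marker, m x n.
#' @slot scheduleRate s_r = max(round(n_M / n^2), 1).
#'
#' @export
setClass("BlockPlan",
  representation(
    blockSize    = "integer",
    nBlocks      = "integer",
    bounds       = "matrix",
    nOuter       = "integer",
    chainLength  = "integer",
    scheduleRate = "integer"
  )
)

setValidity("BlockPlan", function(object) {
  msg <- character()
  b <- object@bounds
  if (nrow(b) != object@nBlocks)
    msg <- c(msg, "bounds must have one row per block")
  if (nrow(b)) {
    if (b[1, 1] != 1L) msg <- c(msg, "first block must start at marker 1")
    if (nrow(b) > 1 && any(b[-1, 1] != b[-nrow(b), 2] + 1L))
      msg <- c(msg, "blocks must tile the markers without gaps or overlap")
    sizes <- b[, 2] - b[, 1] + 1L
    if (nrow(b) > 1 && any(sizes[-nrow(b)] != object@blockSize))
      msg <- c(msg, "all blocks except possibly the last must have size n")
  }
  if (object@chainLength != object@nOuter * object@blockSize)
    msg <- c(msg, "chainLength must equal nOuter * blockSize")
  if (length(msg)) msg else TRUE
})

#' Posterior summaries from one MCMC chain
#'
#' @slot gMean posterior-mean marker effect (post burn-in), on the scaled
#'   genotype scale.
#' @slot pp per-marker posterior inclusion probability: fraction of
#'   retained samples with a non-zero component (or J = 1 when produced
#'   by the multi-trait sampler).
#' @slot componentFreq markers x components matrix of per-marker
#'   component occupancy frequencies (rows sum to 1).
#' @slot traces data.frame with one row per outer cycle: sigmaE2,
#'   sigmaG2, h2 (= sigmaG2/(sigmaG2+sigmaE2)), nm (markers in model).
#' @slot betaTrace outer cycles x (class, component) counts of markers
#'   per mixture component.
#' @slot nRetained number of post burn-in samples per marker.
#' @slot plan the [BlockPlan-class] used.
#' @slot finalState list of final u, g, a, e, k, pi, variances.
#' @slot residualCheck per-outer-cycle max absolute deviation of the
#'   running residuals from y - Xu - Vg - Za (empty unless requested).
#' @slot seed integer seed the chain was run with.
#'
#' @export
setClass("ChainFit",
  representation(
    gMean         = "numeric",
    pp            = "numeric",
    componentFreq = "matrix",
    traces        = "data.frame",
    betaTrace     = "array",
    nRetained     = "integer",
    plan          = "BlockPlan",
    finalState    = "list",
    residualCheck = "numeric",
    seed          = "integer"
  )
)

#' Posterior summaries from a multi-trait chain
#'
#' @slot perTrait list of [ChainFit-class], one per (decorrelated) trait.
#' @slot jpp per-marker posterior probability of inclusion in the model
#'   (fraction of retained samples with J = 1).
#' @slot piStarTrace outer cycles x 2 matrix of sampled (P(J=0), P(J=1)).
#' @slot seed integer seed.
#'
#' @export
setClass("MultiTraitFit",
  representation(
    perTrait    = "list",
    jpp         = "numeric",
    piStarTrace = "matrix",
    seed        = "integer"
  )
)
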