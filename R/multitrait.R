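## Multi-trait model: trait decorrelation, the shared model-inclusion
## indicator J, its Beta-updated prior pi*, and the multi-trait chain
## driver.

#' Decorrelate traits by principal components
#'
#' The multi-trait model assumes uncorrelated traits (the genetic and
#' residual covariances are taken proportional), so raw traits are
#' replaced by their leading principal components: column-centred
#' scores, keeping the smallest leading set whose cumulative variance
#' reaches \code{threshold} (default 0.99).
#'
#' @param Y records x traits matrix (complete for retained records).
#' @param threshold variance fraction to retain, in (0, 1].
#' @return list with \code{scores} (records x kept components),
#'   \code{loadings} (rotation, traits x kept), \code{varianceExplained}
#'   (per-component fraction) and \code{nKept}.
#' @export
decorrelateTraits <- function(Y, threshold = 0.99) {
  Y <- as.matrix(Y)
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(Y) < ncol(Y) && threshold >= 1)
    warning("fewer records than traits: components beyond the record ",
            "count carry no variance")
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  nKept <- which(cumsum(ve) >= threshold - 1e-12)[1]
  list(scores = pc$x[, seq_len(nKept), drop = FALSE],
       loadings = pc$rotation[, seq_len(nKept), drop = FALSE],
       varianceExplained = ve[seq_len(nKept)],
       nKept = nKept)
}

#' Inclusion probability of a marker across traits
#'
#' Computes p = 1 / (1 + exp(p(gBar|J=0) - p(gBar|J=1))) with
#' p(gBar|J=0) = log pi*_0 + sum_t log L_{t,1} and
#' p(gBar|J=1) = log pi*_1 + sum_t log sum_k L_{t,k} pi_{t,k}, where
#' L_{t,k} = sqrt(v_{t,k}) exp(-0.5 v_{t,k} gBar_t^2) and
#' v_{t,k} = 1 / (sigma_k^2 + sigma_e^2) for trait t. A zero pi*
#' component selects the other state deterministically.
#'
#' @param gBars per-trait least-squares effect estimates for the marker.
#' @param piStar 2-vector (P(J=0), P(J=1)).
#' @param piTrait list (per trait) of mixing-proportion vectors.
#' @param sigmaK2 list (per trait) of component variances.
#' @param sigmaE2 per-trait residual variances.
#' @return the probability that J = 1.
#' @export
inclusionProbability <- function(gBars, piStar, piTrait, sigmaK2,
                                 sigmaE2) {
  p0 <- if (piStar[1] > 0) log(piStar[1]) else -Inf
  p1 <- if (piStar[2] > 0) log(piStar[2]) else -Inf
  for (t in seq_along(gBars)) {
    v <- 1 / (sigmaK2[[t]] + sigmaE2[t])
    L <- sqrt(v) * exp(-0.5 * v * gBars[t]^2)
    p0 <- p0 + log(L[1])
    p1 <- p1 + log(sum(L * piTrait[[t]]))
  }
  if (!is.finite(p1)) return(0)
  if (!is.finite(p0)) return(1)
  1 / (1 + exp(p0 - p1))
}

#' Sample the shared model-inclusion indicator
#'
#' @inheritParams inclusionProbability
#' @return integer J in \{0, 1\}.
#' @export
sampleModelIndicator <- function(gBars, piStar, piTrait, sigmaK2,
                                 sigmaE2) {
  p <- inclusionProbability(gBars, piStar, piTrait, sigmaK2, sigmaE2)
  as.integer(runif(1) < p)
}

#' Sample pi* from its Beta posterior
#'
#' pi* ~ Beta(alpha* + beta*) where beta* = (markers out of model,
#' markers in model); sampled at the end of each outer iteration.
#'
#' @param betaStar 2-vector of counts (out, in).
#' @param alphaStar Beta prior, default (1, 1).
#' @return 2-vector (P(J=0), P(J=1)).
#' @export
samplePiStar <- function(betaStar, alphaStar = c(1, 1)) {
  stopifnot(length(betaStar) == 2, all(betaStar >= 0))
  p0 <- rbeta(1, alphaStar[1] + betaStar[1], alphaStar[2] + betaStar[2])
  c(p0, 1 - p0)
}

#' Run a multi-trait blocked Gibbs chain
#'
#' Blocked processing as in [runChain()], but before each marker's
#' per-trait updates the shared inclusion indicator J is sampled from
#' all traits' least-squares estimates; with J = 0 the marker's effect
#' on every trait is zeroed (with right-hand-side corrections), with
#' J = 1 each trait's component and effect are sampled independently as
#' in the single-trait case. pi* starts at (0.95, 0.05) and is
#' Beta-updated at the end of every outer cycle. Traits are assumed
#' uncorrelated; see [decorrelateTraits()].
#'
#' @param design a [ScaledDesign-class] shared by all traits.
#' @param traits list of [TraitData-class], one per (decorrelated)
#'   trait.
#' @param prior a [MixturePrior-class] (shared across traits).
#' @param blockSize,chainLength,nOuter,burnIn,seed,componentLikelihood,sigmaGUpdate,verbose
#'   as in [runChain()].
#' @param piStarInit initial (P(J=0), P(J=1)).
#' @param alphaStar Beta prior on pi*.
#' @return a [MultiTraitFit-class].
#' @export
runMultiTraitChain <- function(design, traits, prior = mixturePrior(),
                               blockSize = NULL, chainLength = 2000L,
                               nOuter = NULL, burnIn = NULL, seed = NULL,
                               componentLikelihood = c("sampling", "residual"),
                               sigmaGUpdate = c("scaled", "gg"),
                               piStarInit = c(0.95, 0.05),
                               alphaStar = c(1, 1), verbose = FALSE) {
  componentLikelihood <- match.arg(componentLikelihood)
  sigmaGUpdate <- match.arg(sigmaGUpdate)
  if (!length(traits)) stop("need at least one trait")
  V <- designMatrix(design)
  nR <- nrow(V); nM <- ncol(V)
  Y <- sapply(traits, function(tr) tr@y)
  W <- sapply(traits, function(tr) tr@w)
  X <- traits[[1]]@X
  h2 <- vapply(traits, function(tr) tr@h2Guess, numeric(1))
  st2 <- vapply(traits, function(tr) tr@sigmaT2, numeric(1))
  if (is.null(blockSize)) blockSize <- defaultBlockSize(nR)
  n <- as.integer(blockSize)
  m <- if (!is.null(nOuter)) as.integer(nOuter)
       else max(1L, as.integer(round(chainLength / n)))
  if (is.null(burnIn)) burnIn <- m %/% 2L
  burnIn <- as.integer(burnIn)
  plan <- makeBlocks(nM, n, nOuter = m)
  snpClass <- prior@snpClass
  if (!length(snpClass)) snpClass <- rep(1L, nM)

  if (!is.null(seed)) set.seed(as.integer(seed)) else seed <- NA_integer_

  res <- cpp_run_mt_chain(V, Y, W, X, plan@bounds, n, m,
                          plan@scheduleRate, prior@alloc, prior@alpha,
                          snpClass, h2, st2, burnIn,
                          componentLikelihood == "sampling",
                          sigmaGUpdate == "scaled",
                          piStarInit, alphaStar, verbose)

  nClass <- prior@nClasses
  K <- length(prior@alloc)
  perTrait <- lapply(seq_along(traits), function(t) {
    rt <- res$perTrait[[t]]
    betaTrace <- rt$betaTrace
    dim(betaTrace) <- c(m, nClass, K)
    se2 <- as.numeric(rt$sigmaE2Trace)
    sg2 <- as.numeric(rt$sigmaG2Trace)
    traces <- data.frame(cycle = seq_len(m),
                         sigmaE2 = se2,
                         sigmaG2 = sg2,
                         h2 = sg2 / (sg2 + se2),
                         nm = as.integer(rt$nmTrace),
                         retained = seq_len(m) > burnIn)
    new("ChainFit",
        gMean = as.numeric(rt$gMean), pp = as.numeric(res$jpp),
        componentFreq = rt$compFreq,
        traces = traces, betaTrace = betaTrace,
        nRetained = as.integer(res$nRetained), plan = plan,
        finalState = list(u = as.numeric(rt$u), g = as.numeric(rt$g),
                          e = as.numeric(rt$e), k = as.integer(rt$k),
                          sigmaE2 = rt$sigmaE2, sigmaG2 = rt$sigmaG2),
        residualCheck = numeric(0), seed = as.integer(seed))
  })
  new("MultiTraitFit", perTrait = perTrait, jpp = as.numeric(res$jpp),
      piStarTrace = res$piStarTrace, seed = as.integer(seed))
}

#' Rotate component-trait effects back to the original trait scale
#'
#' Posterior-mean marker effects estimated on decorrelated component
#' traits are mapped back through the retained loadings:
#' effects_original = effects_components %*% t(loadings).
#'
#' @param fit a [MultiTraitFit-class].
#' @param loadings the rotation returned by [decorrelateTraits()].
#' @return markers x original-traits matrix of effects.
#' @export
backRotateEffects <- function(fit, loadings) {
  gm <- sapply(fit@perTrait, markerEffects)
  gm %*% t(loadings)
}
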