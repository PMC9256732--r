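## Single-trait blocked Gibbs engine: block planning, the printed
## conditional updates as plain R reference functions, and runChain(),
## which drives the compiled sampler.

#' Default block size
#'
#' Block size and inner-cycle count should equal the square root of the
#' number of records, rounded to the nearest integer (e.g. 41,925
#' records give a block size of 205).
#'
#' @param nR number of phenotype records.
#' @return integer block size (>= 1).
#' @export
defaultBlockSize <- function(nR) {
  stopifnot(nR >= 1)
  max(1L, as.integer(round(sqrt(nR))))
}

#' Partition markers into sequential blocks
#'
#' n_B = ceiling(n_M / n) non-overlapping blocks of size n; the last
#' block may be smaller but still undergoes n inner cycles so that every
#' marker is sampled m x n times.
#'
#' @param nM number of markers.
#' @param n block size (= inner cycles).
#' @param nOuter outer cycles m.
#' @return a [BlockPlan-class].
#' @export
makeBlocks <- function(nM, n, nOuter = 1L) {
  stopifnot(nM >= 1, n >= 1, nOuter >= 0)
  n <- as.integer(n)
  nB <- as.integer(ceiling(nM / n))
  starts <- seq.int(1L, nM, by = n)
  ends <- pmin(starts + n - 1L, as.integer(nM))
  new("BlockPlan", blockSize = n, nBlocks = nB,
      bounds = cbind(start = as.integer(starts), end = as.integer(ends)),
      nOuter = as.integer(nOuter),
      chainLength = as.integer(nOuter) * n,
      scheduleRate = scheduleRate(nM, n))
}

#' Auxiliary sampling rate
#'
#' s_r = max(round(n_M / n^2), 1): after every s_r-th block the fixed
#' effects, polygenic effects and sigma_e^2 are re-sampled, so that over
#' one outer cycle they are sampled about n times, matching the SNP
#' effects. sigma_a^2, sigma_g^2 and the Dirichlet updates fire only at
#' the end of each outer cycle.
#'
#' @param nM number of markers.
#' @param n block size.
#' @return integer rate.
#' @export
scheduleRate <- function(nM, n) {
  stopifnot(n >= 1)
  max(1L, as.integer(round(nM / n^2)))
}

#' Weighted phenotypic variance
#'
#' sigma_t^2 = sum((y_i - xbar)^2 / (h2 + (1 - h2)/w_i)) / (n_W - 1)
#' over records with non-zero weight, where xbar is the weighted mean
#' and n_W the number of non-zero weights. With unit weights this is the
#' ordinary sample variance for any h2.
#'
#' @param y phenotypes.
#' @param w non-negative weights.
#' @param h2 heritability guess in [0, 1].
#' @return the weighted phenotypic variance.
#' @export
weightedTraitVariance <- function(y, w = rep(1, length(y)), h2 = 0.5) {
  stopifnot(length(y) == length(w), h2 >= 0, h2 <= 1)
  nz <- w != 0
  nW <- sum(nz)
  if (nW < 2) stop("need at least 2 records with non-zero weight")
  xbar <- sum(y[nz] * w[nz]) / sum(w[nz])
  sum((y[nz] - xbar)^2 / (h2 + (1 - h2) / w[nz])) / (nW - 1)
}

#' Block right-hand side on entry
#'
#' r_b = V_b' W e, the weighted cross-product of the block's genotype
#' columns with the current residuals.
#'
#' @param Vb block design columns (records x block size).
#' @param w weights.
#' @param e current residuals.
#' @return numeric vector of length ncol(Vb).
#' @export
blockEnterRhs <- function(Vb, w, e) {
  as.numeric(crossprod(Vb, w * e))
}

#' One conditional SNP-effect draw
#'
#' The printed conditional posterior: first the component indicator k is
#' drawn (see [sampleComponent()]); with k = 1 the effect becomes 0,
#' otherwise g ~ N((r_bj + d_jj g_old)/(d_jj + kappa),
#' sigma_e^2/(d_jj + kappa)) with kappa = sigma_e^2 / sigma_k^2. The
#' block right-hand side is then corrected by
#' r_b <- r_b + (V_b'WV_b)_{.j} (g_old - g_new).
#'
#' @param rbj j-th element of the block right-hand side.
#' @param djj diagonal element (V_b'WV_b)_jj.
#' @param gOld current effect.
#' @param pi mixing proportions for the marker's class.
#' @param sigmaK2 component variances.
#' @param sigmaE2 residual variance.
#' @param likelihood component-likelihood form, see [sampleComponent()].
#' @return list with elements \code{k}, \code{g} (new effect) and
#'   \code{gBar} (the least-squares estimate used).
#' @export
sampleSnpEffect <- function(rbj, djj, gOld, pi, sigmaK2, sigmaE2,
                            likelihood = c("sampling", "residual")) {
  likelihood <- match.arg(likelihood)
  if (djj <= 0) stop("non-positive diagonal element")
  gBar <- (rbj + djj * gOld) / djj
  k <- sampleComponent(gBar, pi, sigmaK2, sigmaE2, djj, likelihood)
  if (k == 1L) {
    g <- 0
  } else {
    kappa <- sigmaE2 / sigmaK2[k]
    denom <- djj + kappa
    if (sigmaE2 / denom <= 0) stop("non-positive posterior variance")
    g <- (rbj + djj * gOld) / denom + sqrt(sigmaE2 / denom) * rnorm(1)
  }
  list(k = k, g = g, gBar = gBar)
}

#' Residual update on block exit
#'
#' e <- e - V_b (g_new - g_entry), restoring the residual identity
#' e = y - Xu - Vg - Za after the block's inner cycles.
#'
#' @param e residual vector.
#' @param Vb block design columns.
#' @param gNew block effects after the inner cycles.
#' @param gEntry block effects on entry.
#' @return updated residual vector.
#' @export
blockExitUpdate <- function(e, Vb, gNew, gEntry) {
  as.numeric(e - Vb %*% (gNew - gEntry))
}

#' Sequential Gibbs update of the fixed effects
#'
#' Each fixed effect is drawn from
#' u_f ~ N((X_f'We + X_f'WX_f u_f)/(X_f'WX_f), sigma_e^2/(X_f'WX_f))
#' with the residuals corrected immediately.
#'
#' @param u current fixed effects.
#' @param e current residuals.
#' @param X fixed-effect incidence matrix.
#' @param w weights.
#' @param sigmaE2 residual variance.
#' @return list with updated \code{u} and \code{e}.
#' @export
sampleFixedEffects <- function(u, e, X, w, sigmaE2) {
  for (f in seq_along(u)) {
    xwx <- sum(X[, f]^2 * w)
    if (xwx <= 0) stop("empty or collinear fixed-effect column ", f)
    m <- (sum(X[, f] * w * e) + xwx * u[f]) / xwx
    uNew <- m + sqrt(sigmaE2 / xwx) * rnorm(1)
    e <- e - X[, f] * (uNew - u[f])
    u[f] <- uNew
  }
  list(u = u, e = e)
}

#' Element-wise Gibbs update of the polygenic effects
#'
#' a_i ~ N(((Z'We)_i - (A^{-1} lambda a)_i) / (w_i + A^{-1}_{ii} lambda)
#' + a_i, sigma_e^2 / (w_i + A^{-1}_{ii} lambda)) with Z = I and
#' lambda = sigma_e^2 / sigma_a^2, residuals corrected per element.
#'
#' @param a current polygenic effects.
#' @param e current residuals.
#' @param w weights.
#' @param Ainv inverse relationship matrix.
#' @param sigmaE2 residual variance.
#' @param sigmaA2 polygenic variance.
#' @return list with updated \code{a} and \code{e}.
#' @export
samplePolygenic <- function(a, e, w, Ainv, sigmaE2, sigmaA2) {
  n <- length(a)
  if (!is.matrix(Ainv) || nrow(Ainv) != n || ncol(Ainv) != n)
    stop("Ainv must be a square matrix matching the number of records")
  lambda <- sigmaE2 / sigmaA2
  for (i in seq_len(n)) {
    den <- w[i] + Ainv[i, i] * lambda
    m <- (w[i] * e[i] - lambda * sum(Ainv[i, ] * a)) / den + a[i]
    aNew <- m + sqrt(sigmaE2 / den) * rnorm(1)
    e[i] <- e[i] - (aNew - a[i])
    a[i] <- aNew
  }
  list(a = a, e = e)
}

#' Draw the variance components
#'
#' sigma_e^2 ~ sum(e_i^2 w_i) / chisq(n_w - 2), and for the genetic
#' variance either \code{"scaled"} (default):
#' sigma_g^2 ~ sum(g_j^2 / a_{k_j}) / chisq(n_m - 2), the conditional
#' posterior under g_j ~ N(0, a_k sigma_g^2), or \code{"gg"}:
#' sigma_g^2 ~ n_m g'g / chisq(n_m - 2), the unscaled sum of squares.
#' n_m is the number of markers currently in the model (k > 1); the
#' genetic-variance update is skipped when n_m <= 2. Component
#' variances are refreshed as a_k sigma_g^2.
#'
#' @param e residuals.
#' @param w weights.
#' @param g marker effects.
#' @param k component indicators.
#' @param alloc allocation scalars.
#' @param sigmaG2 current genetic variance (returned unchanged when the
#'   update is skipped).
#' @param sigmaGUpdate \code{"scaled"} (default) or \code{"gg"}.
#' @return list with \code{sigmaE2}, \code{sigmaG2}, \code{sigmaK2} and
#'   \code{nm}.
#' @export
sampleVariances <- function(e, w, g, k, alloc, sigmaG2,
                            sigmaGUpdate = c("scaled", "gg")) {
  sigmaGUpdate <- match.arg(sigmaGUpdate)
  nW <- sum(w != 0)
  if (nW <= 2) stop("need more than 2 non-zero weights")
  sigmaE2 <- sum(e^2 * w) / rchisq(1, nW - 2)
  nm <- sum(k > 1)
  if (nm > 2) {
    ss <- if (sigmaGUpdate == "gg") nm * sum(g^2)
          else sum(g[k > 1]^2 / alloc[k[k > 1]])
    sigmaG2 <- ss / rchisq(1, nm - 2)
  }
  list(sigmaE2 = sigmaE2, sigmaG2 = sigmaG2,
       sigmaK2 = componentVariances(sigmaG2, alloc), nm = nm)
}

#' Run one blocked Gibbs chain
#'
#' Fits the mixed model y = Xu + Vg (+ Za) + e with the normal-mixture
#' prior on g by blocked Gibbs sampling with residual updating: on block
#' entry the right-hand sides r_b = V_b'We and the block cross-product
#' V_b'WV_b are formed, the block's effects are swept n times (each
#' sweep re-sampling the component indicator and the effect of every
#' marker in the block), and on exit the residuals are corrected.
#' Auxiliary quantities (fixed effects, polygenic effects, sigma_e^2)
#' are re-sampled after every s_r-th block; sigma_a^2, sigma_g^2 and the
#' mixing proportions at the end of each outer cycle.
#'
#' Initialisation: e = y, u = 0, g = 0, sigma_e^2 = sigma_t^2 (1 - h2),
#' sigma_g^2 = sigma_t^2 h2 (x 0.9 with the polygenic term on, the
#' remaining 0.1 going to sigma_a^2), pi = 1/K per class.
#'
#' @param design a [ScaledDesign-class].
#' @param trait a [TraitData-class].
#' @param prior a [MixturePrior-class].
#' @param blockSize block size n; default [defaultBlockSize()] of the
#'   record count.
#' @param chainLength target samples per marker n_L; the outer-cycle
#'   count is m = round(n_L / n) (ignored when \code{nOuter} is given).
#' @param nOuter outer cycles m.
#' @param burnIn outer cycles discarded (default: first half).
#' @param seed integer seed for the chain (set with \code{set.seed}).
#' @param componentLikelihood \code{"sampling"} (default; v_k =
#'   sigma_k^2 + sigma_e^2/d_jj) or \code{"residual"} (v_k = sigma_k^2
#'   + sigma_e^2), see [sampleComponent()].
#' @param sigmaGUpdate \code{"scaled"} (default) or \code{"gg"}, see
#'   [sampleVariances()].
#' @param polygenic logical; fit the polygenic term Za (off by
#'   default).
#' @param Ainv inverse relationship matrix for the polygenic term
#'   (identity if NULL and \code{polygenic = TRUE}).
#' @param checkResiduals logical; recompute y - Xu - Vg - Za at the end
#'   of every outer cycle and record the maximum deviation from the
#'   running residuals (costly; for diagnostics).
#' @param verbose print per-outer-cycle sigma_e^2, sigma_g^2 and n_m.
#' @return a [ChainFit-class].
#' @examples
#' sim <- simulateDataset(nInd = 200, nSnp = 300,
#'                        qtnCounts = c(1, 3, 6), h2 = 0.3, seed = 1)
#' fit <- runChain(sim$design, sim$trait, chainLength = 200, seed = 1)
#' heritability(fit)
#' @export
runChain <- function(design, trait, prior = mixturePrior(),
                     blockSize = NULL, chainLength = 2000L, nOuter = NULL,
                     burnIn = NULL, seed = NULL,
                     componentLikelihood = c("sampling", "residual"),
                     sigmaGUpdate = c("scaled", "gg"),
                     polygenic = FALSE, Ainv = NULL,
                     checkResiduals = FALSE, verbose = FALSE) {
  componentLikelihood <- match.arg(componentLikelihood)
  sigmaGUpdate <- match.arg(sigmaGUpdate)
  V <- designMatrix(design)
  nR <- nrow(V); nM <- ncol(V)
  stopifnot(length(trait@y) == nR)
  if (is.null(blockSize)) blockSize <- defaultBlockSize(nR)
  n <- as.integer(blockSize)
  m <- if (!is.null(nOuter)) as.integer(nOuter)
       else max(1L, as.integer(round(chainLength / n)))
  if (is.null(burnIn)) burnIn <- m %/% 2L
  burnIn <- as.integer(burnIn)
  stopifnot(burnIn >= 0, burnIn <= m)
  plan <- makeBlocks(nM, n, nOuter = m)

  snpClass <- prior@snpClass
  if (!length(snpClass)) snpClass <- rep(1L, nM)
  stopifnot(length(snpClass) == nM)

  if (polygenic && is.null(Ainv)) Ainv <- diag(nR)
  if (!polygenic) Ainv <- matrix(0, 1, 1)

  if (!is.null(seed)) set.seed(as.integer(seed)) else seed <- NA_integer_

  res <- cpp_run_chain(V, trait@y, trait@w, trait@X, plan@bounds,
                       n, m, plan@scheduleRate,
                       prior@alloc, prior@alpha, snpClass,
                       trait@h2Guess, trait@sigmaT2, burnIn,
                       componentLikelihood == "sampling",
                       sigmaGUpdate == "scaled",
                       polygenic, Ainv, checkResiduals, verbose)

  nClass <- prior@nClasses
  K <- length(prior@alloc)
  betaTrace <- res$betaTrace
  dim(betaTrace) <- c(m, nClass, K)
  se2 <- as.numeric(res$sigmaE2Trace)
  sg2 <- as.numeric(res$sigmaG2Trace)
  traces <- data.frame(cycle = seq_len(m),
                       sigmaE2 = se2,
                       sigmaG2 = sg2,
                       h2 = sg2 / (sg2 + se2),
                       nm = as.integer(res$nmTrace),
                       retained = seq_len(m) > burnIn)
  new("ChainFit",
      gMean = as.numeric(res$gMean), pp = as.numeric(res$pp),
      componentFreq = res$compFreq,
      traces = traces, betaTrace = betaTrace,
      nRetained = as.integer(res$nRetained), plan = plan,
      finalState = list(u = as.numeric(res$u), g = as.numeric(res$g),
                        a = as.numeric(res$a), e = as.numeric(res$e),
                        k = as.integer(res$k), pi = res$pi,
                        sigmaE2 = res$sigmaE2, sigmaG2 = res$sigmaG2,
                        sigmaA2 = res$sigmaA2),
      residualCheck = as.numeric(res$residCheck),
      seed = as.integer(seed))
}

#' Run several independent chains
#'
#' Chains are run sequentially with seeds \code{seed + 0:(nChains-1)}
#' (they are embarrassingly parallel; a deterministic per-chain seed
#' keeps results reproducible).
#'
#' @inheritParams runChain
#' @param nChains number of chains.
#' @param seed base seed.
#' @param ... passed to [runChain()].
#' @return list of [ChainFit-class] objects.
#' @seealso [combineChains()], [chainCorrelation()]
#' @export
runChains <- function(design, trait, nChains = 5L, seed = 1L, ...) {
  lapply(seq_len(nChains) - 1L,
         function(i) runChain(design, trait, seed = seed + i, ...))
}
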