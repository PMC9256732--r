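# Independent single-site BayesR sampler written directly from the
# conditional distributions, maintaining the full residual vector (no
# block right-hand-side machinery). With block size 1 and one inner
# cycle the blocked engine must reproduce it draw for draw, because
# both consume the same RNG stream in the same order.
refSingleSiteChain <- function(V, y, w, X, alloc, alphaMat, snpClass,
                               h2Guess, sigmaT2, nOuter,
                               samplingLik = TRUE, scaledSigmaG = TRUE) {
  nR <- nrow(V); nM <- ncol(V); K <- length(alloc)
  nClass <- nrow(alphaMat)
  e <- y
  u <- rep(0, ncol(X))
  g <- numeric(nM)
  k <- rep(1L, nM)
  sigmaE2 <- sigmaT2 * (1 - h2Guess)
  sigmaG2 <- sigmaT2 * h2Guess
  sigmaK2 <- alloc * sigmaG2
  pimat <- matrix(1 / K, nClass, K)
  xwx <- colSums(X^2 * w)
  nW <- sum(w != 0)
  sr <- max(1L, as.integer(round(nM / 1)))
  counter <- 0L
  sigmaE2Tr <- sigmaG2Tr <- numeric(nOuter)
  nmTr <- integer(nOuter)
  for (l in seq_len(nOuter)) {
    for (j in seq_len(nM)) {
      vj <- V[, j]
      d <- sum(vj^2 * w)
      rb <- sum(vj * w * e)
      gOld <- g[j]
      gBar <- (rb + d * gOld) / d
      cls <- snpClass[j]
      v <- sigmaK2 + if (samplingLik) sigmaE2 / d else sigmaE2
      logp <- log(pimat[cls, ]) - 0.5 * gBar^2 / v - 0.5 * log(v)
      logp[pimat[cls, ] <= 0] <- -Inf
      p <- exp(logp - max(logp))
      p <- p / sum(p)
      x <- runif(1)
      kj <- which(cumsum(p) >= x)[1]
      k[j] <- kj
      if (kj == 1L) {
        gNew <- 0
      } else {
        kap <- sigmaE2 / sigmaK2[kj]
        gNew <- (rb + d * gOld) / (d + kap) +
          sqrt(sigmaE2 / (d + kap)) * rnorm(1)
      }
      g[j] <- gNew
      e <- e - vj * (gNew - gOld)
      counter <- counter + 1L
      if (counter %% sr == 0L) {
        for (f in seq_along(u)) {
          m0 <- (sum(X[, f] * w * e) + xwx[f] * u[f]) / xwx[f]
          uNew <- m0 + sqrt(sigmaE2 / xwx[f]) * rnorm(1)
          e <- e - X[, f] * (uNew - u[f])
          u[f] <- uNew
        }
        sigmaE2 <- sum(e^2 * w) / rchisq(1, nW - 2)
      }
    }
    beta <- matrix(0, nClass, K)
    for (j in seq_len(nM)) beta[snpClass[j], k[j]] <- beta[snpClass[j], k[j]] + 1
    nm <- sum(k > 1L)
    if (nm > 2) {
      ss <- if (scaledSigmaG) sum(g[k > 1]^2 / alloc[k[k > 1]])
            else nm * sum(g^2)
      sigmaG2 <- ss / rchisq(1, nm - 2)
    }
    sigmaK2 <- alloc * sigmaG2
    for (cl in seq_len(nClass)) {
      gd <- rgamma(K, shape = alphaMat[cl, ] + beta[cl, ], rate = 1)
      pimat[cl, ] <- gd / sum(gd)
    }
    sigmaE2Tr[l] <- sigmaE2
    sigmaG2Tr[l] <- sigmaG2
    nmTr[l] <- nm
  }
  list(g = g, e = e, u = u, k = k, pi = pimat,
       sigmaE2Trace = sigmaE2Tr, sigmaG2Trace = sigmaG2Tr, nm = nmTr)
}

# small simulated design + trait, shared by several test files
makeToy <- function(nInd = 100, nSnp = 60, seed = 42, h2 = 0.4,
                    qtnCounts = c(1, 2, 5), h2Guess = 0.5) {
  simulateDataset(nInd = nInd, nSnp = nSnp, qtnCounts = qtnCounts,
                  h2 = h2, h2Guess = h2Guess, seed = seed)
}
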