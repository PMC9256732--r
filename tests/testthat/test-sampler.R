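test_that("weighted trait variance reduces to the sample variance", {
  set.seed(2)
  y <- rnorm(30)
  expect_equal(weightedTraitVariance(y, rep(1, 30), 0.37), var(y))
  expect_equal(weightedTraitVariance(c(1, 2, 3)), 1)
  # at h2 = 0 each term is (y - xbar)^2 * w, so doubling w doubles it
  w <- runif(30, 0.5, 2)
  expect_equal(weightedTraitVariance(y, 2 * w, h2 = 0),
               2 * weightedTraitVariance(y, w, h2 = 0))
  # zero-weight records are excluded entirely
  y2 <- c(y, 1e6); w2 <- c(w, 0)
  expect_equal(weightedTraitVariance(y2, w2, 0.3),
               weightedTraitVariance(y, w, 0.3))
  expect_error(weightedTraitVariance(c(1, 5), c(1, 0)), "at least 2")
})

test_that("block right-hand side is the weighted cross-product", {
  Vb <- matrix(c(1, 2, -1, 0.5, 1, 3), nrow = 3)
  e <- c(0.2, -1, 0.4)
  w <- c(1, 2, 0.5)
  expect_equal(blockEnterRhs(Vb, w, e * 0), c(0, 0))
  expect_equal(blockEnterRhs(Vb, rep(1, 3), e),
               c(1 * 0.2 + 2 * -1 + -1 * 0.4,
                 0.5 * 0.2 + 1 * -1 + 3 * 0.4))
  expect_equal(blockEnterRhs(Vb, 3 * w, e), 3 * blockEnterRhs(Vb, w, e))
})

test_that("the SNP-effect draw matches its printed conditional", {
  sk2 <- componentVariances(5)
  # spike assignment zeroes the effect
  set.seed(4)
  res <- sampleSnpEffect(0.1, 40, 0.3, c(1, 0, 0, 0), sk2, 2)
  expect_identical(res$k, 1L)
  expect_identical(res$g, 0)
  # fixed rng: returned value equals mean + z * sd evaluated independently
  set.seed(10)
  res <- sampleSnpEffect(3, 40, 0.2, c(0, 0, 0, 1), sk2, 2)
  set.seed(10)
  x <- runif(1); z <- rnorm(1)
  kappa <- 2 / sk2[4]
  expect_identical(res$k, 4L)
  expect_equal(res$g, (3 + 40 * 0.2) / (40 + kappa) +
                 z * sqrt(2 / (40 + kappa)))
  expect_equal(res$gBar, (3 + 40 * 0.2) / 40)
  # kappa -> 0 limit: the posterior mean tends to the least-squares
  # estimate (subtract the captured noise draw to isolate the mean)
  huge <- c(0, 1e8, 1e9, 1e10)
  set.seed(1)
  res <- sampleSnpEffect(3, 40, 0.2, c(0, 0, 0, 1), huge, 2)
  set.seed(1)
  x <- runif(1); z <- rnorm(1)
  kap <- 2 / huge[4]
  expect_equal(res$g - z * sqrt(2 / (40 + kap)), res$gBar,
               tolerance = 1e-6)
})

test_that("block-exit update restores the residual identity", {
  set.seed(6)
  Vb <- matrix(rnorm(12), 4, 3)
  e <- rnorm(4); gE <- rnorm(3); gN <- rnorm(3)
  expect_equal(blockExitUpdate(e, Vb, gE, gE), e)
  expect_equal(blockExitUpdate(e, Vb, gN, gE),
               as.numeric(e - Vb %*% (gN - gE)))
  # single-marker block: e changes by -V[, j] * delta
  e1 <- blockExitUpdate(e, Vb[, 1, drop = FALSE], 2, 0.5)
  expect_equal(e1, e - Vb[, 1] * 1.5)
})

test_that("fixed-effect updates match the printed conditional", {
  set.seed(8)
  X <- cbind(1, rnorm(20))
  w <- runif(20, 0.5, 2)
  e <- rnorm(20); u <- c(0.4, -0.2)
  sE2 <- 1e-12   # vanishing residual variance: deterministic posterior mean
  out <- sampleFixedEffects(u, e, X, w, sE2)
  xwx1 <- sum(X[, 1]^2 * w)
  m1 <- (sum(X[, 1] * w * e) + xwx1 * u[1]) / xwx1
  expect_equal(out$u[1], m1, tolerance = 1e-5)
  # residual identity preserved
  expect_equal(out$e, e - X %*% (out$u - u), ignore_attr = TRUE)
  expect_error(sampleFixedEffects(0, e, matrix(0, 20, 1), w, 1),
               "collinear")
})

test_that("polygenic draws centre on zero with variance sigmaE2/(w+lambda)", {
  set.seed(12)
  n <- 5
  sE2 <- 2; sA2 <- 1
  # one draw matches mean + z * sd computed independently
  set.seed(7)
  one <- samplePolygenic(rep(0, n), rep(0, n), rep(1, n), diag(n),
                         sE2, sA2)
  set.seed(7)
  z <- rnorm(1)
  expect_equal(one$a[1], sqrt(sE2 / (1 + sE2 / sA2)) * z)
  expect_equal(one$e[1], -one$a[1])   # residual corrected in place
  draws <- replicate(4000, {
    out <- samplePolygenic(rep(0, n), rep(0, n), rep(1, n), diag(n),
                           sE2, sA2)
    out$a[1]
  })
  expect_lt(abs(mean(draws)), 0.05)
  expect_lt(abs(var(draws) - sE2 / (1 + sE2 / sA2)), 0.08)
  expect_error(samplePolygenic(rep(0, 3), rep(0, 3), rep(1, 3),
                               diag(2), 1, 1), "square")
})

test_that("variance draws follow the scaled inverse chi-squares", {
  set.seed(14)
  w <- rep(1, 30)
  out <- sampleVariances(rep(0, 30), w, rep(0, 10), rep(1L, 10),
                         componentVariances(1), 4)
  expect_identical(out$sigmaE2, 0)
  expect_identical(out$sigmaG2, 4)     # nm = 0: update skipped
  expect_identical(out$nm, 0L)
  e <- rnorm(30); g <- c(rnorm(5), rep(0, 5))
  k <- c(2L, 3L, 4L, 2L, 3L, rep(1L, 5))
  alloc <- c(0, 1e-4, 1e-3, 1e-2)
  set.seed(20)
  out <- sampleVariances(e, w, g, k, alloc, 4, sigmaGUpdate = "scaled")
  set.seed(20)
  c1 <- rchisq(1, 28); c2 <- rchisq(1, 3)
  expect_equal(out$sigmaE2, sum(e^2) / c1)
  expect_equal(out$sigmaG2, sum(g[1:5]^2 / alloc[k[1:5]]) / c2)
  expect_equal(out$sigmaK2, alloc * out$sigmaG2)
  set.seed(20)
  out2 <- sampleVariances(e, w, g, k, alloc, 4, sigmaGUpdate = "gg")
  expect_equal(out2$sigmaG2, 5 * sum(g^2) / c2)
})

test_that("blocked chain equals the single-site sampler draw for draw", {
  sim <- makeToy(nInd = 80, nSnp = 120, seed = 3)
  V <- designMatrix(sim$design)
  tr <- sim$trait
  m <- 12
  fit <- runChain(sim$design, tr, blockSize = 1, nOuter = m, burnIn = 0,
                  seed = 99)
  set.seed(99)
  ref <- refSingleSiteChain(V, tr@y, tr@w, tr@X,
                            alloc = c(0, 1e-4, 1e-3, 1e-2),
                            alphaMat = matrix(1, 1, 4),
                            snpClass = rep(1L, ncol(V)),
                            h2Guess = tr@h2Guess, sigmaT2 = tr@sigmaT2,
                            nOuter = m)
  expect_equal(fit@finalState$g, ref$g, tolerance = 1e-10)
  expect_equal(fit@finalState$e, ref$e, tolerance = 1e-10)
  expect_equal(fit@finalState$u, ref$u, tolerance = 1e-10)
  expect_identical(fit@finalState$k, ref$k)
  expect_equal(fit@traces$sigmaE2, ref$sigmaE2Trace, tolerance = 1e-10)
  expect_equal(fit@traces$sigmaG2, ref$sigmaG2Trace, tolerance = 1e-10)
  expect_identical(fit@traces$nm, ref$nm)
})

test_that("residual identity holds after every outer cycle", {
  sim <- makeToy(nInd = 100, nSnp = 200, seed = 8)
  fit <- runChain(sim$design, sim$trait, blockSize = 14, nOuter = 10,
                  seed = 2, checkResiduals = TRUE)
  expect_length(fit@residualCheck, 10)
  expect_lt(max(fit@residualCheck), 1e-8)
  # also with weights, covariates and the polygenic term on
  set.seed(31)
  w <- runif(100, 0.2, 3)
  X <- cbind(rnorm(100))
  tr <- traitData(sim$trait@y, w = w, X = X, h2Guess = 0.4)
  fitp <- runChain(sim$design, tr, blockSize = 14, nOuter = 6, seed = 2,
                   polygenic = TRUE, checkResiduals = TRUE)
  expect_lt(max(fitp@residualCheck), 1e-8)
  expect_gt(sd(fitp@finalState$a), 0)
})

test_that("beta counts are conserved and chain bookkeeping is exact", {
  sim <- makeToy(nInd = 60, nSnp = 50, seed = 13)
  n <- 7; m <- 8   # short last block: 50 = 7 x 7 + 1
  fit <- runChain(sim$design, sim$trait, blockSize = n, nOuter = m,
                  seed = 5)
  nM <- ncol(designMatrix(sim$design))
  expect_true(all(apply(fit@betaTrace, 1, sum) == nM))
  expect_identical(fit@nRetained, as.integer((m - m %/% 2) * n))
  # every marker, including the short last block, logs m x n samples
  expect_true(all(abs(rowSums(fit@componentFreq) - 1) < 1e-12))
  expect_true(all(fit@pp >= 0 & fit@pp <= 1))
  expect_equal(fit@traces$h2,
               fit@traces$sigmaG2 /
                 (fit@traces$sigmaG2 + fit@traces$sigmaE2))
})

test_that("chains are reproducible from their seed", {
  sim <- makeToy(nInd = 50, nSnp = 40, seed = 17)
  f1 <- runChain(sim$design, sim$trait, blockSize = 6, nOuter = 6,
                 seed = 123)
  f2 <- runChain(sim$design, sim$trait, blockSize = 6, nOuter = 6,
                 seed = 123)
  expect_identical(markerEffects(f1), markerEffects(f2))
  expect_identical(f1@finalState, f2@finalState)
  expect_identical(f1@traces, f2@traces)
  f3 <- runChain(sim$design, sim$trait, blockSize = 6, nOuter = 6,
                 seed = 124)
  expect_false(identical(markerEffects(f1), markerEffects(f3)))
  # runChains assigns consecutive seeds
  fs <- runChains(sim$design, sim$trait, nChains = 2, seed = 123,
                  blockSize = 6, nOuter = 6)
  expect_identical(markerEffects(fs[[1]]), markerEffects(f1))
  expect_identical(fs[[2]]@seed, 124L)
})

test_that("a zero-outer-cycle run returns the initialisation state", {
  sim <- makeToy(nInd = 30, nSnp = 20, seed = 19)
  fit <- runChain(sim$design, sim$trait, blockSize = 5, nOuter = 0,
                  burnIn = 0, seed = 1)
  expect_identical(fit@nRetained, 0L)
  expect_equal(fit@finalState$g, rep(0, 20))
  expect_equal(fit@finalState$e, sim$trait@y)
  expect_equal(fit@finalState$sigmaE2,
               sim$trait@sigmaT2 * (1 - sim$trait@h2Guess))
  expect_equal(markerEffects(fit), rep(0, 20))
})

test_that("one-class BayesRC is exactly BayesR", {
  sim <- makeToy(nInd = 60, nSnp = 40, seed = 23)
  nM <- ncol(designMatrix(sim$design))
  plain <- runChain(sim$design, sim$trait, prior = mixturePrior(),
                    blockSize = 6, nOuter = 8, seed = 7)
  oneClass <- runChain(sim$design, sim$trait,
                       prior = mixturePrior(snpClass = rep(1L, nM)),
                       blockSize = 6, nOuter = 8, seed = 7)
  expect_identical(markerEffects(plain), markerEffects(oneClass))
  expect_identical(plain@finalState, oneClass@finalState)
})

test_that("two-class priors keep separate mixing proportions", {
  sim <- makeToy(nInd = 80, nSnp = 60, seed = 29, qtnCounts = c(1, 2, 4))
  nM <- ncol(designMatrix(sim$design))
  cls <- rep(1L, nM); cls[seq(1, nM, by = 3)] <- 2L
  fit <- runChain(sim$design, sim$trait,
                  prior = mixturePrior(snpClass = cls),
                  blockSize = 8, nOuter = 8, seed = 11)
  expect_equal(dim(fit@finalState$pi), c(2, 4))
  # per-class beta sums equal the class sizes every cycle
  classSizes <- tabulate(cls, 2)
  for (l in seq_len(8))
    expect_equal(unname(apply(fit@betaTrace[l, , ], 1, sum)), classSizes)
})
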