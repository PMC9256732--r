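test_that("principal-component decorrelation matches the eigenstructure", {
  set.seed(41)
  n <- 4000
  z <- matrix(rnorm(2 * n), n, 2)
  rho <- 0.8
  Y <- cbind(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  dec <- decorrelateTraits(Y, threshold = 1)
  expect_identical(dec$nKept, 2L)
  # eigenvalues of the 2x2 correlation matrix are 1 +/- rho
  cv <- unname(apply(dec$scores, 2, var))
  expect_equal(cv, c(1 + rho, 1 - rho), tolerance = 0.1)
  expect_lt(abs(cor(dec$scores[, 1], dec$scores[, 2])), 1e-8)
  # already-uncorrelated traits come back up to sign and order
  U <- cbind(rnorm(n, sd = 2), rnorm(n, sd = 1))
  du <- decorrelateTraits(U, threshold = 1)
  expect_equal(abs(du$loadings), diag(2), tolerance = 0.05,
               ignore_attr = TRUE)
  # a tight threshold keeps only the leading component
  d1 <- decorrelateTraits(Y, threshold = 0.6)
  expect_identical(d1$nKept, 1L)
  expect_gte(sum(d1$varianceExplained), 0.6)
})

test_that("inclusion probability matches the component densities", {
  sk2 <- componentVariances(6)
  sE2 <- 2
  pi4 <- c(0.5, 0.2, 0.2, 0.1)
  # a certain prior pins the indicator
  expect_equal(inclusionProbability(1.3, c(1, 0), list(pi4), list(sk2),
                                    sE2), 0)
  expect_equal(inclusionProbability(1.3, c(0, 1), list(pi4), list(sk2),
                                    sE2), 1)
  # single trait with pi* = (pi_1, 1 - pi_1) and within-model mixing
  # renormalised: p equals the non-spike probability of the plain
  # 4-component multinomial with the matching likelihood
  gBar <- 0.9
  piStar <- c(pi4[1], 1 - pi4[1])
  piIn <- c(0, pi4[2:4]) / (1 - pi4[1])
  p <- inclusionProbability(gBar, piStar, list(piIn), list(sk2), sE2)
  full <- componentProbabilities(gBar, pi4, sk2, sE2,
                                 likelihood = "residual")
  expect_equal(p, sum(full[2:4]))
})

test_that("pi* Beta posterior has the stated mean and ordering", {
  set.seed(43)
  nM <- 300
  draws <- replicate(1e4, samplePiStar(c(nM, 0))[2])
  expect_lt(abs(mean(draws) - 1 / (nM + 2)), 5e-4)
  prior <- replicate(1e4, samplePiStar(c(0, 0))[1])
  expect_equal(mean(prior), 0.5, tolerance = 0.02)
  expect_equal(sum(samplePiStar(c(10, 5))), 1)
})

test_that("multi-trait chains honour the shared inclusion indicator", {
  set.seed(47)
  sim <- makeToy(nInd = 150, nSnp = 80, seed = 51, qtnCounts = c(1, 2, 4))
  y2 <- sim$trait@y * 0.5 + rnorm(150, 0, sd(sim$trait@y))
  traits <- list(sim$trait, traitData(y2, h2Guess = 0.3))
  mt <- runMultiTraitChain(sim$design, traits, blockSize = 10,
                           nOuter = 12, seed = 3)
  expect_length(mt@perTrait, 2)
  expect_true(all(mt@jpp >= 0 & mt@jpp <= 1))
  expect_equal(rowSums(mt@piStarTrace), rep(1, 12))
  # markers never included have zero posterior-mean effect on every trait
  out <- which(mt@jpp == 0)
  if (length(out)) for (t in 1:2)
    expect_true(all(markerEffects(mt@perTrait[[t]])[out] == 0))
  # J = 1 with the null component on every trait is permitted: the
  # inclusion frequency can exceed the non-null component frequency
  spike <- mt@perTrait[[1]]@componentFreq[, 1]
  expect_true(any(mt@jpp + spike > 1 + 1e-9))
  # reproducibility
  mt2 <- runMultiTraitChain(sim$design, traits, blockSize = 10,
                            nOuter = 12, seed = 3)
  expect_identical(mt@jpp, mt2@jpp)
  expect_identical(markerEffects(mt@perTrait[[1]]),
                   markerEffects(mt2@perTrait[[1]]))
  expect_error(runMultiTraitChain(sim$design, list()), "at least one")
})

test_that("a single-trait multi-trait run agrees with the plain sampler", {
  sim <- makeToy(nInd = 250, nSnp = 150, seed = 53, h2 = 0.5,
                 qtnCounts = c(2, 3, 5))
  stFits <- runChains(sim$design, sim$trait, nChains = 3, seed = 11,
                      blockSize = 15, nOuter = 30)
  mtFits <- lapply(11:13, function(s)
    runMultiTraitChain(sim$design, list(sim$trait), blockSize = 15,
                       nOuter = 30, seed = s))
  stH2 <- mean(vapply(stFits, heritability, numeric(1)))
  mtH2 <- mean(vapply(mtFits, function(f) heritability(f@perTrait[[1]]),
                      numeric(1)))
  expect_equal(mtH2, stH2, tolerance = 0.12)
  stG <- rowMeans(sapply(stFits, markerEffects))
  mtG <- rowMeans(sapply(mtFits, function(f)
    markerEffects(f@perTrait[[1]])))
  expect_gt(cor(stG, mtG), 0.85)
})

test_that("effects rotate back to the original trait scale", {
  set.seed(59)
  gm <- matrix(rnorm(20), 10, 2)
  load <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  fit <- new("MultiTraitFit",
             perTrait = list(
               new("ChainFit", gMean = gm[, 1], pp = numeric(10),
                   componentFreq = matrix(1, 10, 1),
                   traces = data.frame(), betaTrace = array(0, c(1, 1, 1)),
                   nRetained = 1L, plan = makeBlocks(10, 5),
                   finalState = list(), residualCheck = numeric(0),
                   seed = 1L),
               new("ChainFit", gMean = gm[, 2], pp = numeric(10),
                   componentFreq = matrix(1, 10, 1),
                   traces = data.frame(), betaTrace = array(0, c(1, 1, 1)),
                   nRetained = 1L, plan = makeBlocks(10, 5),
                   finalState = list(), residualCheck = numeric(0),
                   seed = 1L)),
             jpp = numeric(10), piStarTrace = matrix(0.5, 1, 2),
             seed = 1L)
  expect_equal(backRotateEffects(fit, load), gm %*% t(load))
})
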