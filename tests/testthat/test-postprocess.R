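test_that("EBV prediction is the scaled marker score", {
  sim <- makeToy(nInd = 40, nSnp = 25, seed = 97)
  V <- designMatrix(sim$design)
  nM <- ncol(V)
  expect_equal(unname(predictEbv(sim$design, rep(0, nM))), rep(0, 40))
  g1 <- c(2, rep(0, nM - 1))
  expect_equal(unname(predictEbv(sim$design, g1)), V[, 1] * 2)
  g <- rnorm(nM)
  expect_equal(predictEbv(sim$design, 2 * g),
               2 * predictEbv(sim$design, g))
})

test_that("new individuals are scaled with training frequencies", {
  sim <- makeToy(nInd = 60, nSnp = 20, seed = 101)
  set.seed(5)
  new <- simulateGenotypes(nInd = 15, nSnp = 30, mafRange = c(0.2, 0.4))
  # give the new panel the training marker ids, shuffled and padded
  ids <- markerInfo(sim$genotypes)$id
  mk <- markerInfo(new)
  ord <- c(sample(seq_along(ids)), seq.int(length(ids) + 1, 30))
  mk$id[ord[seq_along(ids)]] <- ids      # training ids at shuffled spots
  mk$id[ord[-seq_along(ids)]] <- paste0("extra", 1:10)
  new2 <- genotypeData(genotypes(new), markers = mk)
  gm <- rnorm(nMarkers(sim$design))
  ebv <- predictEbv(new2, gm, design = sim$design)
  # manual: subset columns in training order, scale by training p
  idx <- match(markerInfo(sim$design)$id, mk$id)
  p <- alleleFreq(sim$design)
  Vn <- sweep(genotypes(new2)[, idx], 2, 2 * p, "-")
  Vn <- sweep(Vn, 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(unname(ebv), as.numeric(Vn %*% gm))
  bad <- genotypeData(genotypes(new)[, 1:5],
                      markers = markerInfo(new)[1:5, ])
  expect_error(predictEbv(bad, gm, design = sim$design),
               "markers missing")
})

test_that("accuracy is a correlation and bias a regression slope", {
  set.seed(103)
  tbv <- rnorm(50)
  expect_equal(unname(accuracyBias(tbv, tbv)), c(1, 1))
  expect_equal(unname(accuracyBias(tbv, 2 * tbv)), c(1, 0.5))
  ebv <- tbv + rnorm(50, 0, 0.5)
  ab <- accuracyBias(tbv, ebv)
  expect_equal(unname(ab["accuracy"]), cor(tbv, ebv))
  expect_equal(unname(ab["bias"]), cov(tbv, ebv) / var(ebv))
  # accuracy is scale-invariant, bias scales inversely
  ab2 <- accuracyBias(tbv, 3 * ebv)
  expect_equal(ab2[["accuracy"]], ab[["accuracy"]])
  expect_equal(ab2[["bias"]], ab[["bias"]] / 3)
  expect_error(accuracyBias(tbv, rep(1, 50)), "zero variance")
})

test_that("across-chain correlation averages all unordered pairs", {
  x <- list(c(1, 2, 3, 5), c(1.1, 1.9, 3.2, 4.8), c(0.8, 2.2, 2.9, 5.1))
  expected <- mean(c(cor(x[[1]], x[[2]]), cor(x[[1]], x[[3]]),
                     cor(x[[2]], x[[3]])))
  expect_equal(chainCorrelation(x), expected)
  expect_equal(chainCorrelation(list(x[[1]], x[[1]])), 1)
  set.seed(107)
  five <- replicate(5, rnorm(30), simplify = FALSE)
  cm <- cor(do.call(cbind, five))
  expect_equal(chainCorrelation(five), mean(cm[upper.tri(cm)]))
  expect_identical(sum(upper.tri(cm)), 10L)  # 5 chains -> 10 pairs
  expect_error(chainCorrelation(list(rep(1, 5), rnorm(5))), "constant")
})

test_that("long-run correlation follows the closed form", {
  expect_equal(longrunCorrelation(5, 0.8), sqrt(4 / 4.2))
  # the quoted two-decimal figure 0.97 arises from rounding the inner
  # ratio 20/21 to 0.95 before the square root; agree within one unit
  # in the second decimal
  expect_lt(abs(longrunCorrelation(5, 0.8) - 0.97), 0.01)
  expect_equal(longrunCorrelation(3, 1), 1)
  expect_equal(longrunCorrelation(1, 0.49), 0.7)
  expect_error(longrunCorrelation(5, 0))
  expect_error(longrunCorrelation(5, 1.2))
  # monotone increasing in both arguments
  rs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(vapply(rs, longrunCorrelation, numeric(1),
                              nC = 4)) > 0))
  ns <- 1:20
  expect_true(all(diff(vapply(ns, longrunCorrelation, numeric(1),
                              r = 0.6)) > 0))
})

test_that("window summaries use 0-based half-open 50-kb bins", {
  mk <- data.frame(chrom = "1", pos = 10, pp = 1)
  w <- windowPP(mk)
  expect_equal(w$start, 0)
  expect_equal(w$end, 50000)
  expect_equal(w$sumPP, 1)
  # 49,999 and 50,001 land in different windows; 50,000 in the first
  mk2 <- data.frame(chrom = "1", pos = c(49999, 50000, 50001),
                    pp = c(0.2, 0.3, 0.4))
  w2 <- windowPP(mk2)
  expect_equal(w2$start, c(0, 50000))
  expect_equal(w2$sumPP, c(0.5, 0.4))
  expect_equal(w2$nMarkers, c(2L, 1L))
  # totals are conserved exactly; empty windows omitted; flags applied
  set.seed(109)
  mk3 <- data.frame(chrom = sample(c("1", "2"), 200, TRUE),
                    pos = sample.int(5e5, 200), pp = runif(200))
  w3 <- windowPP(mk3, threshold = 0.9)
  expect_identical(sum(w3$sumPP), sum(mk3$pp))
  expect_true(all(w3$nMarkers >= 1))
  expect_identical(w3$flagged, w3$sumPP > 0.9)
  expect_true(all(w3$end - w3$start == 50000))
})

test_that("component summaries average post burn-in counts", {
  sim <- makeToy(nInd = 50, nSnp = 30, seed = 113)
  fit <- runChain(sim$design, sim$trait, blockSize = 5, nOuter = 8,
                  seed = 3)
  s <- summarizeComponents(fit)
  expect_equal(sum(s$meanCounts), ncol(designMatrix(sim$design)))
  keep <- fit@traces$retained
  expect_equal(s$meanCounts[1, ],
               colMeans(fit@betaTrace[keep, 1, , drop = FALSE][, 1, ]))
})

test_that("chain combination averages effect summaries", {
  sim <- makeToy(nInd = 50, nSnp = 30, seed = 127)
  fits <- runChains(sim$design, sim$trait, nChains = 3, seed = 9,
                    blockSize = 5, nOuter = 8)
  comb <- combineChains(fits)
  expect_equal(comb$gMean, rowMeans(sapply(fits, markerEffects)))
  expect_equal(comb$pp, rowMeans(sapply(fits, inclusionProb)))
  expect_equal(comb$h2, mean(sapply(fits, heritability)))
  expect_equal(comb$chainCorrelation, chainCorrelation(fits))
})
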