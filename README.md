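# blockr

Bayesian genomic prediction and QTN fine-mapping with spike-and-slab
normal-mixture priors (the BayesR model family), fitted by a **blocked
Gibbs sampler with residual updating**. The package is for quantitative
geneticists and breeders who want BayesR-class analyses — genetic
architecture, genomic breeding values, posterior inclusion
probabilities — on large SNP panels without the run times of
single-site MCMC, and for methodologists who want a tested, inspectable
reference implementation.

## The model and the sampler

Phenotypes follow the mixed model

    y = Xu + Vg + Za + e,        e ~ N(0, W⁻¹σe²),   a ~ N(0, A σa²)

with `V` the scaled/centred genotype matrix
(`v_ij = (v*_ij − 2p_j)/√(2p_j(1−p_j))`) and SNP effects drawn from a
mixture of normals

    g_j ~ π₁·N(0, 0) + π₂·N(0, 10⁻⁴σg²) + π₃·N(0, 10⁻³σg²) + π₄·N(0, 10⁻²σg²),

with `π ~ Dirichlet(1,1,1,1)` (estimated per marker class for
BayesRC). Instead of updating the full residual vector once per marker
per iteration, markers are processed in blocks of `n ≈ √n_R`: on block
entry the right-hand sides `r_b = V_b'We` and cross-product `V_b'WV_b`
are formed, the block's component indicators and effects are re-sampled
`n` times against `r_b` (inner cycles), and residuals are corrected
once on exit. `m` outer cycles give Markov chains of length
`n_L = m × n` per effect at per-SNP cost proportional to
`(n_R + n)/n` rather than `n_R`. A multi-trait version shares a
per-marker inclusion indicator `J` across (PCA-decorrelated) traits,
with `π* ~ Beta(1,1)` updated from the in/out-of-model counts.

The MCMC kernels are compiled (Rcpp/RcppArmadillo) but draw from R's
RNG, so runs are reproducible from `set.seed()` and the test suite
holds the blocked engine to *draw-for-draw* equality with an
independent single-site R sampler at block size 1.

## Worked example

A few minutes on one CPU (2,000 individuals × 5,000 markers, 200 QTN,
five chains of 2,025 samples per marker):

```r
library(blockr)

sim <- simulateDataset(nInd = 2000, nSnp = 5000,
                       qtnCounts = c(1, 25, 174), h2 = 0.3, seed = 42)
round(sim$truth$realizedH2, 3)
#> [1] 0.294

fits <- runChains(sim$design, sim$trait, nChains = 5, seed = 1,
                  blockSize = 45, nOuter = 45)   # 45 ~ sqrt(2000)
comb <- combineChains(fits)

round(comb$h2, 3)                 # posterior-mean sigma_g^2/(sigma_g^2+sigma_e^2)
#> [1] 0.278
round(comb$chainCorrelation, 3)   # mean of the 10 pairwise chain correlations
#> [1] 0.983

ebv <- predictEbv(sim$design, comb$gMean)
round(accuracyBias(sim$truth$tbv, ebv), 3)
#> accuracy     bias
#>    0.731    0.793

win <- windowPP(cbind(markerInfo(sim$design)[, c("chrom", "pos")],
                      pp = comb$pp))
head(win[order(-win$sumPP), 1:5], 3)
#>     chrom    start      end sumPP nMarkers
#> 148     1 11500000 11550000  6.39       10
#> 180     1  1300000  1350000  6.25       10
#> 401     1 22950000 23000000  6.23       10
```

The posterior-mean heritability (0.278) recovers the realised 0.294;
the across-chain effect correlation of 0.983 means the five chains
agree (by the closed form, `longrunCorrelation(5, 0.983)` = 0.998: the
chain average is essentially the infinite-chain answer); accuracy is
the correlation between true and estimated breeding values, and a bias
(slope of truth on prediction) near 1 means the EBVs are roughly
calibrated. Among the fine-mapping summaries, the five largest
simulated QTN all end with inclusion probability ≥ 0.90, and two of
the three top-ranked 50-kb windows contain one of them (positions
1,320,001 and 22,985,001).

A command-line front end with `simulate`, `run`, `run-mt` and `post`
subcommands is installed at `inst/cli/blockr.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/blockr.R", package="blockr"))') simulate --help`).

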