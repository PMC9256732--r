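---
title: "Blocked Gibbs sampling for mixture-prior genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocked Gibbs sampling for mixture-prior genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockr)
```

## The model

blockr fits the mixed-effects regression used throughout genomic
prediction,

$$y = Xu + Vg + Za + e,$$

where $y$ holds $n_R$ phenotype records, $X$ the fixed-effect
covariates (an intercept is always included), $V$ the scaled and
centred genotype matrix over $n_M$ SNPs, $g$ the SNP effects, $Za$ an
optional polygenic term with covariance $A\sigma_a^2$, and
$e \sim N(0, W^{-1}\sigma_e^2)$ with a diagonal weight matrix $W$ (a
zero weight removes a record; a missing phenotype is encoded as a zero
weight).

Genotypes are coded 0/1/2 copies of the counted allele (PLINK A1) and
standardised per marker, $v_{ij} = (v^*_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$,
with $p_j$ the observed frequency over non-missing entries. Missing
genotypes are imputed at their column mean $2p_j$, which scales to
exactly zero: the marker then contributes nothing for that individual
and all right-hand-side algebra stays exact. Markers with minor-allele
frequency below a threshold (default 0.002) are excluded; the threshold
is exposed because practitioners commonly use 0.005 on dense real
panels.

The SNP effects carry the BayesR spike-and-slab prior, a mixture of
$K$ normals with variances $\mathcal{a}_k \sigma_g^2$ for fixed
allocation scalars $\mathcal{a} = (0, 10^{-4}, 10^{-3}, 10^{-2})$ by
default (any $K \ge 2$ with a leading zero is accepted; adding
$10^{-5}$ helps on very large panels). The mixing proportions $\pi$ get
a flat Dirichlet prior $\alpha = (1,1,1,1)$ and are re-estimated from
the per-component occupancy counts $\beta$. With markers partitioned
into biological classes, $\pi$ is estimated separately per class
(BayesRC); one class recovers plain BayesR exactly.

## The blocked sampler

Single-site Gibbs samplers for this model spend almost all their time
updating the full residual vector once per marker per cycle. blockr
instead partitions the markers into blocks of $n$ and, on entering
block $b$, forms the block right-hand side $r_b = V_b'We$ and the block
cross-product $V_b'WV_b$ once. The block's effects are then swept $n$
times (inner cycles) using only $r_b$ and the cross-product: each sweep
re-draws every marker's component indicator $k$ and its effect from

$$g_{bj} \sim N\!\left(\frac{r_{bj} + d_{jj} g_{bj}^{old}}
{d_{jj} + \kappa},\; \frac{\sigma_e^2}{d_{jj} + \kappa}\right),
\qquad \kappa = \sigma_e^2/\sigma_k^2,$$

with $d_{jj} = (V_b'WV_b)_{jj}$, followed by the rank-one correction
$r_b \leftarrow r_b + (V_b'WV_b)_{\cdot j}(g^{old}-g^{new})$. A spike
assignment ($k = 1$) zeroes the effect. On block exit the residuals are
corrected once, $e \leftarrow e - V_b(g_b^{new} - g_b^{entry})$. After
$m$ outer cycles over all blocks every marker has been sampled
$n_L = m \times n$ times; a short last block still receives $n$ inner
cycles so the chain length is uniform across markers. Per SNP the work
scales as $(n_R + n)/n$ instead of $n_R$, which is where the speed-up
comes from; the block cross-product is rebuilt at each visit, so memory
stays at $O(n^2)$ rather than a genome-wide $V'V$ cache.

The component indicator is drawn from the multinomial with
unnormalised weights
$\pi_k\, \exp(-\tfrac12 \bar g_j^2 / v_k)/\sqrt{v_k}$, where
$\bar g_j = (r_{bj} + d_{jj} g^{old}_{bj})/d_{jj}$ is the
least-squares estimate of the marker effect. Cumulative probabilities
are compared against one uniform draw, taking the smallest $k$ whose
running sum reaches it, so behaviour at a draw of exactly zero is
well defined.

Fixed effects, polygenic effects and $\sigma_e^2$ are re-sampled after
every $s_r$-th block, $s_r = \max(\mathrm{round}(n_M/n^2), 1)$, so they
too are refreshed about $n$ times per outer cycle; $\sigma_a^2$,
$\sigma_g^2$, the component variances and the Dirichlet draws of $\pi$
happen at the end of each outer cycle, when all marker assignments are
current. Initialisation is $e = y$, $u = 0$, $g = 0$,
$\sigma_e^2 = \sigma_t^2(1 - h_t^2)$ and
$\sigma_g^2 = \sigma_t^2 h_t^2$, splitting the genetic part 1:9 between
$\sigma_a^2$ and $\sigma_g^2$ when the polygenic term is on. Here
$\sigma_t^2$ is the weighted phenotypic variance
(`weightedTraitVariance()`), which reduces to the ordinary sample
variance at unit weights, and $h_t^2$ is a user-supplied heritability
guess — it only shapes the starting point and record weighting, and the
chain re-estimates both variances from the data.

### Numerical choices that matter

Two conditional distributions in this model family circulate in more
than one algebraic form, and the choice is consequential; both forms
ship behind configuration switches and the defaults were chosen for
statistical coherence:

* **Component likelihood** (`componentLikelihood`). The marginal
  distribution of the least-squares estimate $\bar g_j$ for a marker in
  component $k$ is $N(0, \sigma_k^2 + \sigma_e^2/d_{jj})$, so the
  default (`"sampling"`) uses $v_k = \sigma_k^2 + \sigma_e^2/d_{jj}$.
  The alternative `"residual"` uses $v_k = \sigma_k^2 + \sigma_e^2$;
  because $\sigma_e^2$ dwarfs every $\sigma_k^2$ in realistic data,
  that form makes the components nearly indistinguishable, so the
  mixture cannot learn from the data and heritability estimates are
  badly biased upward. It is retained for comparison only.
* **Genetic-variance update** (`sigmaGUpdate`). Given
  $g_j \mid k_j \sim N(0, \mathcal{a}_{k_j}\sigma_g^2)$ and a flat
  prior, the conditional posterior of $\sigma_g^2$ is scaled
  inverse-$\chi^2$ with scale $\sum_j g_j^2/\mathcal{a}_{k_j}$ over the
  $n_m$ in-model markers and $n_m - 2$ degrees of freedom; this is the
  default (`"scaled"`). The alternative `"gg"` draws
  $n_m\, g'g / \chi^2(n_m-2)$, which omits the $1/\mathcal{a}_k$
  rescaling; because in-model effects are shrunk towards zero it
  feeds back on itself and can collapse $\sigma_g^2$ to zero (or
  inflate it), which we observed directly on small simulations.
  The update is skipped in cycles with $n_m \le 2$.

Other conventions: $\kappa$ is the scalar $\sigma_e^2/\sigma_k^2$ added
to the scalar diagonal $d_{jj}$; the block-exit correction multiplies by
$V_b$ (an $n_R \times n$ matrix), which is the only dimensionally
consistent form; $s_r$ is rounded to the nearest integer and clamped at
1; initial mixing proportions are the prior mean $1/K$ per class;
burn-in defaults to the first half of the outer cycles; each chain owns
one RNG stream seeded `seed + chain index`, so multi-chain results are
reproducible and chains could be run in parallel without interaction.
All randomness flows through R's RNG, which is how the test suite can
hold the compiled blocked engine to draw-for-draw agreement with an
independently written single-site R sampler at block size 1.

## Multi-trait analysis

The multi-trait model assumes uncorrelated traits — in practice raw
traits are replaced by the leading principal components that explain a
target fraction of variance (default 99%; `decorrelateTraits()`), and
each component trait keeps the single-trait structure above. What links
the traits is a per-marker inclusion indicator $J$: when $J = 0$ the
marker affects no trait; when $J = 1$ each trait independently assigns
its own component and effect (a marker can be in the model yet sit in
the null component for every trait). $J$ is drawn per marker visit
from the traits' least-squares estimates in log space, using
$v_{t,k} = 1/(\sigma_{k,t}^2 + \sigma_{e,t}^2)$ as the likelihood
precision, and its prior probability $\pi^*$ starts at (0.95, 0.05) and
is Beta(1,1)-updated from the in/out counts at the end of every outer
cycle. Posterior inclusion probabilities (`jpp`) are the fraction of
retained samples with $J = 1$. Effects can be rotated back to the
original trait scale through the retained loadings
(`backRotateEffects()`); fine-mapping summaries stay on the component
scale. Residual and genetic covariances are assumed proportional — the
standard simplification for this model family — so no general covariance
estimation is attempted.

## The simulator

`simulateDataset()` emulates the quantitative-trait design used to
validate this class of samplers: causal variants (QTN) are drawn
without replacement and their effects sampled from the three non-null
mixture components — by default 15, 500 and 3485 effects with variances
$0.01$, $0.001$ and $0.0001 \times \sigma_g^2$ and $\sigma_g^2 = 625$ —
true breeding values are $TBV_i = \sum_j v^*_{ij}\varepsilon_j$ on the
raw 0/1/2 coding, and environmental noise is scaled so that
$\mathrm{var}(TBV)/\mathrm{var}(y)$ hits the target heritability (0.1
and 0.3 are the canonical settings). Genotypes are independent
binomial(2, $p_j$) sites with frequencies drawn uniformly from a MAF
range (default 0.05–0.5, chosen so that desk-scale panels are not
dominated by near-monomorphic markers); an optional two-subpopulation
mode shifts frequencies to mimic breed structure, and an optional
group offset adds a two-level fixed effect (default 0). What the
simulator deliberately does **not** reproduce is linkage
disequilibrium: real-panel LD comes from population history that cannot
be captured by independent sites. Parameter-recovery checks on this
generator therefore exercise the sampler's estimation machinery, not
its behaviour under LD; fine-mapping resolution on real data will
differ.

## Post-processing

Breeding values for new individuals are $V_{new}\, \bar g$ with the new
genotypes standardised by the *training* allele frequencies; accuracy
is the Pearson correlation with the true values and bias the slope of
regressing truth on prediction (1 = well calibrated). Convergence is
monitored by the mean pairwise correlation of posterior-mean effects
across chains, and the closed form
$\sqrt{n_C r/(n_C r - r + 1)}$ converts a pairwise correlation $r$ into
the correlation between the $n_C$-chain average and an infinitely long
chain. Fine-mapping uses fixed-grid, non-overlapping 50-kb windows
anchored at position 0 on each chromosome, on 0-based half-open
intervals so no marker is double-counted; the window sum of per-marker
inclusion probabilities is reported and windows above 0.9 are flagged
as likely to contain a causal variant. Window totals equal the marker
total exactly.

## Problem sizes used by the checks

The package's own validation runs at sizes a laptop CPU handles in
minutes: the draw-for-draw oracle comparison uses a 200 × 500 panel;
residual-identity conservation a 50-outer-cycle toy; and parameter
recovery simulates 2,000 individuals × 5,000 markers with 200 QTN
(counts 1/25/174, scaled proportionally from the canonical
15/500/3485 design), running five chains at block size 45
($\approx \sqrt{2000}$) with about 2,000 samples per marker, first half
discarded. At this scale the per-marker information
$d_{jj}\mathcal{a}_2\sigma_g^2/\sigma_e^2 \approx 0.09$ for the
smallest slab, an order of magnitude below what dense real panels
provide, so the occupancy split between the spike and the smallest slab
is only weakly identified: heritability posteriors are wide and
component counts should not be expected to match the simulated design
exactly (see the limitations below).

## Limitations

* Independent-site genotypes: no LD, hence no statement about
  fine-mapping resolution on real panels.
* The multi-trait model estimates no residual/genetic covariance
  matrices; decorrelation is the user's responsibility (PCA provided).
* The spike-vs-smallest-slab split is weakly identified whenever
  $\sigma_{k}^2 \ll \sigma_e^2/d_{jj}$; counts of "markers in the
  model" then reflect the flat direction of the posterior rather than
  the causal architecture, and only grow informative with record
  count. Along the same flat direction the $\sigma_g^2$ chain mixes
  very slowly at desk scale, so heritability summaries depend
  noticeably on chain length and initialisation; the reference
  recovery runs use the prescribed chains of about 2,000 samples per
  marker with the first half discarded, and real-data work at this
  record count should treat the heritability posterior as wide.
* Single-node execution; chains run sequentially (their seeds are
  independent, so external parallelisation is trivial).
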