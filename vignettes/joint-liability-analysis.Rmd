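---
title: "Joint common- and rare-variant liability analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint common- and rare-variant liability analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrisk)
```

polyrisk studies how common polygenic variation and rare potentially
damaging variants (PDVs) combine to confer liability to a complex disorder
such as autism spectrum disorder (ASD). This vignette documents the models
the package implements, the parameters that matter, the design choices made
where the design was genuinely open, and what the simulation-based tests do
and do not establish.

## The liability-threshold model

Liability is a latent standard-normal variable; a subject is affected
exactly when liability exceeds the threshold `t = qnorm(1 - K)` set by the
population prevalence `K`. The package's analytic core
(`threshold_from_prevalence()`, `group_means()`, `carrier_shift()`,
`liability_model()`) evaluates the truncated-normal calculus:

* mean liability of affected subjects, `phi(t)/K`;
* mean liability of unaffected subjects, `-phi(t)/(1 - K)`;
* the mean-liability shift `delta` of rare-variant carriers consistent with
  a `rho`-fold excess risk, `delta = t - qnorm(1 - K_c)` where `K_c` is the
  carrier risk.

At `K = 0.015` these give an affected mean of 2.525 and an unaffected mean
of -0.038 liability SD, so the two group means sit 2.563 SD apart
(half-distance 1.282).

Two deliberate ambiguities are surfaced rather than hidden:

**Risk scale of `rho`.** A "relative risk" can act on the risk itself
(`K_c = rho K`) or on the disease odds
(`K_c = rho Omega / (1 + rho Omega)`, `Omega = K/(1-K)`). The two differ
materially once `rho K` is not small: at `K = 0.015`, `rho = 15` the odds
parametrization gives `delta = 1.277`, the risk parametrization 1.415.
`carrier_shift()` implements both, with the odds scale as the default
because at a 15-fold excess the risk scale pushes the implied carrier risk
(22.5%) toward the regime where risk ratios stop being exchangeable with
odds ratios; both numbers are always reported by `liability_model()`.

**"Mid-point".** Between the affected and unaffected means one can quote
the arithmetic midpoint `(a + u)/2 = 1.243` or the half-distance
`(a - u)/2 = 1.282`. `additivity_diagnostics()` emits both, labeled, and
additionally places an observed carrier-group mean on the normalized
`[unaffected, affected]` interval, where exact additivity of rare and
common risk predicts an intermediate position.

## The synthetic cohort generator

No individual-level ASD cohort is distributable, so every end-to-end check
runs on `simulate_cohort()`, which emulates the statistical structure the
analysis assumes:

* **Ancestry structure.** `k` clusters (default 4, mirroring a typical
  eigenvector clustering of a mixed-ancestry sample) with Balding-Nichols
  allele-frequency divergence: cluster frequencies are
  `Beta(p(1-F)/F, (1-p)(1-F)/F)` around an ancestral `p ~ U(0.05, 0.95)`,
  so that `Var(p_k) = F p (1-p)`. `F` defaults to 0.01, continental-scale
  European substructure; the bias demonstrations use `F = 0.05` to mimic
  stronger divergence.
* **Genetic architecture.** Causal effects are `N(0, h2/m_causal)` on the
  cluster-standardized genotype scale, with `m_causal = m_snps` by default —
  the infinitesimal architecture that is also the G-BLUP working model.
  Standardizing by the subject's own cluster frequency keeps the polygenic
  variance at `h2` inside every cluster, so heritability bookkeeping is
  exact and recovery tests have a well-defined target.
* **Liability and diagnosis.** `liability = polygenic + delta * carrier +
  environment`, with `environment ~ N(0, 1 - h2)` and `h2 = 0.70` by
  default. `h2` refers to the common-variant component only; the rare-variant
  term adds variance on top for carriers, so total liability variance
  slightly exceeds 1 in that (rare) group — documented, not corrected, since
  carriers are ~2% of subjects.
* **Rare variants.** Carriers arise independently at `pdv_rate` (default
  0.02) and are shifted by `delta = carrier_shift(0.015, 15, "odds_ratio")`
  by default; at prevalence 1.5% this yields roughly 20% carriers among
  ascertained cases, in the range reported for damaging-variant carriers in
  ASD cohorts, and a realized carrier odds ratio of ~15
  (`realized_risk_ratio()` verifies the closure in the test suite at
  n = 3e5).
* **Ascertainment.** Cases are collected by rejection sampling (hard cap
  1e7 draws), matched controls mirror the cases' cluster composition, and a
  separate unmatched control pool is drawn for allele-frequency estimation
  only — reproducing the role of an external unselected cohort and keeping
  frequency estimation leakage-free.

One global seed drives everything; per-stage streams are derived
deterministically, and a separate `world_seed` pins the allele frequencies
and causal effects so that independent cohorts of the *same* trait (e.g. a
GWAS training cohort for the PRS machinery) can be drawn.

What the generator does **not** emulate: linkage disequilibrium beyond
structure-induced correlation, sex chromosomes, genotyping error,
cohort-specific ascertainment quirks, or realistic minor-allele-frequency
spectra. Passing tests therefore demonstrate that the estimators behave as
designed under their own assumptions, not that any particular real-data
number is reproducible.

## Ancestry, clustering, and matching

`ld_prune()` implements moving-window r² pruning (defaults 50-variant
windows, 5-variant steps, r² > 0.64 removes the later-positioned variant).
`compute_eigenvectors()` decomposes the tool-default GRM on the pruned set
with a deterministic sign convention (dominant coordinate positive).

Two components of the reference analysis are not reproducible from their
descriptions and were replaced by transparent equivalents:

* **Clustering.** Model-based eigenvector clustering is replaced by k-means
  on the top `d = 3` eigenvectors, with `k` chosen by average silhouette
  over 2..8 when not fixed. Clustering only stratifies allele-frequency
  estimation here, so any method that recovers well-separated clusters
  (ARI > 0.95 in the test battery) is adequate.
* **Matching.** 1:1 `pairmatch`-style optimal matching is implemented as an
  exact minimum-total-distance assignment (Jonker-Volgenant shortest
  augmenting path) within each cluster, on Euclidean distances in the
  eigenvector space. This optimizes the same objective deterministically and
  is verified against brute-force enumeration for up to 7 pairs.

## Allele frequencies and the three GRMs

Allele frequencies come from the unmatched control pool, never from the
analysis sample. Within-cluster frequencies are stabilized by
empirical-Bayes shrinkage toward the pooled frequency: the beta-binomial
posterior mean `(c_k + m p_bar) / (2 n_k + m)`. The prior strength is
`m = (1 - F)/F` with `F` estimated by a Weir-Cockerham-style moment
estimator from the across-cluster dispersion of raw frequencies, floored at
`m = 20` so that a nearly homogeneous pool still shrinks; the exact recipe
of the published method is not printed anywhere accessible, so this
standard empirical-Bayes construction is the package's own, documented
choice.

Three standardizations produce three GRMs (`compute_grm()`):

* **CLS** — `(x - 2p)/sqrt(2p(1-p))` with `p` the EB frequency of the
  subject's own cluster; `A = ZZ'/M`.
* **POP** — the same with the pooled frequency.
* **STD** — the conventional tool-default estimator from all-sample
  frequencies, including its distinctive diagonal
  `1 + mean((x^2 - (1+2p)x + 2p^2)/(2p(1-p)))`.

Using pooled frequencies on a structured sample inflates within-cluster
relatedness (subjects in a diverged cluster all deviate from the pooled
mean in the same direction); cluster-specific standardization removes the
effect. The test suite demonstrates this at `F = 0.05`, m = 10,000, n = 400,
where the POP-mode within-minor-cluster mean off-diagonal exceeds the
CLS-mode one by far more than 5 standard errors.

Monomorphic-in-pool variants are excluded from GRM construction with a
logged count; missing dosages are mean-imputed to `2p` (0 after
standardization); frequencies are clamped to
`[1/(2n+2), 1 - 1/(2n+2)]`.

## Leave-matched-pair-out G-BLUP

The genomic prediction GP is a G-BLUP of case status: phenotype 1/0,
centered on the training set (coding is immaterial because GP is
standardized afterwards), ridge `lambda = (1 - h2)/h2` with `h2` a fixed
input (0.70 by default, never estimated). The training plan holds out one
matched pair at a time and predicts its two members from the remaining
N - 2 subjects.

Refitting N/2 systems is unnecessary: with `A = K + lambda I` inverted
once, the block (Schur) downdate of `A^{-1}` for a held-out pair `S`
collapses algebraically to

`g_S = y*_S - (A^{-1}_{S,S})^{-1} (A^{-1} y*)_S`

with `y*` the fold-centered phenotype. The implementation uses this O(1)
per-fold form; its exactness against the naive per-pair refit (relative
error below 1e-8 for every fold) is the module's central correctness test.
When the factorization fails numerically a 1e-8 diagonal jitter is applied
and logged. Predictions are concatenated across folds and then standardized
once (standardizing per fold would discard between-fold scale information;
the choice is immaterial for rank-based uses of GP).

**Genomic control.** Leave-pair-out training overfits the labels, so the
Wald chi-square of the case-control GP contrast is inflated under the null.
`gp_case_control_test()` calibrates it by within-pair phenotype
permutation: each pair's labels are flipped with probability 1/2, GP is
fully re-estimated (cheap, by linearity of the fold predictions in the
phenotype), and the genomic-control factor
`lambda_GC = median(chi2_perm)/qchisq(0.5, 1)` deflates the observed
statistic (deflation only; `lambda_GC` below 1 is not used to inflate). 200
permutations are the default — enough to pin the null median to a few
percent. At the package's study conditions (500 pairs, 5,000 variants,
h2 = 0.70) the permutation null typically yields `lambda_GC` near 2.3,
the same order as reported for the reference analysis.

## Polygenic scores and the weighted score

The P+T machinery (`align_alleles()`, `clump()`, `prs_score()`) follows
standard practice: orientation of summary-statistic effects to the counted
allele with sign flips for swapped alleles and removal of strand-ambiguous
(A/T, C/G) variants; greedy p-value-ordered clumping (defaults r² > 0.1
within 250 kb — conventional settings, chosen because the reference QC
parameters are not public); inclusion threshold p < 0.01; mean-imputation
of missing dosages; standardization of the final score. The LD reference
for clumping is the unmatched control pool, keeping the analysis sample
untouched.

`combine_wgrs()` forms the weighted genomic risk score: each component's
weight is its Nagelkerke pseudo-R² against case status divided by the sum
(or 1/k under the equal scheme), and the weighted sum is re-standardized.
Weighting on the same sample that is subsequently analyzed follows the
reference design and is optimistically biased; a `weight_on` argument
provides a split-sample alternative. With component pseudo-R² of 7.80, 1.23
and 0.95 (percent), the weights are 0.7816/0.1232/0.0952.

`ptdt()` implements the polygenic transmission disequilibrium test: the
child-minus-midparent deviation scaled by the midparent SD, tested against
zero mean by a one-sample t-test. A degenerate all-identical deviation is
reported with `t = 0` rather than an error.

## Carrier classification

`classify_carriers()` applies the rules: a qualifying PDV is a
protein-truncating variant in a risk gene, a missense variant in a risk
gene with MPC strictly greater than 2 (the boundary is strict by
construction — MPC = 2 does not qualify), or a CNV flagged as damaging.
Trisomy or large/multiple CNVs make a subject `undetermined` regardless of
other records. Among carriers the most severe class is recorded with
severity CNV > PTV > MIS. Subjects without any records default to
non-carrier — the reference assumption for unassayed subjects — and an
`assayed` flag marks them for sensitivity analyses. The risk-gene list is
an input file, not embedded; the simulator emits a synthetic 102-gene set.

## Numerical and reproducibility choices

* All randomness flows from one seed through fixed per-stage offsets; the
  pipeline's `summary.json` is byte-identical across reruns of the same
  config and seed.
* k-means is seeded deterministically (10 restarts); cluster labels are
  relabeled by descending size.
* Pruning ties are broken by genomic position (later removed), then
  lexicographic variant id.
* Bootstrap CIs in `burden_contrasts()` use 2000 seeded percentile
  resamples.
* Logistic evaluation flags complete separation (infinite-OR sentinel)
  instead of failing; constant scores are rejected with a clear error.

## Problem sizes used by the validation suite

The simulation-based checks run at sizes chosen to make their conclusions
statistically decisive: parameter recovery at 500 matched pairs and 5,000
variants (GP-truth correlation > 0.1, case-control AUC > 0.55, and a
50-replicate permutation-null calibration of the GC-corrected test); the
standardization-bias demonstration at n = 400 and 10,000 variants; and the
additivity ordering — control mean < carrier-case mean < non-carrier-case
mean of GP — over a 40-seed battery at 400 pairs and 1,000 variants, where
the expected carrier deficit of several tenths of a GP standard deviation
dwarfs its standard error.

## Known limitations

* The EB prior-strength estimator and the PRS clumping parameters are
  documented stand-ins for unpublished details of the reference analysis.
* GP's permutation-based genomic control calibrates the case-control
  contrast, not downstream uses of GP as a covariate.
* The generator's lack of LD means clumping is exercised on
  structure-induced correlation and hand-built LD blocks only.
* `h2` is an input, not an estimate; misspecifying it changes the ridge
  and hence GP's scale, though standardization absorbs most of the effect.
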