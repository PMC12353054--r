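# dimorphomics

Cross-omics analysis of sexual dimorphism for paired proteomic and
transcriptomic profiles of the same tissue, built for human dorsal
root ganglion (DRG) data and validated end-to-end on synthetic data
with known ground truth.

Sex differences in pain biology are easy to claim and hard to pin
down: proteomic, transcriptomic and chromatin-accessibility readouts
of the same tissue rarely correlate feature-by-feature, yet may share
latent structure. This package implements the analysis chain for that
question:

* **Preprocessing** of DIA proteomics matrices: gene-group
  deduplication by primary symbol ("TRPV1" vs "TRPV1, TRPV2, TRPA1"
  keeps the higher-abundance row under "TRPV1"), an inclusive 80%
  completeness filter, log2 transform, technical-replicate merging by
  observed mean, and cross-study feature alignment.
* **Moderated differential testing**: empirical-Bayes variance
  shrinkage (`s2_post = (d0*s0^2 + d*s^2)/(d0 + d)`, prior estimated
  by digamma/trigamma moment inversion), BH correction, and strict
  differential calls (|LFC| > 1, FDR < 0.05).
* **Enrichment**: weighted Kolmogorov–Smirnov GSEA on ranked
  statistics with a gene-label permutation null (10,000 permutations;
  minimum set size 25, or 5 in loading mode), hypergeometric
  overrepresentation against an explicit background, and 95%-quantile
  marker-set construction.
* **Supervised PCA**: PCA restricted to an external feature list
  (sexually dimorphic chromatin regions or differentially expressed
  genes), PC1 eigengenes/eigenvectors, Welch test on PC1 scores.
* **Multi-study factor analysis**: the shared/specific factor model
  `Sigma_s = Phi Phi' + Lambda_s Lambda_s' + Psi_s` fitted by ECM
  under a block-lower-triangular identifiability constraint, gated on
  KMO >= 0.5 per study, with Bartlett factor scores
  `(Phi' Psi^-1 Phi)^-1 Phi' Psi^-1 x`, male-positive sign alignment,
  and a factor-by-sex ANOVA with single-step-adjusted per-factor
  contrasts (q < 0.1).
* **Phospho-array quantification**: `mean(PBS) - mean(ROI)` per
  membrane, then a sex-by-site type-II ANOVA with Tukey HSD.

A first-class synthetic-data module (`gen_multistudy()`,
`gen_proteomics_raw()`, `gen_ranked_with_sets()`,
`gen_phospho_grid()`) generates every input at the real design's
dimensions (two studies of 16 and 50 samples over 402 aligned genes,
3 shared factors) so the whole pipeline is testable without raw
mass-spectrometry or sequencing data.

## Worked example

Plant a 1.5-SD sex shift on shared factor 3 of a two-study dataset at
the real design's scale, fit the factor model, and ask which factors
separate the sexes and which gene set drives the flagged factor:

```r
library(dimorphomics)

sim <- gen_multistudy(sex_effect = c(0, 0, 1.5), seed = 1)
fit <- msfa_fit(sim$matrices, sim$meta, K = 3, J_s = c(1, 1), seed = 1)
fit$model
#> MsfaModel: p = 402, K = 3 shared, J_s = (1, 1); converged after 25 iterations
round(fit$kmo, 3)
#> [1] 0.716 0.863
fit$anova
#> Factor x Sex ANOVA: interaction p = 0.312
#>    factor  estimate           q
#> 1 factor1 0.2593739 0.609253014
#> 2 factor2 0.5997924 0.033306993
#> 3 factor3 0.7550397 0.004467122
#> significant (q < threshold): factor2, factor3

gs <- gsea_permutation_test(
  shared_loading_ranking(fit$model, 3),
  gene_set_collection(sim$truth$planted_sets),
  n_perm = 1000, min_size = 5, seed = 2
)
gs[, c("set", "size", "es", "nes", "p_perm", "q")]
#>       set size         es        nes      p_perm          q
#> 1 factor3   25 -0.4672221 -1.7321539 0.008385744 0.02515723
#> 2 factor2   25  0.2163988  0.7666913 0.813333333 0.99047619
#> 3 factor1   25  0.1485411  0.5262745 0.990476190 0.99047619
```

Both studies clear the KMO gate (0.72 and 0.86). The planted factor is
flagged decisively (male−female contrast 0.76 score-SD, q = 0.004) and
its truly-loaded gene set ranks first in the loading GSEA
(q = 0.025); factor 2 also crosses q < 0.1 here through score leakage
— the same two-of-three pattern the method exhibits on real DRG data.
Spot checks of the rest of the chain: `t_test_power(3, 1, alpha =
0.1)` returns `0.2706077`, and `ebayes_moderate(..., d0_override = 0)`
reproduces the ordinary two-sample t-test exactly.

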