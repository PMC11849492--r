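---
title: "Methods: linking skin metagenomes to the skin imaging phenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking skin metagenomes to the skin imaging phenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermalink)
```

# The analysis problem

Facial skin can be scored by imaging devices along ten quantitative axes —
the skin imaging phenotypes (SIPs): lightening, sebum, porphyrins, texture,
melanin, pore, pigment, wrinkle, hemoglobin and UV spot. The same cheek
carries a metagenome: species abundances, a gene catalog, and KEGG ortholog
(KO) functional profiles. dermalink implements a pipeline that asks, stage
by stage, how the two layers relate:

1. **Phenome dynamics** — which SIPs change with age, and how samples
   separate in phenome space (PCA, Mann–Whitney tests on PC1).
2. **Skin-age indices** — how well SIPs (SPA), microbial species (SMA) or
   both (SIA) predict chronological age under cross-validated
   random-forest regression.
3. **Diversity** — Shannon diversity and Bray–Curtis structure versus the
   SIPs (age-adjusted Spearman, PERMANOVA).
4. **MGS construction** — co-abundance gene groups (CAGs) by canopy
   clustering, promoted to metagenomic species (MGSs) and taxonomically
   labeled by identity-threshold majority rules.
5. **Module association** — a rank-based enrichment statistic relating
   each KEGG module to each SIP.
6. **Driver attribution** — leave-one-MGS-out analysis of which MGS
   drives a module–SIP correlation.

Because real paired metagenome–phenome cohorts cannot be bundled with a
package, every stage is validated against a synthetic cohort generator
(`generate_cohort()`) that plants known effects and records them in a
truth object.

# Statistical primitives

* **Spearman correlation (SCC)**: Pearson correlation of midranks;
  two-sided p from the t-approximation on n − 2 df. The *age-adjusted*
  variant is a partial Spearman correlation: all three vectors are
  midrank-transformed and the partial Pearson correlation of the x and y
  ranks controlling the covariate ranks is taken (n − 3 df). Adjustment by
  partial correlation (rather than stratification) was an open choice; it
  is deterministic, needs no binning decisions, and reduces exactly to the
  plain SCC when the covariate is rank-orthogonal to both arguments.
* **Mann–Whitney U** (two-sided): exact enumeration-based p whenever
  n1 + n2 ≤ 16 and the pooled sample is tie-free; otherwise a
  tie-corrected normal approximation with continuity correction. The
  module enrichment test compares hundreds of correlation values, where
  the exact branch is infeasible and midranks handle ties.
* **FDR**: Benjamini–Hochberg step-up q-values throughout; the package
  treats "FDR < t" and "q < t" as synonymous.
* **Percentile**: CAG profiles use the linearly interpolated 75th
  percentile (index h = (n − 1)·0.75). The interpolation convention is
  fixed and documented so profiles are bit-reproducible.

# The synthetic cohort generator

`sim_config()` defaults define the reference study condition used by the
whole test suite: 150 subjects aged 18–65 (uniform), 50% female, 40
species each carrying 80–120 genes (~4000 genes), 300 KOs organised into
20 non-overlapping 8-KO modules.

**Phenome.** Each SIP is affine in age and gender plus Gaussian noise,
truncated at zero (device scores are non-negative; truncation also keeps
the normalized MAE well defined). Slopes are ±0.35 score-units/year
against an sd-10 residual — pigment, pore, UV spot, melanin, hemoglobin
and wrinkle rise with age, lightening and texture decline, sebum and
porphyrins are flat — giving marginal age correlations around
|r| ≈ 0.3–0.5: detectable at n = 150 but far from trivial.

**Species.** Per-species baseline log-abundances span 4 natural-log units;
a per-sample shrink factor 1/(1 + δ·t), with t the subject's position in
the age range and δ = `diversity_age_effect` (default 1), compresses that
spread with age, so evenness and hence Shannon diversity rise in older
subjects. Log-normal sample noise (sd 0.8) is added and profiles are
renormalized to relative abundance.

**The driver.** One species (the most abundant) mixes a standardized copy
of the target SIP into its log-abundance noise. The mixing weight is
calibrated by binary search against a large (n = 3000) common-random-numbers
simulation of the full generative path — including the softmax
renormalization — so that the *realized* Spearman correlation between the
driver's relative abundance and the SIP hits the planted value (default
0.4). A closed-form weight is not available because renormalization and
the age trend both leak into the rank correlation; the empirical
calibration is monotone in the weight, hence the bisection.

**Genes and function.** Gene g of species s has abundance
`rel(s) × baseline(g) × exp(ε)`, with baselines log-uniform over two
orders of magnitude and ε ~ N(0, 0.1) — small enough that within-species
gene pairs have Pearson r > 0.9, the canopy clustering radius. KOs of the
three target modules are assigned almost exclusively to driver genes
(light contamination, ~25% of target KOs receiving one non-driver gene,
keeps the driver share ≥ 90%); every other gene draws a KO uniformly from
the remaining universe. Taxonomic hits label each annotated gene (90% of
genes) with its true species at identity ~ N(96, 2) clipped to [70, 100].

**What the generator does not emulate**: read-level noise, compositional
zero-inflation, strain heterogeneity, longitudinal structure, correlated
SIP residuals, or taxonomic misannotation. Passing tests therefore show
that the estimators recover planted effects under a clean generative
model — not that they are robust to every pathology of real skin
metagenomes.

# Stage-specific choices

**Age regression direction.** The trend stage regresses *age on the SIP*
(the SIP is the independent variable), which mirrors how such trend tables
are usually reported for device scores; `flip = TRUE` exposes the inverse.
Gender is not covaried by default; the generator's balanced gender offsets
make this visible in the residuals rather than the slopes.

**PCA.** SIP columns are z-scored before eigendecomposition
(correlation-matrix PCA) because the ten device scores have heterogeneous
units. Component signs are fixed by making each loading vector's
largest-magnitude entry positive.

**Random forests.** `ranger` with 500 trees and package-default
feature subsampling, always `num.threads = 1` and explicit seeds for exact
reproducibility. Five-fold cross-validation assigns every sample exactly
one out-of-fold prediction — the skin age. R² is computed per fold on
held-out data (it can be negative under the null) and summarized as a
mean; MAE is over all out-of-fold predictions. Cross-gender transfer
refits the five fold models on the training group and averages their five
predictions per transfer sample. The integration index (SIA) concatenates
z-scored SIPs with raw species relative abundances; species features are
left untransformed.

**PERMANOVA.** Implemented from the McArdle–Anderson trace formulation
(Gower-centered −½D², hat matrix of the centered design,
R² = tr(HGH)/tr(G)), with the label-permutation p-value
(1 + #{F* ≥ F})/(1 + B). For the combined SIPs + age analysis both a joint
fit (the "combined variance explained") and per-variable marginal fits are
reported; marginal fits are order-invariant, which a sequential
decomposition is not. `vegan::adonis2` serves as an independent
cross-check in the test suite, never as the implementation.

**Per-species associations.** A linear-model stand-in in the MaAsLin
tradition: arcsine-square-root transformed relative abundance regressed on
the z-scored SIP plus z-scored age, with a 10% prevalence filter. The
filter avoids degenerate fits on near-absent species; 10% is a
conventional default, not a fitted value.

**Canopy clustering.** The published canopy tool leaves seed order, merge
policy and stop conditions to the implementation, so dermalink fixes a
deterministic greedy variant: seeds visited by descending total abundance;
membership = unassigned genes with Pearson r > 0.9 to the canopy profile;
the profile (per-sample 75th percentile of members) and membership are
iterated to a fixed point (≤ 10 rounds); no canopy merging. Determinism
was preferred over fidelity to an undocumented binary. Constant-profile
genes have no defined correlation and become singleton CAGs.

**MGS selection and taxonomy.** MGSs are CAGs with strictly more than
`min_genes` genes (500 at catalog scale; 50 is the synthetic-cohort
preset, since desk-scale species carry ~100 genes). Taxonomy: species /
genus / family rank if > 50% of *all* member genes (unannotated genes count
in the denominator, at every rank) hit the same taxon at ≥ 95 / 85 / 75%
identity; a "classified species" additionally requires ≥ 80% of member
genes on the same species, evaluated at the species-level 95% identity
convention (the threshold inside the 80% rule is not standardised; the
species-level convention is applied). Label ties break by supporting gene
count, then lexicographically.

**Module–SIP statistic.** Per KO and SIP, the age-adjusted SCC; per module
and SIP, a two-sided Mann–Whitney test of the in-module SCCs against all
out-of-module SCCs for that SIP, with BH correction across all
module × SIP pairs jointly (the more conservative of the plausible
scopes). Modules need ≥ 3 KOs with defined correlations — a rank test on
fewer values is uninformative. The default significance threshold is
q < 0.05, the threshold attached to the headline module count in this
analysis tradition; 0.1 is exposed as a parameter. Age adjustment of the
per-KO SCCs is on by default with a plain mode available.

**Leave-one-MGS-out.** KO abundance is a sum over genes, so removing an
MGS is exact and additive. KOs whose abundance becomes all-zero or
constant after removal are dropped from the post-removal median (a
constant column has no rank correlation) and reported via
`n_kos_retained`; an MGS that owned every module KO yields an undefined
marker rather than an error. Candidates default to MGSs that contribute at
least one gene to a module KO — any other MGS provably has delta = 0.
Ranking is by |delta| with the signed value always reported.

# Problem sizes and runtimes

The validation suite runs the reference condition (150 × 40 × ~4000 ×
300 KOs) across 20 seeds for driver recovery, 200 null replicates for
module-test calibration, 10 seeds for CAG recovery, and 200 replicates
(999 permutations each) for PERMANOVA type-I calibration. These sizes were
chosen to give binomial confidence adequate for the pass criteria while
keeping a full run on one CPU in a few minutes.

# Known limitations

* The partial-Spearman age adjustment removes monotone age signal only.
* The canopy variant here is deterministic but single-linkage-like per
  canopy; extremely similar species (profile correlation above the 0.9
  radius) would merge.
* The module test inherits the dependence of in-module KO correlations
  (KOs of one module often sit in one MGS); BH control under such
  dependence is approximate, which the null-calibration test quantifies.
* Random-forest age indices are proxies for association strength, not a
  calibrated age predictor.
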