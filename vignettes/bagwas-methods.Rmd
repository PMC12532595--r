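---
title: "Methods: brain-age-gap GWAS from simulation to gene prioritization"
author: "bagwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-age-gap GWAS from simulation to gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagwas)
```

# Overview

`bagwas` implements a complete genetic-epidemiology workflow for brain age
gap (BAG) phenotypes: estimating brain age from imaging features by stacked
cross-prediction, computing and bias-adjusting BAG, running dosage GWAS and
fixed-effects meta-analysis, selecting independent signals by stepwise
conditional analysis, constructing approximate-Bayes-factor credible sets,
testing mediation with summary-data Mendelian randomization (SMR/HEIDI),
nominating and prioritizing genes across seven evidence streams, testing
gene sets, and estimating causal effects (GSMR) and polygenic scores. A
synthetic cohort generator supplies every input with the statistical
structure the downstream methods assume, so the whole pipeline is testable
without access-restricted biobank data.

This vignette documents the models, the parameters that matter, what the
generator does and does not emulate, and the design choices made where the
methodology was genuinely open.

# Age estimation and BAG

Brain age is estimated by tenfold cross-prediction: the cohort is split
into folds, and in each repeat every individual is predicted by models
trained without them. PCA is fitted on the training folds only and its
rotation applied to the held-out fold, so no information leaks from test to
train. Each tissue (grey and white matter) and each learner produces one
out-of-fold prediction per repeat; with 2 tissues, 3 learners and 100
repeats this is 600 estimates per individual.

Learner predictions are combined within tissue by an ordinary-least-squares
meta-model fitted on nested out-of-fold predictions; the combined estimate
stacks the two tissue-level predictions the same way, and repeat-level
estimates are averaged at the end. *Design choice:* the stacking learner is
OLS with an intercept because it is deterministic, adds no hyperparameters,
and matches the semantics of stacking linear combinations of unbiased
predictors. With a single learner the meta-step is the identity, so
stacking can never silently alter a lone prediction. Whether repeat
averaging should precede or follow stacking is not fixed by the method
itself; here stacking happens within repeat and averaging last, which keeps
every repeat a self-contained cross-prediction.

BAG is predicted minus chronological age. Because prediction error shrinks
predictions toward the training mean (regression dilution), raw BAG is
negatively correlated with age; `compute_bag()` residualizes BAG on the
covariate set (sex, age, age squared, scanner site, TIV, genotyping array,
genetic PCs), which removes this bias, and the same covariates enter every
downstream association model. Model quality is reported as the
product-moment correlation *r*, the coefficient of determination
R^2 = 1 - SS_res/SS_tot (computed without refitting, so it can be negative
and is not the square of *r*), the mean absolute error in years, and
test-retest reliability as ICC(C,1), the two-way mixed-effects consistency
single-measurement intraclass correlation.

Desk-scale defaults are `n_components = 50` PCA components and
`n_repeats = 5`; the study-scale values (500 components, 100 repeats)
remain configurable. The default learner roster is an L2-penalized linear
model (glmnet ridge) plus gradient-boosted trees (xgboost); the roster is
pluggable, and any learner exposing `fit(X, y)`/`predict(model, X)` can be
used.

# The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates:

- **Genotypes with block LD.** A latent Gaussian AR(1) process per block,
  thresholded independently per haplotype at the effect-allele-frequency
  quantile. Independent thresholding guarantees Hardy-Weinberg equilibrium
  exactly; the AR(1) parameter gives tunable r-squared decay. Blocks are
  distributed round-robin across 22 autosomes with 20 Mb between
  same-chromosome blocks so that distinct blocks never fall inside one
  clumping window; within a block variants sit 5 kb apart. Dosages respect
  the ploidy scale (0-2 diploid/chrX/chrXY, 0-1 chrY). INFO is carried as
  metadata and fixed at 1.0; imputation uncertainty is not modeled.
- **A heritable BAG phenotype.** `bag_true` is a centered genetic score
  over `n_causal` planted variants scaled so its variance share equals
  `h2_bag`, plus small covariate effects (sex 0.3 y, per-site effects with
  SD 0.2 y, a TIV slope of 0.002 y per unit — free parameters chosen to be
  realistic nuisance magnitudes, documented here and fixed) and Gaussian
  noise topping the total SD up to `bag_sd` (default 3 years).
- **Voxel-like features.** Each feature loads on the signal
  `age + bag_true` plus three shared nuisance latents plus measurement
  noise; with zero noise a linear readout reproduces the signal exactly.
- **Test-retest replicates.** The retest session's signal is
  `lambda * signal + sqrt(1 - lambda^2) * fresh noise` with `lambda` equal
  to the ICC target, which is the closed-form mixing weight for a
  consistency ICC; nuisance latents and feature noise are redrawn.
- **Mediation-consistent omics fixtures.** A designated subset of causal
  loci (in distinct LD blocks) receives eQTL/sQTL instrument effects, and
  the matching outcome effects are set to `b_xy * beta_zx` plus optional
  noise, so SMR recovers the planted expression-to-BAG effect; the same
  instrument effects back both probe types so one outcome table is
  consistent with both. Multi-tissue lookup records are generated on both
  sides of every filter boundary (9 vs 10 tissues, m-value 0.89 vs 0.90,
  RE2 p above and below 5e-8) with the truth recorded in a manifest.
- **A two-sample exposure GWAS.** Designated instruments (one per LD
  block) get exposure effects of eight standard errors, which gives well
  over 90% power at p < 5e-8 at the stated sample size; outcome effects
  embed the planted `b_xy_true`, and the exposure and outcome error streams
  are drawn independently, as the two-sample design requires.

The generator does **not** emulate realistic voxel geometry, imputation
uncertainty, population stratification or relatedness, or non-additive
effects. Tests passing on this cohort therefore demonstrate the
correctness and calibration of the statistical machinery under the stated
model, not robustness to confounding structures the generator omits.

# Association, meta-analysis and signal selection

`gwas_linear()` fits, per variant, OLS of the phenotype on dosage plus
covariates with a two-sided t-test, implemented by residualizing phenotype
and dosages on the covariates once (Frisch-Waugh), which is exact and fast.
Monomorphic variants return flagged NA rows rather than disappearing.

`ivw_meta()` combines cohorts with fixed-effects inverse-variance weights,
harmonizing alleles on (chrom, pos): an a1/a2 swap flips the sign of beta
and the frequency; strand flips are resolved by complementing; palindromic
variants are resolved by allele frequency when `|freq - 0.5| > 0.2` and
excluded otherwise. Heterogeneity is Cochran's Q on k-1 df. After
combination, variants with a sample size below 67% of the 90th percentile
or with heterogeneity p below 1e-6 are removed, and the removed rows are
returned as a manifest attribute.

`stepwise_conditional()` performs exact joint regression on the
individual-level reference data instead of a summary-plus-LD
approximation: at desk scale the exact model is available, and the
contract (select the best conditional signal, skip candidates above the
collinearity cutoff, stop below the threshold) is identical. Subsidiary
signals whose conditional p degrades by more than two orders of magnitude
relative to their marginal p are discarded, as are those that lose
genome-wide significance in the joint model. Conditioning uses selected
variants within the 10,000-kb window of each candidate.

`clump_and_flag()` clumps index variants across traits greedily by
ascending p (r-squared 0.1, 10,000-kb window) and flags a locus as novel
only if no known-list variant clumps with its lead under the same
parameters.

# Replication statistics and winner's curse

Sign concordance and nominal replication are tested with one-sided
upper-tail binomial tests (null proportions 0.5 and 0.05); one-sided is the
convention that reproduces the printed tail probabilities (for example
0.5^25 = 2.98e-8). "One-tailed nominal significance" is operationalized as
the one-sided replication p in the discovery direction below 0.05.

Replication power uses standardized discovery betas corrected for winner's
curse, the replication SE `1/sqrt(n 2 maf (1 - maf))` for a unit-variance
phenotype (conservative: covariate-explained variance is ignored), and
one-tailed normal power; expected replications are the sum of per-variant
power. The winner's-curse correction first computes the
conditional-likelihood MLE of the true z under two-sided truncation at the
variant's own selection threshold (1-D numeric maximization). Simulation
shows the raw conditional MLE overcorrects for observations near the
threshold — strongly enough to leave a larger magnitude bias than no
correction at all — so the returned estimate is the standard combined
estimator, the average of the MLE and the observed z, clamped to the
observed sign and never inflated. Under ascertainment at p < 5e-8 with
truth spanning z = 4-9 this reduces the mean magnitude bias severalfold
(the acceptance script recomputes both biases).

# Fine-mapping, SMR and gene prioritization

Credible sets use single-causal Wakefield approximate Bayes factors,
`ABF = sqrt(1 - r) exp(z^2 r / 2)` with `r = W/(W + se^2)`; the prior SD
defaults to 0.3 years, matching the scale of observed per-allele BAG
effects, and is configurable. PIPs are ABFs normalized within the locus and
the 95% set is the minimal prefix of the PIP-descending order. A set is
assigned to a locus if it contains a genome-wide-significant credible
variant in strong LD (r-squared > 0.8) within 3,000 kb of the index
variant. Fine-mapping is done per index variant; whether secondary
conditional signals deserve their own sets is left to the caller, who can
pass conditional statistics. The single-causal model is a deliberate,
documented stand-in for multi-signal fine-mapping machinery, adequate for
loci dominated by one signal.

SMR estimates the expression-to-outcome effect as the top instrument's
ratio `beta_zy / beta_zx` with the delta-method SE, and HEIDI tests whether
secondary instruments in intermediate LD (0.05 < r-squared < 0.9, at most
20) tell the same story, using the LD-aware delta-method covariance of the
ratio deviations and a chi-squared statistic with one df per secondary
instrument; low HEIDI p indicates linkage rather than mediation. Retention
requires FDR < 0.05 (within probe type) and HEIDI p > 0.01.

Gene nomination fills seven streams: credible-variant posterior mass per
gene (via positional annotation with precedence exonic > splice-region >
UTR > intronic > up/downstream within 1 kb > intergenic-nearest);
nonsynonymous credible variants ranked by CADD Phred score; SMR eQTL and
sQTL genes ranked by p; single-tissue eQTL genes ranked by significant
tissue count among the index variant and its strong-LD significant
neighbors; multi-tissue eQTL genes after the lookup filters (10+ tissues,
m-value at least 0.9 in at least half, RE2 p < 5e-8); and up to three
genes within 500 kb with the highest PoPS scores. Ranks are competition
ranks (ties share the best rank). The composite priority score is

P_i = C_i + sum over the six ranked categories of
2 (n_j + 1 - R_ij) / (n_j (n_j + 1)),

where `C_i` is the posterior-mass stream and the rank contributions within
any category telescope to exactly one point, so each category contributes
equally. The seven streams enter as one unranked mass term plus six ranked
terms — the reading under which the formula's six-term sum and the
seven-stream list are consistent. Exact ties go to the gene nearest the
index variant.

# Gene-based and gene-set tests

The gene-based statistic is the sum of squared variant z-scores with zero
flanking window; its null is a weighted sum of 1-df chi-squares with
weights equal to the LD correlation eigenvalues, approximated by the
two-moment Satterthwaite match (scale `sum(lambda^2)/sum(lambda)`, df
`sum(lambda)^2/sum(lambda^2)`). The approximation is contract-tested
against a Monte-Carlo oracle (within 1.5x at the 1% tail over random LD
structures). Significant genes (FDR < 0.05) are clumped top-p-first within
3,000 kb.

GO enrichment tests each term with a one-sided Wilcoxon rank-sum statistic
for lower-than-expected gene p-value ranks, using the same normal
approximation for the observed data and for label permutations. FWER is
the permutation distribution of the minimum p across all terms of all
three aspects jointly (per-aspect FWERs are also reported; the joint FWER
is never anti-conservative relative to them). The default permutation
count is 1,000 (the calibration suite uses 400 to keep runtime modest; the
estimator adds-one smooths, so the resolution is 1/(B+1)). Terms
significant at joint FWER < 0.05 are refined by elim: most specific terms
first, a significant term's genes removed from its ancestors, ancestors
re-tested against the same null; the elim threshold equals the reporting
threshold. One-sided-toward-enrichment is used throughout, matching the
"lower-than-expected ranks" reading.

# Mendelian randomization and polygenic scores

GSMR selects exposure instruments at p < 5e-8, clumps them at r-squared
0.001 within 10,000 kb, and combines per-instrument ratios by generalized
least squares. Three numerical choices matter and are worth recording:

- Ratio variances are evaluated at a first-pass pooled (median) estimate
  rather than at each instrument's own ratio, with the squared instrument
  effect attenuation-corrected by its sampling variance
  (`beta_zx^2 - se_zx^2`). Weighting each ratio by a variance that depends
  on that same ratio systematically pulls the estimate toward zero;
  evaluating the variance at a common point removes this while leaving the
  exact-ratio identity intact (identical ratios are returned unchanged by
  any weighting).
- Sample-LD correlations between instruments below the reference panel's
  noise floor (r-squared < 0.01) are zeroed before the GLS inverse; after
  clumping at 0.001 the instruments are essentially independent, and
  inverting a matrix of pure LD noise only adds variance.
- The reported SE carries a multiplicative over-dispersion factor
  `sqrt(max(1, Q/(m-1)))`, the standard multiplicative-random-effects
  scaling, which absorbs the mild optimism of the delta-method ratio
  variance.

HEIDI outlier removal references each instrument's deviation to the pooled
estimate rather than to the top instrument's own ratio: the top instrument
is selected for extreme exposure significance, its ratio carries selection
bias, and referencing deviations to it shifts every test in the same
direction and removes high-side ratios preferentially. Deviations
significant at p < 0.01 are removed and the estimate refit. Reverse MR is
the same call with exposure and outcome swapped.

Polygenic scores use clumping (r-squared 0.1, 500-kb window, p-informed)
and ten p-value thresholds (5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2,
0.5, 1.0 — the conventional ladder; the set is configurable). Variant sets
nest across thresholds by construction. Evaluation is the partial
product-moment correlation of score and phenotype given the covariates,
computed by residualizing both; training/target disjointness is enforced by
an id-overlap check.

# Numerical conventions and degenerate inputs

Coordinates are 1-based inclusive internally; BED is written 0-based
half-open, GFF3 1-based. Variant positions are stored as doubles (large
panels overflow 32-bit bp coordinates). Monomorphic variants, genes with
no mapped variants, SMR genes without a valid instrument and empty
conditional-selection inputs all return flagged or empty results with
messages, never silent drops or errors. Competition ranking breaks ties
deterministically. Fold assignment uses a seeded permutation with the
remainder distributed to the first folds. All generator outputs are fully
determined by the config seed.

# Problem sizes used by the test and acceptance suites

The suites run at desk scale, chosen so the whole pipeline exercises in
minutes on one CPU: cohorts of 500-4,000 individuals, panels of 20-5,000
variants, 200 seeds for the GSMR recovery study, 500 loci for credible-set
coverage, 400 replicate datasets for the GO FWER calibration, 1,000
ascertained loci for the winner's-curse study and 100 constructed loci for
the prioritization recovery study. Study-scale parameters (500 PCA
components, 100 repeats, tens of thousands of individuals) remain available
through the same configuration objects.

# Known limitations

The single-causal ABF fine-mapper underperforms multi-signal methods at
loci with several independent causal variants. The gene-based
Satterthwaite tail is a two-moment approximation, accurate to the tested
1.5x at moderate tails but not exact. The GSMR GLS treats instrument LD to
first order and is intended for the near-independent instruments its
clumping produces. The generator's LD is a surrogate (latent AR(1)), not
real haplotype structure, and its covariate effects on BAG are free
parameters of the simulation, not estimates from data. Binary outcomes,
mixed-model association, multi-ancestry meta-analysis and Bayesian
polygenic scoring are out of scope.
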