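---
title: "Predicting treatment response from DNA methylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting treatment response from DNA methylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrx)
```

## The analysis problem

Neoadjuvant treatment cohorts are profiled at several timepoints (before
treatment, mid-treatment, at surgery) for DNA methylation (Illumina-style
beta values in $[0,1]$ per CpG probe) and gene expression, together with
per-patient response labels: pathological complete response (pCR), residual
cancer burden dichotomized into low (RCB 0/I) and high (RCB II/III), and the
continuous fraction of tumor left. methrx implements an integrated analysis
of such cohorts with five connected components:

1. **Response signature discovery.** A sparse predictive signature over a
   preselected CpG panel, found by L1-penalized logistic regression of pCR
   on pre-treatment beta values.
2. **Paired differential methylation** between timepoints.
3. **Delta emQTL**: all-pairs correlation between treatment-induced changes
   in methylation and expression, followed by spectral co-clustering into
   CpG-gene biclusters whose average delta methylation is tested against
   response.
4. **Tumor-purity correction** of beta values to a cancer-cell-specific
   estimate.
5. **Genomic-context enrichment** of CpG and gene lists against chromatin
   states, TF binding sites, gene sets and chromatin loops.

## Signature discovery and scoring

For $n$ samples, one model is trained per sample on the other $n-1$
(leave-one-out, LOO). Each model is an L1-penalized logistic regression
(glmnet); the penalty is chosen inside each training set by 5-fold
cross-validation, minimizing the CV binomial deviance over glmnet's
100-point log-spaced penalty grid. Inner folds are stratified by class so
every fold sees both outcomes. Features are standardized to unit variance
inside the fit; coefficients are reported on the original beta scale so
that signatures can be applied to raw matrices. The held-out sample's
predicted probability is recorded, giving an unbiased LOO probability
vector for ROC evaluation.

The $n$ sparse models are aggregated into one stable signature by keeping
the CpGs selected in at least 50% of the models (inclusive: exactly half
qualifies) and averaging the coefficients. Averaging has two defensible
readings when a probe is absent from some models; both are implemented:

* `coef_average = "present"` (default): mean over the models where the
  probe has a nonzero coefficient;
* `coef_average = "all"`: mean over all $n$ models, counting absence as 0
  (which shrinks coefficients by the selection frequency).

The choice is recorded in the signature's metadata. The intercept is always
the mean over all $n$ model intercepts.

A sample's score is the intercept plus the coefficient-weighted sum of its
feature values; the response probability is the logistic transform of the
score (a monotone map to $(0,1)$, so AUCs computed from scores and
probabilities coincide).

**Translation to expression.** Each signature CpG is mapped to the gene
whose expression has the highest absolute Pearson correlation $\rho$ with
the CpG's methylation across the shared samples; the translated gene
coefficient is the CpG coefficient times the *signed* $\rho$. Exact $|\rho|$
ties break to the lexicographically smaller gene id, making the map
deterministic. Two CpGs may select the same gene; the translated signature
then carries both entries and scoring sums them. Zero-variance CpGs cannot
be correlated and are skipped with a warning.

**Hybrid score.** Two score vectors over the same patients (e.g. a
methylation score and a protein-signature score) are each standardized to
mean 0, SD 1, and averaged per patient. Standardization makes the average
well-defined across scores with different native scales.

**ROC.** The AUC is the pairwise concordance over all positive-negative
pairs, ties counting one half (computed by ranks, verified in the tests
against an $O(n^2)$ brute-force oracle and against pROC). The reported
operating point maximizes Youden's $J$; exact ties break toward higher
specificity, the regime of interest for treatment-selection biomarkers.
Samples at or above the cutoff are called positive. Scoring a signature on
its own discovery data is *in-sample* and is labelled as such wherever the
package reports it; the LOO probabilities are the honest estimate.

## Paired differential methylation

CpGs enter a comparison only if their interquartile range across the
samples of that comparison (both timepoints pooled) exceeds 0.1 — a filter
against flat, uninformative probes. The IQR uses linear interpolation
between order statistics (quantile type 7, R's default); the type is
configurable because the threshold is a hard cutoff and the quantile
convention moves probes across it. Per CpG, a two-sided paired t-test is
run on the per-patient deltas (patients lacking either timepoint are
dropped and counted); p-values are Benjamini-Hochberg adjusted across
tested CpGs, and a CpG is called significant when $q < 0.05$ **and**
$|\overline{\Delta\beta}| > 0.1$, both strict as printed conventions.
Degenerate probes are reported, not silently dropped: fewer than two
complete pairs flags `untested`; zero-variance deltas (up to float fuzz)
flag `zero_variance` with $p$ forced to 1.

## Delta emQTL and spectral co-clustering

Per-patient deltas (later minus earlier timepoint; week 0 to week 12 by
default) are formed for methylation and expression. Every CpG-gene pair is
tested by Pearson correlation across patients (non-constant features only);
p-values are Bonferroni-corrected by the number of tested pairs, and pairs
with corrected $p < 0.05$ are significant. Bonferroni (not BH) is used here
to match the familywise convention of emQTL analyses.

CpGs and genes with at least one significant pair are carried into
co-clustering; the matrix fed to the algorithm contains *all* retained
CpG-gene correlation entries, not only the significant cells, since the
screen restricts features rather than cells. Because within-bicluster
CpG-gene delta correlations are negative (methylation up, expression down,
or vice versa), correlations are converted to non-negative affinities as
$\max(-r, 0)$: negation makes within-bicluster affinity positive, and the
floor satisfies the algorithm's non-negativity requirement. The reciprocal
$1/r$ is numerically unusable and $|r|$ (also available via
`transform = "abs"`) would reward positive correlation equally. A tiny
constant ($10^{-12}$) guards all-zero rows before degree normalization.

The co-clustering itself is the bipartite spectral algorithm: normalize
$A$ to $D_1^{-1/2} A D_2^{-1/2}$, take the $1 + \lceil \log_2 k \rceil$
leading singular vector pairs (dropping the trivial first), stack the
degree-scaled row and column embeddings, and k-means the joint embedding
into $k$ groups (25 restarts, seeded). Every retained CpG and gene lands in
exactly one bicluster; labels are renumbered by order of first appearance
so runs are comparable.

$k$ is chosen by the mean silhouette width of the joint spectral embedding
under Euclidean distance, evaluated for each candidate $k$ (default 2-8,
clipped to the matrix dimensions); the full score table is returned for
inspection. The embedding, rather than the raw affinity matrix, is the
natural space because it is what k-means partitions.

A bicluster's per-patient *delta score* is the arithmetic mean of its CpG
(or gene) deltas. Scores are compared between response groups by two-sided
Welch t-tests (pCR, RCB low/high) or against the fraction of tumor left by
a Pearson correlation test, optionally within one treatment arm.

## Tumor-purity correction

Bulk beta values mix tumor and non-tumor methylation in proportion to the
tumor cell fraction $p_i$. Per CpG $j$, ordinary least squares fits
$m_{ij} = a_j + b_j p_i + \varepsilon$; the fitted value at $p = 1$ is the
mean tumor-cell methylation, and adding each sample's residual gives

$$\hat m^{corr}_{ij} = m_{ij} + b_j (1 - p_i).$$

Under the identifying assumption that non-tumor methylation is constant
per CpG across samples, this recovers the tumor methylation exactly on
noise-free mixtures (verified to $10^{-10}$ in the tests). CpGs with no
purity association ($b_j = 0$, or unfittable: fewer than 3 complete cases
or no purity variance) pass through unchanged — each CpG is adjusted only
as far as its own purity association warrants. Corrected values are clipped
to $[0,1]$ (beta semantics; clip events counted and reported), fits are
complete-case per CpG without imputation, and the regression pools
whatever sample set is passed in — per-cohort, per-arm or per-timepoint
correction is the caller's choice.

## Enrichment conventions

All enrichment tests are upper hypergeometric tails $P(X \ge k)$ with fold
$= (k/n)/(K/N)$, BH-corrected within each family (per set collection, per
chromatin-state track, per TF panel). CpG probes are 1-bp intervals at the
interrogated cytosine; all coordinates are BED-style 0-based half-open.

* **Chromatin-state consensus:** for each subtype with $\ge 2$ cell lines,
  only positions where *all* lines carry the same state keep that state;
  discordant or partially covered positions are omitted, and adjacent
  same-state pieces are merged to maximal intervals.
* **TF binding sites:** probe positions are extended 150 bp both ways
  (301-bp half-open window $[pos-150, pos+151)$; the convention is
  documented and the width configurable). Sites are union-merged per TF
  across experiments before overlap, so duplicated experiments cannot
  double-count. Strand is ignored: CpG methylation is strand-symmetric.
* **Loops:** a CpG-gene pair is in a loop only when the CpG and the gene's
  TSS occupy *opposite* anchors of the same loop; both-in-one-anchor does
  not count. The background is all possible same-chromosome CpG-gene
  pairs, and only cis loops are accepted (trans pairs in BEDPE input are
  dropped with a count).

## The synthetic cohort

`generate_cohort()` produces the reference conditions the tests and the
acceptance script run under (defaults of `sim_config()`):

* 60 patients, 3 timepoints each; pCR prevalence 0.3; two treatment arms
  assigned alternately; 300 CpGs, 120 genes.
* Baseline tumor methylation bimodal (Beta(2,8) / Beta(8,2) probe means),
  per-sample biological spread SD 0.05.
* 20 *predictive* CpGs centered at beta 0.5 whose week-0 tumor methylation
  differs by 0.4 between response groups, alternating direction.
* Two planted biclusters (30 CpGs and 20 genes each). A per-patient latent
  response factor $f_i \sim N(1.5\cdot\mathrm{pCR}_i, 1)$ drives the week-0
  to week-12 deltas: methylation moves by $\pm 0.15 f_i$ (opposite signs
  for the two biclusters) and expression by the opposite sign, giving the
  negative CpG-gene delta correlations the emQTL stage expects, and tying
  the deltas to response. The fraction of tumor left decreases in $f_i$.
* Observed beta $= p \cdot \text{tumor} + (1-p)\cdot \text{normal} +
  N(0, 0.03)$, clipped to $[0,1]$, with purity $p \sim U(0.3, 0.9)$ per
  sample and the non-tumor level a fixed per-probe constant — exactly the
  purity model's identifying assumption, so correction quality measures
  implementation correctness, not model misfit.

`generate_tracks()` lays probes and TSSs 1 kb apart on one toy chromosome
and plants consistent context: bicluster-1 CpGs sit in enhancer segments
and in one TF's binding sites (background rate 0.1 elsewhere), bicluster-1
CpG-gene pairs are connected by loop anchors, and the gene set collection
contains each planted bicluster's genes plus random sets. A second
chromatin track disagrees on 5% of background segments to exercise the
consensus step.

What the simulation does *not* emulate: realistic genome geometry,
probe-to-gene annotation, correlated probe blocks, copy number, batch or
array artifacts, and non-constant non-tumor methylation. Passing recovery
tests therefore demonstrates that the algorithms recover the structure
they model, not that real cohort results are reproduced — published
cohort-level numbers depend on restricted clinical data and are out of
scope here.

## Numerical choices and degenerate inputs

* Seeds: every stochastic step (simulation, fold assignment, k-means) takes
  an explicit seed; the pipeline derives all of them from one recorded
  master seed, and reruns are bit-identical.
* Constant-feature designs: `loo_lasso()` returns intercept-only models
  (held-out probability = training class rate); `emqtl_scan()` skips
  constant features; `select_k()` rejects an all-equal matrix.
* $r = \pm 1$ correlations get $p = 0$ rather than NaN from the t
  transform.
* Missing values: policies are per-operation, not global — scoring and
  `loo_lasso()` refuse missing cells loudly, paired tests drop incomplete
  pairs per probe, purity fits are complete-case per probe.
* Problem sizes in the test-suite simulations (60-patient reference
  cohort, 1500-2000 null probes, 100 null-scan replicates) were chosen as
  the smallest designs that leave comfortable margins around the tested
  thresholds.

## Known limitations

* The silhouette space for selecting $k$ and the floor-at-zero affinity
  are documented conventions, not uniquely determined choices; both are
  exposed as arguments.
* LOO probability vectors are pessimistic under null labels (the training
  class rate moves against the held-out label), so permutation AUCs center
  below 0.5; permutation tests should compare against that behavior, not
  against 0.5.
* The purity correction is linear per CpG and assumes constant non-tumor
  methylation; CpGs that vary across non-tumor cell types will be
  over- or under-corrected.
* The TFBS analysis merges sites across all experiments per TF and is
  therefore not tissue-specific.
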