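---
title: "Quantifying chromosomal instability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosomal instability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinscore)
```

# The problem

Chromosomal instability (CIN) — an elevated rate of chromosome and
chromosome-arm gains and losses arising from mitotic missegregation — is
a hallmark of aggressive tumors, in prostate cancer in particular. CIN
leaves two complementary footprints in routine genomic data:

* a **genomic** footprint: recurrent arm-level ("broad") copy-number
  alterations, visible in segmented copy-number profiles;
* a **transcriptomic** footprint: coordinate up-regulation of a module
  of mitosis, spindle and chromosome-segregation genes, summarized by
  expression signatures such as the 70-gene CIN70 list and its compact
  seven-gene prostate-specific distillation PC-CIN (PBK, CEP55, UBE2C,
  MELK, TPX2, PTTG1, CDCA3).

`cinscore` implements both footprints and the machinery connecting
them: per-sample genomic alteration scores from copy-number segments,
mutations and fusions; single-sample signature activation scores;
permutation-based differential expression with cross-cohort
intersection; gene set enrichment analysis (GSEA) with leading-edge
extraction and signature distillation; and a PCA + SVM classifier of
metastasis stage. A synthetic cohort generator with a latent per-sample
CIN level makes every stage testable end to end without external data.

# Copy-number alteration scoring

Input is a SEG-style segment table (sample, chromosome, start, end, and
a GISTIC-style log2 ratio) plus a *genome arm model*: the chromosome-arm
intervals and a gene catalog, which supply the denominators of the two
scores. All coordinates are 0-based half-open; 1-based inclusive input
can be declared on read (`read_seg(coords = "1incl")`).

The chain is:

1. **Thresholding** (`threshold_segments`): a segment is a *gain* when
   its value exceeds 0.3 and a *loss* when it is below −0.3. The
   inequalities are strict: values exactly at ±0.3 are neutral.
2. **Arm splitting** (`split_segments_by_arm`): segments are
   intersected with arm intervals (a centromere-spanning segment is cut
   in two, value copied). Total altered base pairs are conserved
   exactly; this is asserted by tests against an independent
   interval-sweep oracle.
3. **Event calling** (`call_events`): for each (sample, arm, direction)
   the altered intervals are merged; if the merged length exceeds 98% of
   the arm (again strictly) a single *broad* event is recorded for that
   sample/arm/direction, otherwise each maximal merged run is a *focal*
   event. The broad test is applied to the merged per-direction altered
   length, not to single contiguous segments, because segmentation
   fragments arbitrarily; with this rule at most one broad event per
   (arm, direction) can exist, and a whole-chromosome event counts as
   two arm-level broad events. Gains and losses on the same arm are
   independent events.
4. **Scores**: the broad-CNA score of a sample is its broad-event count
   divided by the total number of chromosome arms; the focal-CNA score
   is its focal-event count divided by the number of genes in the
   catalog.

Two further per-sample scores use simple printed constants: tumor
mutational burden (`tmb_score`) is the nonsynonymous mutation count per
megabase of exome, with the 299.029409 Mb consensus exome as the default
denominator, and the fusion score (`fusion_score`) is the ratio of
observed fusion events to the number of fusion types assayed.
Microsatellite instability is a passthrough column (MANTIS-style
precomputed scores); no MSI computation is implemented. Cohort-level
descriptions are provided by `cna_frequency_profile` (per-bin fraction
of samples with an overlapping gain/loss) and
`score_correlation_matrix` (pairwise Pearson correlations; constant
columns are reported as undefined, never coerced to 0).

# Expression preprocessing and signature activation

Raw counts are filtered by total evidence: a gene is kept when its
summed raw count across all libraries reaches 2. The alternative
reading — at least 2 in *every* library — is available via
`per_library = TRUE`; the summed interpretation is the default because
it is the weaker filter and retains rare-but-real transcripts.
Normalization is trimmed-mean-of-M-values (TMM) with the standard trim
parameters (30% on log-ratios, 5% on absolute expression), delegated to
edgeR's implementation behind the `tmm_normalize()` surface; the
returned matrix is log2 counts per million of the factor-adjusted
library size with a 0.5 pseudocount.

Signature activation (`signature_zscore`) is a single-sample Z-score:
each member gene is standardized to zero mean and unit variance across
the cohort, and a sample's score is the sum of its member z-values
divided by `sqrt(k)` (a Stouffer combination; the plain mean of
z-values is available via `combine = "mean"`). Under the default, a
random gene set on null data is asymptotically standard normal, which
makes scores comparable across signature sizes. Standardization is
per-cohort: scores are relative to the cohort they are computed in, and
cross-cohort comparisons should standardize within each cohort first.
Members absent from the matrix are skipped with a message;
zero-variance members are excluded with a warning.

CIN-high/low stratification (`stratify_cin`) defaults to the cohort
median split (scores strictly above the median are "high"); a tertile
mode (lowest/middle/highest) is provided for descriptive displays. The
median is the default because it is parameter-free and reproducible
from the scores alone.

The shipped CIN70 membership is a reconstruction of the published
70-gene chromosomal-instability signature with gene symbols modernized
to current HGNC names (CDK1 for CDC2, PBK for TOPK, AURKA for STK6,
CDC45 for CDC45L, NCAPD2 for CNAP1, SRSF2 for SFRS2, and so on); the
seven PC-CIN genes are printed in the source literature and hard-coded.
No numeric result in the package depends on the exact CIN70 membership
— it seeds synthetic tests and worked examples only.

# Differential expression: the integrative permutation test

`integrative_deg_test` computes, per gene, a Welch t statistic and a
log2 median-ratio between the two groups, builds empirical null
distributions for both from random label permutations (pooled across
genes for stable tail estimates), converts each observed statistic to a
two-tailed empirical p-value with the +1 correction (p is never 0), and
combines the two by a Stouffer-style signed-z sum. Because the two
statistics are strongly dependent — both measure a location shift — the
combined z is **not** referred to a normal distribution: the same
combination is applied to every permuted statistic pair and the
combined p-value is taken empirically against that null. This
permutation calibration keeps the combined p uniform under the null
regardless of the dependence, which the test suite verifies as FDR
control on null cohorts. Benjamini–Hochberg adjustment produces
q-values, and a gene is a DEG when `q < 0.05` and its linear fold
change is at least 1.5 (`|log2 FC| >= log2 1.5`, fold change estimated
as the difference of group means on the log2 scale).

The null construction is canonicalized (samples in lexicographic order,
the smaller group size drawn, complement as the other group) so that
swapping the two groups negates every fold change and preserves every
p-value exactly.

Cross-cohort machinery: `intersect_degs` reports all Venn region counts
over the cohorts' DEG sets and the *shared* list — genes in the focal
cohort's set that are a DEG in at least one other cohort;
`directional_concordance` flags each shared gene as concordant when its
fold-change sign agrees across all cohorts where it is a DEG;
`deg_fc_correlation` is the Pearson correlation of log2 fold changes on
common genes. Degenerate cases (no shared genes, constant fold-change
vectors) are reported as missing, never as 0.

# GSEA: ranking, running sum, leading edge, distillation

Genes are ranked by the canonical Signal2Noise metric,
`(meanA − meanB) / (sdA + sdB)`, with each group standard deviation
floored at `max(sd, 0.2 · |mean|, 1e-8)`. Ties are broken by gene id so
the ranking is strictly ordered — the enrichment score depends on
order, so the tie-break is part of the contract.

The enrichment score (`enrichment_score`) is a Kolmogorov–Smirnov
running sum: walking the ranked list, each gene-set hit adds
`|metric|^w / Σ|metric|^w` and each miss subtracts `1/(N−k)`; the ES is
the signed maximum deviation from zero (first peak on ties). The
default weight `w = 0` is the classical equal-weight KS statistic; the
weighted variant common in GSEA software (`w = 1`) is available by
argument. Significance (`random_geneset_pvalue`) is assessed against a
null of uniformly drawn random gene sets of the same size, with
`p = (1 + #{|ES₀| ≥ |ES|}) / (n_perm + 1)`; phenotype permutation is
deliberately not the default null here. The leading edge of a positive
ES is the set members ranked at or before the running-sum peak (at or
after the minimum for negative ES), in rank order.

`distill_signature` compresses a leading edge into a compact signature:
take the top `k_max` leading-edge genes and intersect with a curated
annotation mask, preserving rank order. The mask is an *input* —
curated biology is not computed. The shipped worked-example fixtures
(`top19_leading_edge_synthetic()`, `mitosis_regulators_synthetic()`)
are constructed stand-ins, labelled `_synthetic` in their filenames:
a rank-ordered top-19 leading edge containing the seven PC-CIN mitotic
genes among twelve CIN70 replication/repair/chromatin genes, and a
mitosis-regulator mask. Distilling the fixture recovers exactly the
seven PC-CIN genes:

```{r distill}
distill_signature(top19_leading_edge_synthetic(),
                  mitosis_regulators_synthetic(), k_max = 19)$genes
```

# The PCA–SVM metastasis-stage classifier

`fit_pca_svm` restricts the expression matrix to the signature genes,
standardizes each gene (correlation-mode PCA, since signature genes sit
on different scales), projects samples onto the top two principal
components, and fits a Gaussian-kernel SVM on the 2-D scores. The
kernel width defaults to the median heuristic on pairwise training
distances in PC space (`gamma = 1/(2·h²)`); the regularization constant
defaults to 1. Both are configurable but no hyperparameter search is
performed. Decision values are oriented so larger means more like the
positive class; genes missing at prediction time are imputed at the
training mean with a message.

Evaluation (`cv_auc`) defaults to stratified 5-fold cross-validation
with **all** preprocessing (standardization, PCA, kernel width) learned
inside each training fold, pooling held-out decision values into one
ROC. A resubstitution mode is provided and labels itself as such in the
output, since published AUCs of this kind of panel are often
resubstitution values. `roc_auc` sweeps thresholds over unique scores
and integrates by trapezoid, which equals the Mann–Whitney pair-count
with half credit for ties; the suite asserts this equality on random
instances.

# The synthetic cohort generator

`generate_cohort` draws a cohort in which one latent variable per
sample — its CIN level — jointly drives all observable layers, because
that joint structure is precisely what the analysis assumes:

* **Stage classes and latent CIN.** Five stage classes mirror a
  diagnostic M-stage design (M0-NM, M0-oligo, M0-poly, M1-oligo,
  M1-poly) with latent CIN means 0.2, 0.4, 0.6, 0.9, 1.2 (unit-free
  scale, within-component sd 0.25) — ordered so metastatic-at-diagnosis
  classes carry more CIN, with the M0 sub-classes uncalibrated middle
  ground. Within M1 classes the latent CIN is a two-component normal
  mixture: with probability `m1_bimodal_weight` (default 1/3, a
  tertile-style split) a sample is drawn from the low mode at the
  lowest non-M1 mean, so the M1 population is bimodal.
* **Copy number.** Each arm of a toy genome (default 46 arms of 1 Mb)
  independently suffers a broad event with probability
  `clip(0.3 · cin, 0, 1)`; broad events emit one segment covering 99%
  of the arm with |value| > 0.3. Focal events (Poisson, mean 3 per
  sample) emit segments of 1–10% of an arm on arms without a broad
  event. The 99%/≤10% construction keeps every planted event
  unambiguous under the strict 98% rule, so classification tests have
  exact expected answers.
* **Expression.** Counts are negative binomial (dispersion 0.1,
  variance `mu + 0.1·mu²`) around per-gene baselines uniform on log2
  ∈ [3, 8], with per-sample library-size factors (log-normal, sd 0.2).
  The planted signature genes (default 70 of 2000) have their log2 mean
  shifted by `cin_effect · cin` (default 1 log2 per unit CIN).
* **Mutations, fusions, flags.** Nonsynonymous mutation counts are
  Poisson with mean `30 · exp(0.5 · cin)`; fusion events Poisson with
  mean `max(0.2, 1 + cin)` against 3 assayed fusion types; the MSI
  passthrough is uniform noise (deliberately unrelated to CIN);
  BCR/CRPC/death flags are Bernoulli with a logistic link on CIN
  (plumbing for survival-style columns, not modeled further).

Reproducibility: one master seed; cohort-level draws and per-sample
draws use sub-seeds derived deterministically from it, so identical
configurations give byte-identical cohorts and partial regeneration is
stable.

What the generator does *not* emulate: tumor purity and ploidy,
allele-specific copy number, GC/length biases, batch effects,
overlapping segment calls, and any read-level artifacts. Passing tests
therefore demonstrate the correctness and statistical calibration of
the machinery under the stated model, not robustness to every artifact
of real tumor profiling.

# Numerical choices and degenerate inputs

* Strict inequalities at all printed boundaries (±0.3 value, 98% arm
  fraction, "at least 2" counts is `>=`).
* Empirical p-values always carry the +1 correction; permutation
  counts below 100 warn.
* The running-sum peak takes the first position on ties; ranking ties
  break by gene id; the median split sends exact-median scores to
  "low" (strictly greater is "high").
* Constant inputs error or return missing explicitly: constant scores
  cannot be stratified, constant score columns correlate as `NA`,
  an empty shared-DEG set has undefined (not zero) concordance.
* Quantile type 7 (R default) for tertiles; geometric-mean-1 convention
  for TMM factors; pseudocount 0.5 in the log2 transform.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` exercise the pipeline at desk
scale, chosen to finish on a single CPU in minutes while leaving
Monte-Carlo error well below the asserted margins: 1000 (suite) / 300
(script) random segment tables against the interval oracle; 200 / 60
null cohorts of 500 genes, 10 vs 10 samples, 300 permutations for FDR
control; planted-effect cohorts of 400–1000 genes with 15–40 samples
per group for power, GSEA and classifier checks; 200 random ranked
lists (N ≤ 50) against the exhaustive ES oracle. Property tests that
assert a *planted* effect size (the "2-fold shift" and "strongly
separated" checks) switch the M1 bimodal mixture off
(`m1_bimodal_weight = 0`), because with the default mixture a third of
M1 samples intentionally carry baseline CIN and the realized shift
would be smaller than the nominal one; the mixture default itself is
exercised by the bimodality and stratification tests.

# Known limitations

* The integrative DEG test is a permutation test: its p-value
  resolution is bounded by the permutation count, and with very small
  groups (3–5 per arm) the pooled null is coarse.
* Broad/focal calling assumes segments of one sample do not overlap;
  overlapping input is rejected, not resolved.
* The CIN70 fixture is a symbol-modernized reconstruction (see above);
  analyses keyed to exact historical membership should supply their own
  list via `gene_signature()` or GMT.
* Signature scores are cohort-relative Z-scores; they are not
  comparable across cohorts without per-cohort standardization, and a
  cohort dominated by high-CIN samples will shift its own zero.
* The classifier reports discrimination (AUC) only; no calibration,
  no multiclass staging, no survival modeling.
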