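---
title: "Parent-of-origin expression in the placenta: model, correction, and calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin expression in the placenta: model, correction, and calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placimprint)
```

# Overview

`placimprint` analyses allele-specific expression (ASE) from reciprocal
mouse crosses to detect genomic imprinting in the placenta. The central
difficulty is that fetal placenta dissections contain maternal tissue, and
contaminating reads are 100% maternal-allele: uncorrected, contamination is
indistinguishable from maternal imprinting. This vignette documents the
model, the parameters that matter, the synthetic-data generator used for
validation, and the numerical and design choices behind the implementation.

# The bias score

With the reference allele fixed per cross type (the dam strain of the
forward direction), P1 is the proportion of a gene's allelic expression
from that allele when maternally inherited and P2 when paternally
inherited. The bias score `b = P1 - P2` ranges from -1 (complete paternal
expression) to +1 (complete maternal expression). Two properties make it
the right statistic for a reciprocal design:

* a cis-regulatory difference between strains shifts P1 and P2 equally, so
  it cancels in the difference;
* 70% expression from one parental allele in both directions corresponds to
  `|b| = 0.4`, the calling threshold.

Allelic counts of each replicate are scaled by a per-million factor of the
replicate's assigned library before pooling (summation) across replicates,
and the chi-square test (Pearson, 1 df, no continuity correction) is run on
the pooled 2x2 direction-by-allele table. Because the scaled cells are not
integers, p-values are approximate under scaling; this mirrors the use of
TPM-normalized counts in contingency tests and keeps the test's count-like
behaviour. Bonferroni correction uses the number of powered, testable genes
in the cross.

Power filtering requires, per replicate, at least 2 diagnostic variants
with assigned reads separated by at least 150 bp (one read length, so the
variants tag independent reads) with at least 20 assigned reads in total,
in at least 4 biological replicates.

# Contamination: estimation and correction

Observed expression is the mixture `(1 - c) e + c m`, where `c` is the
sample's maternal-tissue fraction, `e` embryonic and `m` maternal-tissue
expression (both on the TPM scale). For a balanced gene (expected 1:1
allelic expression), the observed maternal-allele fraction is

```
f(c) = (0.5 (1 - c) e + c m) / ((1 - c) e + c m)
```

which inverts to `c = e (2 f - 1) / (m (2 - 2 f) + e (2 f - 1))`.

**Balanced genes** are powered autosomal genes, absent from the validated
imprinted list, with mean allelic fraction `(P1 + P2)/2` in `[0.45, 0.55]`
(window configurable). This is a reconstruction — the original rule is not
fully specified — and is deliberately permissive about the M:E ratio: genes
with low ratios carry individually noisy estimates, but the inversion is
monotone in `f`, so each gene's estimate is median-centred on the true `c`
and the per-sample median over hundreds of genes is robust.

**Summaries.** The per-sample estimate is the median of the per-gene
inversions; the within-sample maximum (after trimming the top 1% as an
outlier guard) is also reported. Cross-level values used downstream are the
median of per-sample estimates (correction) and their maximum (the
stringent triage threshold). We deliberately do not use a within-sample
maximum over per-gene estimates as the stringent threshold: per-gene
inversions at weakly informative genes have noise spanning most of [0, 1],
so that maximum reflects sampling noise, not contamination.

**Correction.** The predicted contribution of contamination to a gene's
bias is `D(c, r) = c r / ((1 - c) + c r)` with `r = m/e` the gene's
maternal:embryonic expression ratio (per maternal genotype; both reciprocal
genotypes contribute through the mean finite ratio). For a biallelic gene
this is exactly the expected inflation of the raw score. The first-order
form `D = c r` is available (`correction = "product"`); it over-corrects
when `c r` is large, so the exact form is the default. Corrected scores are
clipped to [-1, 1]. Genes with `e = 0` and `m > 0` (infinite ratio) cannot
be corrected and are flagged instead.

Two properties are worth noting. First, the correction removes the
*additive* inflation, not the *multiplicative* dilution of the embryonic
signal: an imprinted gene's corrected expectation is `(2 theta - 1)(1 - D)`,
slightly attenuated relative to the pure-tissue value. Second, because the
estimated `r` enters the correction, genes whose `r` is overestimated by
sampling noise are slightly overcorrected and vice versa; this
regression-to-the-mean artifact bounds how close to zero the post-correction
correlation between score and M:E ratio can get (it stays below 0.05 in
absolute value at the default scale, against ~0.9 before correction). A
deconvolution refinement (re-estimating `e` from the contaminated profile)
reduces the small bias of `c` but amplifies this ranking artifact, and is
therefore not applied.

# Imprintome calling

Calling is a pure cascade — every input gene receives exactly one status:

1. per-cross classification from corrected scores (|b| >= 0.4,
   Bonferroni p < 0.01);
2. replication in the same direction in >= 2 of the 3 reciprocal cross
   types; direction conflicts are excluded outright rather than
   majority-voted (conflicts are flagged, none are expected under the
   generative model);
3. exclusion of genes with M:E > 3 in any contributing cross — these are
   the genes whose apparent maternal bias is most sensitive to residual
   contamination;
4. validated genes and paternally biased genes are classified as imprinted
   (contamination cannot produce paternal bias, so paternal calls need no
   triage);
5. novel maternal candidates survive only with corrected bias > 0.7 under
   the maximum (stringent) contamination estimate in >= 2 crosses and no
   high blood expression (blood is an additional maternal contamination
   source; a gene is blood-high when its blood expression exceeds the
   maximum of all other tissues in a supplied table).

X-linked genes are analysed in female conceptuses only (the male X is
hemizygous and uninformative for imprinting) with the autosomal thresholds:
under imprinted X-chromosome inactivation most genes call maternal, powered
genes failing the threshold are XCI escapers (biallelic), and an Xist-like
gene calls paternal.

Between-lineage divergence of imprinting is declared when the corrected
score differs by more than 0.4 or significance is lost in exactly one
lineage; because only genes imprinted in the ingroup are tested, gain of
imprinting in the outgroup is undetectable by construction.

# Layer-induced expression

zFPKM standardizes log2 FPKM against the actively transcribed background:
the mode of a Gaussian kernel density fit (Silverman bandwidth — a
deterministic default where the reference method leaves the choice open)
and a half-Gaussian fit to the right shoulder,
`sigma = sqrt(pi/2) mean(log2 FPKM - mu | log2 FPKM > mu)`. A gene is
expressed in a layer when its median zFPKM exceeds -3 (strict inequality),
induced when its median expression in the focal layer is at least twice the
sum of its medians in the other two layers ("at least" is inclusive), and
its specificity score is the focal median minus that sum. The expressed
test uses zFPKM (the scale on which the threshold is defined); the
induction rule and specificity score use TPM medians, keeping the 2x rule
library-size-free — statements of the rule usually leave the scale open, so
this choice is made explicit here. In cross-species comparisons, a
discordant gene is counted as a threshold effect when its fold-ratio in the
non-induced species falls in [1.5, 2): an explicit, configurable stand-in
for an unspecified margin.

# Parent-of-origin methylation

Bisulfite reads are partitioned by parent using diagnostic SNVs, with
conversion-aware informativeness: a C/T allele difference cannot be scored
on a C-to-T-converted (plus-strand) read, nor G/A on a minus-strand read;
at other sites an allele C may legitimately read as T (plus strand) and G
as A (minus strand). A read is assigned when informative sites support one
haplotype and none support the other. CpG methylation is called per parent
at reference CpGs, pooling both strands of the symmetric dinucleotide, with
a minimum of 10 reads per site. Replicates are merged (counts summed)
before calling.

The DMR caller is deliberately simple and transparent (the HMM-based callers
usually applied at this step are opaque external tools, and their internals
are not part of this package's contribution): per-CpG one-sided Fisher exact tests between parents (the
side follows the observed level difference), significant CpGs
(p < 0.01, level difference >= 0.3) merged within 300 bp when they share
direction, with a minimum of 5 member CpGs per region. Absolute DMR counts
are therefore not comparable to HMM-based callers; directional properties
(recovery of implanted regions, no directional artifact on symmetric data)
are the validated quantities. DMRs link to genes within a 2,000 bp flank
(closed on the gene side, half-open outward, symmetric) and inherit
imprinted-cluster membership from linked genes.

Maternal methylation is corrected for contamination by removing fraction
`c` of maternal read counts under the conservative assumption that
contaminating reads are fully methylated:
`meth' = max(0, meth - c total)`, `total' = total (1 - c)`.

# The synthetic-data generator

The generator emulates the statistical structure of a reciprocal-cross
placental study; its defaults are the study conditions every validation
runs under:

* 5,000 genes (200 X-linked), log-normal baseline expression on the TPM
  scale; library size 15 million reads; negative-binomial counts with
  shared dispersion 0.1 (standard RNA-seq overdispersion; no canonical
  noise model exists for this design);
* ~40 truly imprinted autosomal genes, half maternal / half paternal, with
  near-monoallelic effects (`theta` in [0.9, 1] resp. [0, 0.1] — canonical
  imprinting is near-monoallelic);
* per-sample contamination from Beta(14, 186) (mean 7%, matching the
  reported scale of placental dissections), 2 x 10 whole-placenta
  replicates per cross; contaminating reads are fully maternal-allele and
  drawn from the maternal-tissue profile (maternal tissue is homozygous for
  the dam genotype);
* maternal:embryonic ratios log-normal with log-sd 0.8, so a realistic
  minority (~8%) of genes exceeds M:E = 3; both expression profiles are
  normalized to the TPM scale so the mixture fraction is well-defined;
* cis effects Beta(60, 60) around 0.5; per-gene read assignability
  (informativeness) Beta(5, 5); diagnostic-variant positions fixed per gene;
* X-linked genes at `theta = 0.97` in females (imprinted XCI), 8 escapers
  at 0.5, one Xist-like gene at 0.02; only female conceptuses are
  simulated by default (the male X would conflate hemizygosity with
  imprinting);
* layer profiles with mild Dirichlet variation; 20% of genes induced in one
  layer at folds 2.2-6 of the sum of the others;
* bisulfite haplotypes with planted CpGs and SNVs that never disrupt CpGs,
  conversion rate 0.99 by default.

What the generator does **not** emulate: mapping bias and reference-genome
asymmetries, positional dependence of diagnostic variants within
transcripts, sample-specific batch structure, correlated dispersion, PCR
duplicates, or genes whose imprinting is isoform- or layer-restricted.
Passing tests therefore demonstrate correctness of the statistical
machinery under the declared model, not robustness to every artifact of
real data. Ground-truth labels are carried in separate objects and never
consumed by pipeline stages.

Validation sizes were chosen at desk scale: the full-pipeline checks run on
the 5,000-gene default with three cross types; estimator-consistency and
null-property checks use 1,200-3,000 genes; brute-force oracle comparisons
use hundreds of randomized small instances.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion happens
  only at IO boundaries (GFF3 is 1-based closed, BED is native).
* Zero FPKM maps to a -Inf zFPKM sentinel; such genes are never expressed.
* A chi-square table with a zero row or column returns p = 1 with a
  degenerate flag rather than NaN; a direction with zero assigned
  expression makes P1/P2 undefined and the gene unpowered.
* Per-gene contamination estimates are clipped to [0, 1]; genes with zero
  maternal-tissue expression carry no contamination signal and are dropped
  from estimation; if none remain, the sample's estimate is 0 with a
  warning.
* Ties: the induction rule is inclusive (>= 2x), the M:E exclusion strict
  (> 3), the bias cutoff inclusive (>= 0.4), the DE thresholds inclusive
  (>= 1, <= 0.05), matching the conventional statement of each rule.
* The Bonferroni factor is the number of powered, testable genes per cross
  type.

# Known limitations

* The balanced-gene definition and the contamination estimator are a
  documented reconstruction of a procedure whose full details are not
  public; the estimator trades per-gene efficiency for robustness
  (median of monotone inversions).
* With ~500 balanced genes the per-sample estimate carries a standard error
  near 0.004, so worst-case errors across 20 samples approach 0.01; several
  thousand balanced genes (the default scale) keep every sample within
  0.01.
* Corrected scores cannot undo the multiplicative dilution of embryonic
  signal by contamination; strong imprinting is attenuated by a factor
  (1 - D).
* The DE engine included for hermetic synthetic runs (edgeR exact test with
  BH adjustment) is plumbing, not a contribution; real analyses should
  supply result tables from a full DE pipeline.
* The DMR caller's absolute counts are not comparable to HMM-based
  detectors.
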