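---
title: "Decoding cell-type origins of cfDNA from fragment-level methylation"
author: "cfOrigins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding cell-type origins of cfDNA from fragment-level methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfOrigins)
```

## The problem

Dying cells release short DNA fragments (cell-free DNA, cfDNA; peak ~167 bp)
into the blood. Most of it comes from leukocytes, but injured solid organs
contribute small, diagnostic amounts. DNA methylation is strongly
cell-type-specific and stable across individuals, so the methylation pattern
of each sequenced cfDNA molecule carries a signature of the cell type that
released it. `cfOrigins` implements the computational chain that turns
fragment-level bisulfite methylation calls into cell-type contributions:

1. **Segmentation** of the CpG-indexed genome into blocks of homogeneous
   methylation across reference samples.
2. **Marker (DMB) discovery**: one-vs-all selection of cell-type-specific
   differentially methylated blocks by soft-margin separation.
3. **Fragment classification**: a fourth-order Markov model per marker and
   cell type, with Bayesian hard assignment of each fragment.
4. **Quantification**: averaging over markers, normalization to fractions,
   rescaling of endothelial subtypes within the pan-endothelial estimate,
   and conversion to genome equivalents per mL of serum (Geq/mL).
5. **Validation**: an in-silico mix-in protocol that spikes known
   proportions of target fragments into a leukocyte background.

Everything is exercised on synthetic data with full ground truth; see
"What the generator does and does not emulate" below.

## Data model

Fragment-level calls live in PAT-style tables: chromosome, global CpG index
of the first covered site, a pattern over `C` (methylated), `T`
(unmethylated) and `.` (missing), and a multiplicity. Per-site summaries
live in BETA-style tracks (methylated and total calls per CpG). The
`CpGIndexMap` ties global CpG indices (0-based internally, 1-based on disk,
matching the prevailing PAT dialect) to genomic coordinates. Blocks are
`GRanges` with the CpG-index interval carried in metadata columns.

## Segmentation model

A block is scored per sample by the marginal likelihood of its aggregated
counts under one latent methylation level $\theta \sim \mathrm{Beta}(\alpha,
\beta)$:

$$\log P(\text{block}) = \sum_{s}\left[\log B(\alpha + m_s,\ \beta + t_s -
m_s) - \log B(\alpha, \beta)\right] - \lambda$$

with $m_s$ methylated of $t_s$ total calls in sample $s$ and a per-block
penalty $\lambda$. Dynamic programming over CpG indices finds the tiling
that maximizes the total score subject to a 5 kb genomic span cap; ties
break toward fewer blocks, then earlier boundaries, so output is
deterministic. Uncovered sites contribute nothing (no imputation). The
published segmentations this emulates do not state their scoring function;
ours is a declared stand-in validated against exhaustive search on small
instances, not a reproduction.

**Default penalty.** $\lambda = 6$ per channel. Calibration: across
hundreds of homogeneous instances at depth 30 the largest spurious split
gain is ~5 for one channel and shrinks as channels are added (the
beta-binomial marginal already charges an Occam factor per channel), while
a true level change of 0.5 at depth 20 gains more than 10 per boundary
site. $\alpha = \beta = 1$ (uniform prior on the latent level).

## Marker discovery

Candidates must cover ≥ 3 CpGs, span < 2 kb, and carry ≥ 10 fragment
observations *in every sample of the target group* (the strict per-sample
reading; it prevents markers driven by one deep sample). For each group,
each block is compared one-vs-all in both directions:

* **delta-beta** (hard margin): `min(background) − max(target)` for
  hypomethylated markers, mirrored for hypermethylated ones;
* **soft margin**: `quantile(bg, 0.1) − quantile(target, 0.8)` for
  hypomethylated markers (mirrored for hypermethylated: `quantile(target,
  0.2) − quantile(bg, 0.9)`), allowing outliers.

Markers pass at soft margin ≥ 0.4 (human) or ≥ 0.35 (mouse; boundary
retained) and are sorted by delta-beta. Quantiles use linear interpolation
between order statistics (R type 7); the convention matters because the
threshold sits directly on the quantile scale, so it is fixed and
documented. A block enters a comparison only when its beta is missing in at
most 10% of samples (aligned with the 90%-coverage clustering rule);
missing samples are excluded from the quantiles.

The atlas is hierarchical: a bulk-immune tier separating hematopoietic from
solid-organ cfDNA, individual solid-organ cell types, pan-endothelial
markers shared by all endothelial populations, and tissue-specific
endothelial subtypes whose marker sets must not overlap (enforced by the
`MethylAtlas` validity method). Groups with more than 200 markers are cut
to the top 200 by the delta-beta sort.

## Fragment classification

Within a marker, the methylation state of each CpG in a fragment is
modelled as depending on up to 4 adjacent previous called sites in the
fragment. Per marker, conditional tables are estimated for the target group
and for the pooled remaining samples (each sample rescaled to the pool's
mean depth so no sample dominates). Estimation uses an additive pseudocount
of 0.5 per outcome; a context never observed in training backs off to its
longest observed suffix. A `.` (missing) site is skipped and *resets* the
context: a gap breaks the adjacency the order-4 dependence assumes, so
conditioning across it would be conditioning on non-adjacent sites.

Each fragment's posterior is $\pi L_t / (\pi L_t + (1 - \pi) L_b)$ with
per-tier priors $\pi$ = 0.85 (bulk immune), 0.10 (pan-endothelial), 0.05
(other solid organs), and hard assignment at posterior > 0.5 (a tie goes to
the background — conservative toward not inflating rare cell types).

**Minimum called sites per classified fragment: 5.** An order-4 model
needs order + 1 = 5 called sites before a single full-depth context is ever
exercised; fragments below that carry mostly order-≤3 information and are
systematically under-assigned at the 0.05 prior, which biases admixture
recovery. The threshold is configurable (`minCalled`).

Per group, assigned fractions are averaged (unweighted) over markers with
at least one eligible fragment; a coverage-weighted mode exists but is off
by default. Raw proportions of the composition tier (bulk immune, solid
organs, pan-endothelial) are normalized to sum to 1; endothelial subtype
estimates are then rescaled to partition the pan-endothelial fraction
exactly. Fractions convert to Geq/mL as `fraction × concentration (ng/mL) ÷
haploid genome mass` (3.3×10⁻³ ng human, 3.0×10⁻³ ng mouse) — the mass
enters as a denominator so that ng/mL becomes genomes/mL.

## In-silico mix-in validation

`runMixinExperiment()` spikes known fragment-count fractions of one cell
type into a leukocyte background over the atlas' full marker panel
(default grid 0.05%–15%, 3 replicates, 200 fragments per panel marker,
plus a zero-admixture control), deconvolves every mixture through the
complete pipeline, and reports the mean and SD of the target's normalized
fraction. Design choices:

* Ratios are fragment-count fractions; target counts round half to even.
* Each replicate's seed is shared across ratios (common random numbers):
  the pool is permuted once and prefixes taken, so mixtures within a
  replicate are nested and the recovery curve is compared on common draws —
  a standard variance-reduction device that leaves each ratio's marginal
  distribution untouched.
* The reported prediction is the normalized fraction from the full
  deconvolution, not the raw per-marker proportion, because the sum-to-1
  constraint cancels most of the shared hard-assignment bias across
  classifiers.

With one replicate the SD column is `NA`, never 0.

## The synthetic data generator

`generateReference()` emulates a reference WGBS atlas: six leaf cell types
(leukocyte; hepatocyte, cardiomyocyte, lung epithelial; two endothelial
subtypes, CPEC-like and LSEC-like, under a pan-endothelial tier), 20 marker
blocks per type (real atlases carry 69–374 per type), 50 null blocks, and 3
replicate samples per type. Blocks carry 3–15 CpGs spaced 30 bp apart and
sit 6 kb apart so each segments independently under the 5 kb cap. Planted
levels are 0.05 (marker side) vs 0.85 (background), with 86% of per-type
markers hypomethylated; per-sample block levels get Gaussian noise (sd
0.02). BETA tracks draw Poisson(50) depth with binomial counts;
in the noiseless case (sd 0, error rates 0) counts are deterministic so
block betas equal planted levels exactly.

Fragments are emitted from a two-state order-4 chain,
$P(\mathrm{C}\mid\text{context}) = p + \rho(\bar{c} - p)$ with persistence
$\rho = 0.1$ over the mean of up to 4 previous true states, so generated
data genuinely exercise the order-4 likelihood. Fragments cover 5–7 CpGs
(a ~167 bp molecule spans ~5.6 sites at 30 bp spacing); reference samples
carry 300 fragments per block (hybridization capture yields hundreds-fold
depth over targeted blocks). Conversion noise is applied per call:
methylated sites read `T` at rate 0.005 (inappropriate conversion) and
unmethylated sites read `C` at rate 0.005 (conversion failure, the quantity
the unmethylated lambda phage spike-in estimates); interior sites go
missing at rate 0.02. One master seed fans out to per-component child
seeds, so every artifact is reproducible byte for byte.

**What passing tests do and do not show.** The generator reproduces the
structural features the method relies on — planted cell-type-specific
blocks, within-fragment co-methylation, coverage noise, conversion error,
leukocyte-dominated mixtures — but not sequence-level effects (GC bias,
capture efficiency, mapping artifacts, fragment-end biology) or real
biological heterogeneity between individuals. Recovery on synthetic data
therefore validates the algorithmic chain, not clinical performance.

## Worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(seed = 1, outDir = "run1")
bundle <- runPipeline(cfg)
resultTable(bundle$results$serum_01)
# mix-in validation of hepatocyte detection
pools <- mixinPools(bundle$ref, "hepatocyte", seed = 2)
rep <- runMixinExperiment(mixinDesign(seed = 3), bundle$atlas,
                          bundle$models, "hepatocyte",
                          pools$target, pools$background)
rep$summary
recoveryMetrics(rep)
```

## Problem sizes, tolerances and degenerate inputs

* The default end-to-end run uses ~1,800 CpGs in 190 blocks, 18 reference
  samples (~57,000 fragments each), and serum samples of ~28,000 fragments;
  it completes in a few minutes on one CPU and is bit-identical across
  runs at a fixed seed.
* Segmentation is validated against exhaustive search on instances of ≤ 12
  CpGs; posteriors against raw-probability chain-rule enumeration on all
  patterns of ≤ 6 sites (tolerance 1e-12).
* Degenerate inputs are explicit errors: meth > total in a BETA record,
  fragments past the CpG map, zero target training fragments at a marker
  (named), an all-zero proportion vector at normalization, incomplete
  pairs under a paired test, overlapping endothelial-subtype marker sets
  (offending blocks listed). A zero-coverage block has a missing beta; a
  marker with no eligible fragments is excluded from the group mean and
  flagged when all markers are empty.

## Group statistics on deconvolved outputs

`runGroupTests()` applies the design-appropriate standard test per cell
type — Kruskal-Wallis (unpaired multigroup), Friedman (paired repeated
measures), Wilcoxon signed-rank (paired two-condition), Spearman (dose
association) — through the standard R implementations, and adjusts p-values
across cell types with Benjamini-Hochberg. The two-stage linear step-up
procedure is not re-implemented; BH is the default and the only procedure
exposed, which is the main place this package simplifies the surrounding
statistical reporting.

## Known limitations

* The segmentation score is a stand-in consistent with "homogeneous
  methylation per sample", not a reproduction of any published tool's
  internal score.
* Hard assignment at fixed priors is biased for fragments with weak
  patterns; the normalization step compensates only partially. Soft
  (fractional) assignment is out of scope.
* The generator's single persistence parameter cannot reproduce the
  bimodal within-block co-methylation of real data (where target molecules
  at selected markers are almost always fully concordant), so synthetic
  sensitivity is, if anything, pessimistic.
* Real genome coordinates, BAM/FASTQ handling and the binary BETA encoding
  are out of scope; all I/O is the text PAT/BETA/BED/TSV/YAML dialects.
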