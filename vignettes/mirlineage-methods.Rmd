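---
title: "Methods: miRNA lineage signatures from Ct values to chromatin"
author: "mirlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA lineage signatures from Ct values to chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlineage)
```

# The problem

Sorted mammary epithelial subsets — MaSC/basal, luminal progenitor (LP),
mature luminal (ML), plus stroma — each carry a distinctive miRNA
expression program. `mirlineage` implements the full computational chain
that (i) turns TaqMan low-density-array Ct values into normalized log2
expression and subset signatures, (ii) asks whether each signature
miRNA's predicted target mRNAs move in the opposite direction, (iii)
scores breast-tumor miRNA-seq profiles against the normal-subset
signatures, and (iv) relates miRNA expression changes to H3K4me3
(activating) and H3K27me3 (repressive) histone marks at miRNA loci.

Every stage is driven by a synthetic-data generator with known ground
truth, so calibration and recovery are tested properties, not
assumptions.

# Ct preprocessing

**Transform.** The array's maximum measurable Ct is 40, and wells
reported as `Undetermined` are coerced to that ceiling. Expression is
`E = 40.5 - min(Ct, 40)`, so an undetected well maps to `E = 0.5` and
each earlier cycle adds one log2 unit. Treating undetected wells as the
censoring bound rather than as missing keeps the probe-wise linear
models balanced; it is a deliberate choice, and the generator can emit
the literal `Undetermined` token to exercise the reader.

**Normalization.** Between-sample biases are removed by cyclic loess
with housekeeping probes up-weighted 100-fold (defaults: span 0.7, five
iterations; mouse housekeeping set `{U6}`, human `{U6, RNU6B, RNU24,
RNU43, RNU44, RNU48}`; the plant spike-in ath-miR159a is excluded from
fitting and never adjusted, and no background subtraction is
performed). The dialect implemented is the classical all-pairs scheme:
per iteration, for every unordered sample pair an M-versus-A curve is
fitted by degree-1 loess (tricube weights multiplied by the probe fit
weights) and `fitted/(2(n-1))` is moved between the two samples. The
original analysis named a specific software dialect of cyclic loess;
exact reproduction of that dialect is not claimed — this one is
documented, fixed, and tested for the properties that matter (constant
shifts shrink geometrically; identical samples are untouched to 1e-12;
probe totals are conserved; the procedure is equivariant to sample
order). The 100x weight enters only the local fit, not the span
neighborhood.

**Filter.** Probes are kept when the normalized value reaches 2 in at
least three samples (both bounds inclusive); housekeeping and
negative-control probes leave the analysis set but stay in the
provenance attribute.

# Linear models and moderated statistics

Subset means use a cell-means parameterization (one coefficient per
subset), which makes every comparison a plain weight vector: subset
signatures are `(1, -1/2, -1/2)` against the other two epithelial
subsets, the stroma contrast is stroma versus the mean of the three
epithelial subsets, and a moderated F over any two-contrast basis
spanning the subset differences gives the three-subset ANOVA (the test
is invariant to the basis chosen).

Probe-wise residual variances are shrunk by empirical Bayes: sample
variances are modeled as scaled F, the prior degrees of freedom `d0`
and prior variance `s0^2` are estimated by matching the first two
moments of `log s_g^2` (digamma/trigamma inversion), and posterior
variances `(d0 s0^2 + d_g s_g^2)/(d0 + d_g)` feed t-statistics on
`d0 + d_g` df. When the spread of `log s_g^2` does not exceed its
sampling component the prior df is infinite and the pooled (arithmetic
mean) variance is used. The implementation is validated to 1e-10
against the reference empirical-Bayes implementation in the test suite,
and hyperparameter recovery (±25% on `d0`, ±10% on `s0^2` at 5000
probes) is an acceptance criterion. False discovery rates use our own
Benjamini–Hochberg step-up, applied within each analysis family
separately.

For the cross-species analysis, probes are matched by symbol after
stripping the `mmu-`/`hsa-` prefix (case-insensitive; `-3p/-5p`
suffixes must agree), and the combined model adds a species main-effect
covariate without species-by-subset interaction — only concordant
changes survive. Batch-corrected values (species effect subtracted in a
model that protects subset effects, with the first-appearing species as
reference) are used for clustering and ordination only. The MDS
distance between two samples is the root-mean-square of their top-k
(default 500) largest absolute log2 differences — the "typical" fold
change of the most discordant probes.

# Rotation tests of miRNA–target inverse correlation

For each DE miRNA, its predicted target genes (consumed as a
TargetScan-style table; the prediction algorithm itself is out of
scope) are tested for coordinated movement opposite to the miRNA's own
fold change. The set statistic is the arithmetic mean of the per-gene
moderated t-statistics — matching the "average fold change of the
targets" reading — and alternatives (maxmean, median) were deliberately
excluded. Each gene's data are reduced to a `(d+1)`-vector: the
component along the contrast direction plus the residual-space
coordinates, spherical under the null. Rotations replace the contrast
direction with uniformly random unit vectors shared across genes (so
inter-gene correlation is preserved), and the one-sided p-value is
`(b + 1)/(B + 1)` over `B` rotations (default 9999; the original's `B`
is not stated, so no reproduction claim is made). The minimum
attainable p is therefore `1/(B+1)`; calibration is checked by KS on
mid-p over independent null datasets.

Genes selected for GO enrichment must be (i) targets of a DE miRNA and
(ii) themselves DE at FDR < 0.2 with sign opposite to the miRNA; the
enrichment test is the upper-tail hypergeometric against a supplied
gene-to-term table (never a live database, for version independence).

# Tumor signature scores

TCGA-style miRNA-seq counts are collapsed (technical replicates share an
analyte ID and are summed; isoform rows are summed into their parent
symbol; only primary solid tumors kept), filtered at >= 1 CPM in >= 29
samples, TMM-normalized (30% M-trim, 5% A-trim, inverse-variance
weights, reference = sample with upper-quartile CPM closest to the
mean), and converted to log2 CPM with a prior count of 0.25 scaled by
effective library size — effective rather than raw sizes is our choice
where the original is silent. A tumor's score for a subset is
`sum(logFC * logCPM) / sum(|logFC|)` over the subset's signature
miRNAs (FDR < 0.05 fold changes from the normal-subset contrast). The
subtype comparison (one-sided Wilcoxon rank-sum of the named subtype
against all others pooled) is a robustness choice documented here, not
a claim about the original's unstated test.

# Epigenome linkage

miRNA loci (internally 0-based half-open; GFF input converted at the
reader) are flanked 3 kb on both sides, strand-ignorantly; 3p/5p
isoform partners share one merged interval. Reads count toward every
interval they overlap by >= 1 bp, with no duplicate or mapping-quality
filtering (the original's filtering is unstated; none is applied here).
Mark fold changes come from a one-factor negative-binomial log-linear
model at fixed dispersion 0.05 with a library-scaled prior count of 1
added to the counts (and twice the prior to the offsets), shrinking
low-count fold changes toward zero; dispersion 0 reduces to the Poisson
closed form. Expression log2FC for the same subset pair is regressed
through the origin on the mark log2FC (`slope = sum(xy)/sum(x^2)`,
`SE^2 = sum((y - bx)^2)/((n-1) sum(x^2))`), restricted to the top 200
DE miRNAs by p (ties: |logFC|, then symbol); a 140-row matrix of
expression/H3K4me3/H3K27me3 fold changes is emitted for heatmaps.
Per-base coverage is exported as reads-per-million bedGraph for
visualization only.

# What the generator emulates — and what it does not

The generator reproduces the statistical structure the pipeline
assumes: Gaussian noise on the Ct scale (the true TaqMan replicate
noise model is unpublished; Gaussian-on-Ct is the documented
assumption), subset-specific planted shifts, sample-wide plate shifts
for the normalization to remove, stable housekeeping probes spread over
the abundance range, ceiling-censored undetected wells, mRNA target
sets moved opposite to their miRNA with decoys mixed into the map,
negative-binomial tumor counts (dispersion 0.1) with technical
replicate and isoform structure, and ChIP read piles whose intensity is
coupled to expression fold changes with the stated slopes (+0.5 active,
−0.5 repressive).

Deliberate simplifications: no amplification-efficiency or PCR
chemistry effects, no probe-specific variance structure, no
sequence-level read content, uniform read placement within a locus
window, and random (rather than abundance-dependent) well drop-out.
Censoring is applied to target wells only — censoring the endogenous
controls would remove the anchor the weighted normalization requires,
which essentially never happens in practice. A green test therefore
establishes correctness of the computations and calibration under the
stated model, not robustness to every pathology of real plates.

Documented generator constants: housekeeping noise SD 0.1 log2 units;
tumor NB dispersion 0.1; default plate-shift SD 0.5 Ct; default
undetected fraction 0.05. The calibration and recovery criteria state
their own worlds (probe counts, effect 3, noise 0.5, four replicates)
and set drop-out to zero so the measured property is not confounded
with censoring, which is exercised by its own tests.

# Numerical choices and degenerate inputs

* Zero residual variances are excluded from prior estimation and simply
  shrink to the prior; if more than half the variances coincide the
  prior df becomes infinite without overflow.
* The trigamma inverse uses Newton iteration with asymptotic guards at
  both extremes.
* Rotated residual variances are floored at zero before the posterior
  shrink (pure numerical guard; exact zeros occur only when a rotation
  aligns with the data).
* Single-sample normalization warns and returns the input; an
  all-housekeeping matrix normalizes with constant weights.
* TMM pairs sharing no positively expressed gene with the reference are
  an error; factors within 1e-6 of log-zero snap to exactly 1.
* Ties in DE tables sort by p, then probe ID, so output order is stable.
* One global seed is expanded into fixed per-stage seeds in the
  pipeline runner; every stochastic operation takes an explicit seed.

# Known limitations

* The loess dialect is not byte-identical to the original software's
  "affy" variant, so probe counts on the deposited data may shift by a
  few probes.
* The rotation-test `B` and set statistic of the original are unstated;
  defaults are documented above.
* Fragment-level (paired-end) ChIP input is out of scope; each BED line
  is one read.
* No PAM50 calling, no TargetScan internals, no GO retrieval — those
  artifacts are consumed as tables.

# Session info

```{r}
sessionInfo()
```
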