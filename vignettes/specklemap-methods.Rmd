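---
title: "Mapping speckle-proximal chromatin from RNA-DNA ligation pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping speckle-proximal chromatin from RNA-DNA ligation pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specklemap)
```

## The scientific problem

Nuclear speckles are membraneless bodies whose protein cores (SC35, SON)
barely touch chromatin, so ChIP-style assays fail to reveal which parts of
the genome sit near them. Noncoding RNAs that accumulate at the speckle
periphery — the spliceosomal snRNAs (U1, U2, U4, U4atac, U5, U6, U6atac,
U11, U12), 7SK and Malat1, collectively *nsaRNAs* — reach far enough toward
chromatin that RNA–DNA proximity-ligation sequencing (MARGI-style chimeric
read pairs) records their genomic neighbourhoods. Clustering the DNA ends of
nsaRNA-containing pairs yields broad domains (*nsaPeaks*) that serve as a
genomic footprint of speckle proximity. specklemap implements that pipeline
end to end: pair classification, nascent-transcript filtering, broad-domain
calling, a battery of association statistics, and a single-cell DNA FISH /
immunofluorescence colocalization analysis — together with a synthetic-data
generator so that every stage runs and is testable without any external
download.

## Pair classification

Each ligation pair carries an RNA-end interval and a DNA-end interval. The
classifier assigns one RNA class per pair with precedence
`nsaRNA > rRNA > p_pre_mRNA > other`:

* **nsaRNA** — the RNA end overlaps an exon of a configured species gene.
  Overlap is strand-ignored (the loci are unambiguous), and a pair counts
  once toward its species regardless of how many annotated gene copies it
  touches.
* **rRNA** — the RNA end overlaps an rRNA gene or maps to the rDNA
  repeating-unit pseudo-chromosome. Modeling rDNA as an extra chromosome in
  the chrom.sizes table keeps a single coordinate frame while matching the
  practice of aligning rRNA reads against the repeating unit separately.
* **p_pre_mRNA** (posttranscriptional pre-mRNA) — the RNA end straddles an
  exon–intron junction of a coding transcript on the matching strand,
  covering at least 1 nt of exon and, by default, at least 10 nt of the
  adjacent intron. Strand must match because pre-mRNA identity is
  strand-specific; the exon/intron arithmetic alone is symmetric.
* **other** — everything else.

The precedence order resolves reads that overlap genes of several classes:
a specific annotation (an snRNA locus) beats a generic one (a coding intron
hosting it). The classes are treated as disjoint analyses downstream.

**Nascent filter.** A pair whose two ends are near-adjacent on the same
chromosome likely reflects an RNA still tethered at its transcription locus,
not a spatial contact. `flag_nascent()` marks pairs whose same-chromosome
gap — the number of bases strictly between the two intervals, 0 for
overlapping ends — is at most 2,000 nt, inclusive. Inclusive-at-threshold is
the conservative reading (removes more potential nascent signal). One
configurable threshold serves both the general pipeline filter and the
pre-mRNA analysis; the boundary behaviour (1,999 / 2,000 flagged, 2,001
kept) is pinned by tests.

## Broad-peak calling

The published analysis delegated broad-domain calling to an external tool
(Homer, broad-peak option); specklemap re-implements the step as a
documented, deterministic algorithm rather than promising bit-identical
output of that tool:

1. reduce each DNA end to its midpoint (reads are ~30 bp; domains are
   100 kb–13 Mb, so the midpoint carries all positional information);
2. tile the genome in 25-kb bins and count midpoints per bin;
3. mark bins whose count exceeds `max(1, 4 x genome-mean count per bin)`;
4. merge marked bins closer than 100 kb;
5. keep merged regions with at least 9 reads, at least 100 kb span, and an
   overall read density that still exceeds the step-3 enrichment rule over
   the full region span.

The region-level density requirement in step 5 is what separates true broad
domains — where essentially every bin is enriched — from chance pairs of
marginally-enriched noise bins that the merge step would otherwise bridge
into a pseudo-domain; it is the calibration that makes a uniform (sporadic)
read cloud yield no peaks at all. The enrichment ratios make the caller
invariant to read duplication and to record order. The 100-kb span floor for *broad peaks*
follows the smallest reported domain size; the much stricter 500-kb /
9-read pair of cutoffs belongs to the *candidate-peak* scatter analysis
(`cluster_dna_ends()` + `candidate_peaks()`, single-linkage clustering of
midpoints at a 100-kb joining distance), and both paths are exposed because
the published account does not state whether the final domains were
constrained by the candidate thresholds.

Window width, enrichment fold, merge gap and span floor are all
`peak_params()` fields. At the synthetic study conditions (below), a 25-kb
bin holds ~1.5 reads on average genome-wide versus ~10–12 inside planted
domains, so the 4-fold rule separates the two regimes with a comfortable
margin while a single noise bin (Poisson, P(X > 6) under the genome mean)
almost never survives the span floor.

## Association statistics

* 2x2 tables use the sample cross-product odds ratio `(a d)/(b c)`; a zero
  off-diagonal yields `Inf` with a warning, or the Haldane–Anscombe 0.5
  correction on request. Note that for the published single-cell table
  (170/40 vs 110/83) the cross-product ratio is 3.21 while the source
  prints 3.1 by an unstated estimator; specklemap reports the cross-product
  ratio and documents the discrepancy rather than matching an unknown
  formula.
* The chi-square test is Pearson's with 1 df and no continuity correction
  by default — the plain "chi-square test"; Yates' correction is a flag.
  Fisher's exact test is two-sided.
* Density profiles count midpoints in fixed-width bins tiling each
  chromosome (1 Mb by default, the genome-browser scale used for the
  published density curves); profile correlations use Spearman with
  mid-ranks for ties, the standard treatment for count data.
* Permutation nulls re-place each interval uniformly at random on its own
  chromosome, preserving its length and rejecting overlaps (up to 1,000
  attempts). This chromosome-preserving uniform shuffle is the most common
  convention when the original account names only "permutation test";
  assembly-gap masking is unnecessary on the synthetic genome and therefore
  not implemented. Empirical p-values use the add-one estimator
  `p = (1 + #{null >= obs}) / (1 + n_perm)` — unbiased, never zero, and
  "p < 0.001" with 1,000 permutations means the observation beat every null
  draw (p = 1/1001). `permutation_test()` accepts any deterministic statistic
  over (shuffled, fixed); for the heavily used reads-in-peaks statistic,
  `permutation_test_points()` evaluates the identical statistic and shuffle
  in plain vector arithmetic (sorted positions + `findInterval`), consuming
  the random stream in the same order so the two routes give draw-identical
  null samples under one seed - a property the test suite pins.
* `boundary_alignment()` counts peak boundaries within a tolerance of any
  TAD boundary, and peaks tiled by consecutive TADs. The default tolerance
  is 40 kb, one Hi-C bin, because TAD boundaries are bin-quantised and the
  source states no tolerance.

## Single-cell imaging

Stacks are two-channel 3D voxel grids (FISH, SC35) with a nucleus mask.
Detection thresholds each channel inside the nucleus with Otsu's method,
floored at the in-nucleus mean plus three standard deviations so that a
channel with no real signal yields an empty mask instead of a split of the
noise distribution; both terms scale linearly, making detection invariant
under positive intensity rescaling. Connected components use the
26-neighbourhood in 3D (a per-slice 8-neighbourhood mode is available for
fidelity to slice-wise particle analysis); components below `min_voxels`
(4 for FISH spots, 5 for SC35 clusters) are discarded and centroids are
intensity-weighted.

Colocalization is the conservative pixel-overlap rule: a FISH spot is
*isolated* only when none of its voxels is SC35-positive — a single positive
voxel makes it colocalized. This overestimates colocalization relative to
any centroid-distance rule, which is the stated intent (conservative for
calling isolation). Per-image summaries average spots within an image;
images with zero detected spots are excluded with a warning. Distance
analysis measures 3D centre-to-centre Euclidean distance from each spot to
its nearest cluster in voxel units, treating voxels as isotropic (physical
voxel size is metadata only); histograms bin distances into (d−1, d] for
d = 1..10, with exact zeros kept in bin 1 so counts are conserved, and a
remainder bucket beyond 10. Group comparisons are Welch's t-test on
per-image fractions and the two-sample Kolmogorov–Smirnov test on pooled
distances.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed and every
acceptance property is asserted under them.

**Genome and annotation.** Four autosome stand-ins (60/60/55/55 Mb) plus a
43-kb rDNA repeating unit. One single-exon gene per nsaRNA species (snRNA
genes 107–331 bp, Malat1 8.7 kb), 40 coding genes of 5–8 exons
(exons 120–300 bp, introns 800–4,000 bp, far above the 10-nt junction
threshold), and a 13-kb rRNA gene on the rDNA unit, all placed uniformly
with overlap rejection.

**Pairs.** Per-class counts default to 15,000 nsaRNA, 15,000 pre-mRNA,
2,000 rRNA and 5,000 intergenic pairs — the nsaRNA count matching the
~15k-pair scale of the real HEK dataset. Pair construction, per class:

* a 10% nascent fraction places the DNA end at a gap drawn uniformly from
  0–2,000 nt of the RNA end; all *intended non-nascent* same-chromosome
  placements are re-drawn until their gap exceeds the threshold, so truth
  labels and the filter agree exactly (pairs on the 43-kb rDNA unit instead
  record the label the distance rule implies);
* in the **speckled** scenario, non-nascent nsaRNA and pre-mRNA DNA ends
  fall inside planted domains with probability 0.72 (the published
  reads-in-peaks fraction), positioned length-proportionally; background
  draws explicitly exclude the domains so the planted fraction is exact;
* pre-mRNA DNA ends target a different chromosome with probability 0.93
  (the published interchromosomal fraction);
* rRNA DNA ends hit the rDNA unit with probability 0.5, and every other
  class hits it at the baseline rate that makes the planted
  rRNA-vs-rest x rDNA-vs-genome odds ratio equal 404, the published
  HEK value;
* five deterministic boundary-probe pairs (gaps 1,999/2,000/2,001 nt;
  junction reads with 10 and 9 intronic nt) are appended for threshold
  pinning.

**Planted domains.** Ten domains with lengths drawn log-uniformly over
[100 kb, 13 Mb] — the published domain size range — then rescaled so the
domains jointly cover 9% of the autosomal genome. The rescaling is a power
consideration settled at design time: with 15,000 reads, an unnormalised
log-uniform sum varies by an order of magnitude across seeds, which would
swing the in-domain read density across the enrichment threshold and make
domain recovery a lottery rather than a property of the method. At 9%
coverage the expected in-domain density (~10 reads per 25-kb bin against a
genome mean of ~1.5) sits comfortably above the 4-fold rule for every draw.
Domains keep at least 1 Mb of separation so that distinct planted domains
remain resolvable at the caller's 100-kb merge scale.

**Background field.** In the speckled scenario all background DNA ends
share a per-megabase log-normal weight field (sdlog 0.8, mean 1). This is
what makes the nsaRNA and pre-mRNA 1-Mb density profiles co-vary genome-wide
(Spearman ~0.92 at these problem sizes) the way two speckle-associated
signals co-vary over chromatin state in real nuclei; with a flat background
the two profiles would only agree inside domains and the genome-wide rank
correlation would collapse to ~0.3. Heavier-tailed fields (sdlog 1.0–1.2)
were examined and buy no additional correlation — Poisson noise in ~16-count
background bins caps the achievable rank agreement below the 0.957 reported
at full scale (188k pairs, 3.1-Gb genome) — while degrading broad-peak
precision, so 0.8 stands. The **diffuse** scenario plants no domains and
uses a strictly uniform background; per-chromosome uniformity of its DNA
ends is itself a tested property.

**Images.** Per nucleus: an 80x80x16 voxel grid, an ellipsoidal nucleus
(semi-axes 34/34/6.5 voxels), 20–35 Gaussian SC35 blobs (sigma 1.2, centre
separation >= 6 voxels so distinct speckles stay resolvable after
thresholding) and 1–3 FISH spots (sigma 1.0). A spot is planted colocalized
(centre within 1 voxel of a cluster centre) with the group's probability,
else kept at least 8 voxels centre-to-centre from every cluster — beyond
the ~2-voxel thresholded radii of both objects plus a 3-voxel guard — so
recovered calls reproduce planted truth. Flat background (10) plus Gaussian
noise (SD 2) completes the stack; no point-spread, chromatic shift or
z-anisotropy realism is attempted, so passing tests say nothing about
deconvolution-grade data.

**What the generator does not emulate.** Mappability and GC structure,
read-level sequence, replicate variability, assembly gaps, true Hi-C
matrices (TADs and compartments are synthetic partitions with planted
alignment/bias), and the full genome scale. Quantities that depend on scale
— 295 domains, 3.08 million windows, Spearman 0.957 — are emulated
qualitatively at desk scale, not asserted numerically.

## Problem sizes and determinism

Module tests run on reduced configurations (hundreds of pairs, three
chromosomes); the acceptance suite runs the full synthetic conditions:
15,000-pair scenario contrasts over 20 seeds with 1,000-permutation tests,
a 10,000-pair filter-exactness check, 100 randomized instances per
brute-force oracle, 200 null datasets at 200 permutations for p-value
calibration, and the 82 + 100-nucleus imaging design over 20 seeds. Every
stochastic step consumes an explicit seed; `run_pipeline()` writes a
manifest (resolved configuration, seeds, package version) and two runs from
one manifest are byte-identical, which the suite asserts by checksum.

## Known limitations

* The broad-peak caller is a faithful *replacement* for the published
  tool's broad option, not a reproduction; on real data peak boundaries
  will differ.
* The permutation null does not model mappability or gap structure; on a
  real genome an excluded-region mask would be required.
* The junction rule requires annotated junctions; unannotated splicing is
  invisible to the pre-mRNA class.
* Voxel distances assume isotropy; with a real confocal z-step the distance
  histograms would need per-axis scaling.
* The cross-product odds ratio intentionally differs from the unstated
  estimator behind one published value (3.21 vs 3.1 on the same table).
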