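# specklemap

Nuclear speckles sit apart from chromatin, so ChIP of their core proteins
(SC35, SON) cannot reveal which genomic regions lie near them. specklemap
implements the alternative: use the noncoding RNAs that accumulate at the
speckle periphery — snRNAs (U1–U12 variants), 7SK, Malat1, collectively
*nsaRNAs* — as proximity-labeling media. RNA–DNA proximity-ligation read
pairs (MARGI-style chimeras) whose RNA end maps to an nsaRNA mark the DNA
their RNA was near; clustering those DNA ends yields broad domains
(*nsaPeaks*, 100 kb–13 Mb) that footprint the speckle-proximal genome.

The package is aimed at computational genomicists working with RNA–chromatin
ligation data. It provides:

* strict readers/writers for the pair dialect (11-column, BEDPE-like),
  BED3+, GTF subset and chrom.sizes files;
* pair classification (nsaRNA / rRNA / posttranscriptional pre-mRNA via an
  exon–intron junction rule / other) and a nascent-transcript distance
  filter (same-chromosome gap <= 2,000 nt);
* a deterministic broad-peak caller (25-kb windows, 4x genome-mean
  enrichment, 100-kb merge) plus the candidate-peak path (>= 9 reads and
  >= 500 kb single-linkage cluster span);
* association statistics: cross-product odds ratios, chi-square / Fisher
  tests, genome-binned density profiles with Spearman correlation,
  chromosome-preserving interval-shuffling permutation tests (add-one
  p-values), TAD boundary alignment, window-level compartment association;
* single-cell 3D imaging analysis: Otsu-thresholded spot/cluster detection,
  the conservative pixel-overlap colocalization rule, nearest-cluster
  distance distributions, Welch-t and Kolmogorov–Smirnov group comparisons;
* a synthetic-data generator ("speckled" vs "diffuse" scenarios with planted
  truth, plus 3D image stacks) so the whole pipeline runs offline.

## The statistics at the core

A pair is **nascent** when its ends share a chromosome with gap
$g \le 2{,}000$ nt. A read is **p-pre-mRNA** when it covers $\ge 1$ exonic
nt and $\ge 10$ intronic nt across one junction of a same-strand transcript.
Broad peaks are merged runs of 25-kb bins with midpoint count
$> \max(1, 4\,\bar n)$, where $\bar n$ is the genome-mean count per bin,
filtered at $\ge 9$ reads, $\ge 100$ kb span, and a region-level density
still exceeding the same $4\,\bar n$ rule (so bridged noise bins never
survive). Association uses the
cross-product odds ratio $\mathrm{OR} = ad/bc$ and permutation p-values
$p = (1 + \#\{T_{\text{null}} \ge T_{\text{obs}}\})/(1 + n_{\text{perm}})$
under uniform, length- and chromosome-preserving interval re-placement.

## Worked example

```r
library(specklemap)

cfg <- sim_config()                          # the synthetic study conditions
ann <- simulate_annotation(cfg, seed = 1)
sim <- simulate_pairs(cfg, ann$annotation, ann$sizes, seed = 2)
cls <- classify_pairs(sim$pairs, ann$annotation, filter_params_from(cfg))
table(cls$rna_class)
#>     nsaRNA      other p_pre_mRNA       rRNA
#>      15003       5001      15001       2000

nsap <- cls[cls$rna_class == "nsaRNA" & !cls$nascent]
peaks <- call_broad_peaks(nsap, ann$sizes)
#> call_broad_peaks: 13533 reads -> 10 broad peak(s)
reads_in_peaks(nsap, peaks, ann$sizes)$fraction
#> [1] 0.7192788
evaluate_peaks(peaks, sim$peaks)
#> $recall
#> [1] 1
#> $precision
#> [1] 1
```

Ten broad domains are called, recovering all ten planted domains exactly
(recall and precision 1), and 72% of the non-nascent nsaRNA DNA ends fall
inside them — the planted in-domain probability. The `analysis/` directory holds the numbered drivers that
replay the full study on synthetic data (simulation, classification and the
rRNA→rDNA control, peak calling and the speckled/diffuse contrast, pre-mRNA
concordance, TAD/compartment context, single-cell imaging), writing their
tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

## Package layout

```
R/                  io, classify, peaks, stats, imaging, simulate, pipeline
analysis/           numbered narrative drivers over the package functions
scripts/acceptance.R
tests/testthat/     module tests, property tests, brute-force oracles,
                    end-to-end acceptance checks
vignettes/          methods vignette: models, parameters, design decisions
```
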