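#!/usr/bin/env Rscript
# Structural-genomics context of the nsaPeaks, on synthetic comparators
# (real analyses would consume TAD and A/B compartment BEDs from a Hi-C
# caller): boundary alignment of nsaPeaks and union-peaks with TADs plus
# permutation nulls, and the window-level association with the A compartment
# via Fisher's exact test on 1,000-bp genome windows.

suppressPackageStartupMessages({library(specklemap); library(GenomicRanges)})

dat <- "results/data"
sizes <- read_chrom_sizes(file.path(dat, "chrom.sizes"))
pk <- read_bed("results/nsapeaks_speckled.bed", sizes)
un <- read_bed("results/union_peaks.bed", sizes)
tads <- read_bed(file.path(dat, "tads.synthetic.bed"), sizes)
A <- read_bed(file.path(dat, "compartment_A.synthetic.bed"), sizes)
B <- read_bed(file.path(dat, "compartment_B.synthetic.bed"), sizes)

stat_bnd <- function(p, td) boundary_alignment(p, td, tolerance = 40000)$n_aligned
for (nm in c("nsaPeaks", "union-peaks")) {
  set <- if (nm == "nsaPeaks") pk else un
  ba <- boundary_alignment(set, tads, tolerance = 40000)
  perm <- permutation_test(stat_bnd, set, tads, sizes, n_perm = 500, seed = 7)
  message(sprintf(
    "%s: %d of %d boundaries aligned with TAD boundaries (%.1f%%), %d peaks tiled by consecutive TADs, permutation p = %.3g",
    nm, ba$n_aligned, ba$n_boundaries, 100 * ba$n_aligned / ba$n_boundaries,
    ba$n_tiled, perm$p.value))
}

# fraction of each compartment covered by nsaPeaks
cov_frac <- function(comp) {
  sum(width(GenomicRanges::intersect(comp, pk, ignore.strand = TRUE))) /
    sum(width(comp))
}
message(sprintf("nsaPeaks cover %.1f%% of the A compartment and %.1f%% of B",
                100 * cov_frac(A), 100 * cov_frac(B)))
wa <- window_association(A, pk, sizes, window = 1000)
message(sprintf("1,000-bp window association with A: odds ratio = %.2f, Fisher p = %.2g",
                odds_ratio(wa), fisher_exact(wa)))
# narrow ChIP-style comparator (synthetic): point-source peaks, a third of
# them planted within 150 bp of an nsaRNA DNA end, the rest uniform - how
# many lie within 200 bp of an nsaRNA-interacting DNA sequence?
set.seed(99)
cls <- read_pairs(file.path(dat, "classified_speckled.tsv"), sizes)
nsap <- cls[cls$rna_class == "nsaRNA" & !cls$nascent]
mids <- dna_midpoints(nsap, sizes)
n_np <- 2000L
near <- sample(length(mids), round(n_np / 3))
near_chr <- as.character(seqnames(mids))[near]
near_pos <- start(mids)[near] + sample(-150:150, length(near), replace = TRUE)
autos <- names(sizes)[1:4]
bg_chr <- sample(autos, n_np - length(near), replace = TRUE, prob = sizes[autos])
bg_pos <- vapply(bg_chr, function(ch) sample.int(sizes[[ch]] - 200, 1L), 1L)
np_chr <- c(near_chr, bg_chr)
np_pos <- pmax(1, c(near_pos, bg_pos))
narrow <- GRanges(np_chr, IRanges(np_pos, np_pos + 199))
n200 <- proximity_count(narrow, mids, max_dist = 200)
message(sprintf(
  "synthetic narrow comparator: %d of %d peaks (%.1f%%) within 200 bp of an nsaRNA-interacting DNA end",
  n200, length(narrow), 100 * n200 / length(narrow)))

data.table::fwrite(data.table::data.table(
  metric = c("A_covered_pct", "B_covered_pct", "window_or", "window_fisher_p",
             "narrow_within_200bp_pct"),
  value = c(100 * cov_frac(A), 100 * cov_frac(B), odds_ratio(wa),
            fisher_exact(wa), 100 * n200 / length(narrow))),
  "results/05_compartments.tsv", sep = "\t")
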