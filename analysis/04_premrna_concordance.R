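#!/usr/bin/env Rscript
# Tests whether posttranscriptional pre-mRNA-proximal DNA corroborates the
# nsaPeaks: overlap of the two broad-peak sets, their union, the genome-wide
# density-profile correlation at 1-Mb bins, and permutation significance of
# the reads-in-peaks enrichment.

suppressPackageStartupMessages({library(specklemap); library(GenomicRanges)})

dat <- "results/data"
sizes <- read_chrom_sizes(file.path(dat, "chrom.sizes"))
cls <- read_pairs(file.path(dat, "classified_speckled.tsv"), sizes)
nsap <- cls[cls$rna_class == "nsaRNA" & !cls$nascent]
prem <- cls[cls$rna_class == "p_pre_mRNA" & !cls$nascent]
pk_nsa <- read_bed("results/nsapeaks_speckled.bed", sizes)
pk_pre <- read_bed("results/premrna_peaks_speckled.bed", sizes)

ov <- overlap_peaksets(pk_nsa, pk_pre)
un <- union_peaks(pk_nsa, pk_pre)
message(sprintf("%d of %d nsaPeaks (%.1f%%) overlap a p-pre-mRNA broad peak; %d union-peaks",
                ov$n, length(pk_nsa), 100 * ov$fraction, length(un)))
write_bed(un, "results/union_peaks.bed")

d_nsa <- density_profile(nsap, sizes, 1e6)
d_pre <- density_profile(prem, sizes, 1e6)
pc <- profile_correlation(d_nsa, d_pre, "spearman")
message(sprintf("1-Mb density profiles: Spearman rho = %.3f (p = %.2g)",
                pc$rho, pc$p.value))
prof <- data.table::data.table(
  chrom = as.character(seqnames(d_nsa$bins)), start = start(d_nsa$bins) - 1,
  end = end(d_nsa$bins), nsarna = d_nsa$counts, premrna = d_pre$counts)
data.table::fwrite(prof, "results/04_density_profiles_1mb.tsv", sep = "\t")

perm <- permutation_test_points(pk_nsa, dna_midpoints(nsap, sizes), sizes,
                                n_perm = 1000, seed = 42)
message(sprintf("reads-in-peaks permutation: observed %.3f vs null %.3f +/- %.3f, p = %.2g",
                perm$observed, mean(perm$null), sd(perm$null), perm$p.value))
stat_ov <- function(p, q) overlap_peaksets(p, q)$n
perm2 <- permutation_test(stat_ov, pk_nsa, pk_pre, sizes, n_perm = 1000,
                          seed = 43)
message(sprintf("peak-overlap permutation: observed %d, p = %.2g",
                perm2$observed, perm2$p.value))
data.table::fwrite(data.table::data.table(
  metric = c("overlap_n", "overlap_pct", "n_union", "spearman_rho",
             "reads_in_peaks_perm_p", "overlap_perm_p"),
  value = c(ov$n, 100 * ov$fraction, length(un), pc$rho, perm$p.value,
            perm2$p.value)),
  "results/04_premrna_concordance.tsv", sep = "\t")
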