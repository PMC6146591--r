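#!/usr/bin/env Rscript
# Generates the two synthetic studies every later step consumes: a "speckled"
# dataset (stable nsaRNA-DNA interactions concentrated in planted domains,
# emulating HEK293T) and a "diffuse" one (sporadic interactions, emulating
# hES), plus the toy annotated genome and the synthetic TAD / compartment
# comparators. All outputs land under results/data/.

suppressPackageStartupMessages(library(specklemap))

seed <- 20260930L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg_speckled <- sim_config("speckled")
cfg_diffuse <- sim_config("diffuse")

ann <- simulate_annotation(cfg_speckled, seed = seed)
write_chrom_sizes(ann$sizes, file.path(out, "chrom.sizes"))
write_annotation(ann$annotation, file.path(out, "annotation.gtf"))
message("annotated toy genome: ", length(ann$sizes), " sequences, ",
        nrow(ann$annotation$genes), " genes (",
        sum(ann$annotation$genes$rna_class == "nsaRNA"), " nsaRNA species loci)")

for (scen in c("speckled", "diffuse")) {
  cfg <- if (scen == "speckled") cfg_speckled else cfg_diffuse
  sim <- simulate_pairs(cfg, ann$annotation, ann$sizes, seed = seed + 1L)
  write_pairs(sim$pairs, file.path(out, paste0("pairs_", scen, ".tsv")))
  write_bed(sim$peaks, file.path(out, paste0("truth_peaks_", scen, ".synthetic.bed")))
  data.table::fwrite(sim$truth, file.path(out, paste0("truth_", scen, ".tsv")),
                     sep = "\t")
  message(scen, ": ", nrow(sim$pairs), " pairs, ", length(sim$peaks),
          " planted domain(s) covering ",
          round(sum(GenomicRanges::width(sim$peaks)) / 1e6, 1), " Mb")
  if (scen == "speckled") speckled_peaks <- sim$peaks
}

tads <- simulate_tads(ann$sizes, speckled_peaks, aligned_frac = 0.5,
                      seed = seed + 2L)
write_bed(tads, file.path(out, "tads.synthetic.bed"))
cmp <- simulate_compartments(ann$sizes, speckled_peaks, seed = seed + 3L)
write_bed(cmp$A, file.path(out, "compartment_A.synthetic.bed"))
write_bed(cmp$B, file.path(out, "compartment_B.synthetic.bed"))
message("comparators: ", length(tads), " synthetic TADs; A compartment ",
        round(sum(GenomicRanges::width(cmp$A)) / 1e6), " Mb / B ",
        round(sum(GenomicRanges::width(cmp$B)) / 1e6), " Mb")
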