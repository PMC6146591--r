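utils::globalVariables(c(
  ".", ".N", ".I", "chrom", "start", "end", "gene_id", "transcript_id",
  "rna_class", "species", "sp_rank", "exon_end", "intron_end", "weight",
  "mass", "new_cluster", "cid", "pos", "read_id", "in_peak", "image",
  "coloc", "nascent", "probe", "V1"
))
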