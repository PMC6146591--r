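# small in-code fixtures shared across test files

tiny_sizes <- function() chrom_sizes(c(chrA = 1e6, chrB = 5e5, rDNA = 43000))

# two-chromosome toy for randomized oracle instances
oracle_sizes <- function() chrom_sizes(c(c1 = 2e6, c2 = 1e6))

# hand-built annotation: one coding gene (2 exons), one U1 gene, one rRNA gene
tiny_annotation <- function() {
  genes <- data.table::data.table(
    gene_id = c("g1", "nsa_U1", "rRNA_45S"),
    rna_class = c("coding", "nsaRNA", "rRNA"),
    species = c(NA, "U1", NA),
    chrom = c("chrA", "chrA", "rDNA"),
    start = c(10001, 50001, 2001),
    end = c(12000, 50164, 15000),
    strand = c("+", "+", "+"))
  exons <- data.table::data.table(
    gene_id = c("g1", "g1", "nsa_U1", "rRNA_45S"),
    transcript_id = c("g1.t1", "g1.t1", "nsa_U1.t1", "rRNA_45S.t1"),
    chrom = c("chrA", "chrA", "chrA", "rDNA"),
    start = c(10001, 11001, 50001, 2001),
    end = c(10500, 11500, 50164, 15000),
    strand = c("+", "+", "+", "+"))
  gene_annotation(genes, exons)
}

# build a pair table row-by-row from end coordinates (1-based inclusive)
make_pairs <- function(rna_chrom, rna_start, rna_end,
                       dna_chrom, dna_start, dna_end,
                       rna_strand = "+", dna_strand = "+") {
  n <- length(rna_chrom)
  data.table::data.table(
    read_id = sprintf("t%03d", seq_len(n)),
    rna_chrom = rna_chrom, rna_start = rna_start, rna_end = rna_end,
    rna_strand = rep_len(rna_strand, n),
    dna_chrom = dna_chrom, dna_start = dna_start, dna_end = dna_end,
    dna_strand = rep_len(dna_strand, n))
}

# reduced-size configuration for fast module tests (overridable defaults)
small_config <- function(...) {
  args <- utils::modifyList(
    list(chroms = c(chrA = 20e6, chrB = 20e6, chrC = 15e6),
         n_planted_peaks = 4L, peak_length_range = c(1e5, 3e6),
         peak_genome_fraction = 0.08,
         n_nsarna = 800L, n_premrna = 800L, n_rrna = 300L, n_other = 300L,
         n_coding = 12L),
    list(...))
  do.call(sim_config, args)
}

# minimal synthetic stack with hand-placed Gaussian blobs
blob_stack <- function(dim = c(32L, 32L, 8L),
                       fish_centers = NULL, sc35_centers = NULL,
                       fish_amp = 150, sc35_amp = 120, sigma = 1.1,
                       background = 10, noise_sd = 2, seed = 1) {
  set.seed(seed)
  fish <- array(pmax(rnorm(prod(dim), background, noise_sd), 0), dim = dim)
  sc35 <- array(pmax(rnorm(prod(dim), background, noise_sd), 0), dim = dim)
  mask <- array(TRUE, dim = dim)
  add <- function(arr, c0, amp) {
    for (y in seq_len(dim[1])) for (x in seq_len(dim[2])) for (z in seq_len(dim[3]))
      arr[y, x, z] <- arr[y, x, z] +
        amp * exp(-((y - c0[1])^2 + (x - c0[2])^2 + (z - c0[3])^2) / (2 * sigma^2))
    arr
  }
  if (!is.null(fish_centers))
    for (i in seq_len(nrow(fish_centers))) fish <- add(fish, fish_centers[i, ], fish_amp)
  if (!is.null(sc35_centers))
    for (i in seq_len(nrow(sc35_centers))) sc35 <- add(sc35, sc35_centers[i, ], sc35_amp)
  image_stack(fish, sc35, mask)
}
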