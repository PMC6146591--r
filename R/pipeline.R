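#' Filter parameters matching a simulation configuration
#' @param config a [sim_config()].
#' @return [filter_params()] with the config's thresholds and species list.
#' @export
filter_params_from <- function(config) {
  filter_params(nascent_distance = config$nascent_distance,
                min_intron_overlap = config$min_intron_overlap,
                species = config$species, rdna_chrom = config$rdna_chrom)
}

#' Run the full synthetic pipeline end to end
#'
#' Orchestrates simulate -> classify -> nascent filter -> broad-peak calling
#' -> association statistics -> single-cell imaging, writing every
#' intermediate file, a summary table and a manifest (resolved configuration,
#' seeds, package version) into `out_dir`. All randomness derives from
#' `seed`; two runs with one manifest produce byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param seed master integer seed.
#' @param n_perm permutations for the reads-in-peaks test.
#' @param bin density-profile bin width (bp).
#' @param run_imaging run the single-cell imaging stage.
#' @param imaging_cells cells per probe group in the imaging stage.
#' @param coloc_probs planted colocalization probabilities, named
#'   `nsapeak` / `non_nsapeak`.
#' @return invisibly, a named list of summary statistics.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), seed = 1L,
                         n_perm = 200L, bin = 1e6, run_imaging = TRUE,
                         imaging_cells = 8L,
                         coloc_probs = c(nsapeak = 0.84, non_nsapeak = 0.57)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- filter_params_from(config)
  summary <- list(scenario = config$scenario, seed = seed)

  ann <- simulate_annotation(config, seed = seed)
  write_chrom_sizes(ann$sizes, file.path(out_dir, "chrom.sizes"))
  write_annotation(ann$annotation, file.path(out_dir, "annotation.gtf"))

  sim <- simulate_pairs(config, ann$annotation, ann$sizes, seed = seed + 1L)
  write_pairs(sim$pairs, file.path(out_dir, "pairs.tsv"))
  write_bed(sim$peaks, file.path(out_dir, "truth_peaks.synthetic.bed"))
  message("pipeline: simulated ", nrow(sim$pairs), " pairs, ",
          length(sim$peaks), " planted domain(s)")

  cls <- classify_pairs(sim$pairs, ann$annotation, fp)
  write_pairs(cls, file.path(out_dir, "classified.tsv"))
  tab <- table(cls$rna_class)
  summary$n_pairs <- nrow(cls)
  summary$n_nascent <- sum(cls$nascent)
  for (k in names(tab)) summary[[paste0("n_", k)]] <- unname(tab[k])
  message("pipeline: classes ", paste(names(tab), tab, sep = "=", collapse = " "),
          "; nascent flagged ", sum(cls$nascent))

  nsap <- cls[cls$rna_class == "nsaRNA" & !cls$nascent, ]
  prep <- cls[cls$rna_class == "p_pre_mRNA" & !cls$nascent, ]
  peaks_nsa <- call_broad_peaks(nsap, ann$sizes)
  peaks_pre <- call_broad_peaks(prep, ann$sizes)
  write_bed(peaks_nsa, file.path(out_dir, "nsapeaks.bed"))
  write_bed(peaks_pre, file.path(out_dir, "premrna_peaks.bed"))
  summary$n_nsapeaks <- length(peaks_nsa)
  summary$n_premrna_peaks <- length(peaks_pre)

  rip <- reads_in_peaks(nsap, peaks_nsa, ann$sizes)
  summary$in_peak_fraction <- rip$fraction
  ev <- evaluate_peaks(peaks_nsa, sim$peaks)
  summary$peak_recall <- ev$recall
  summary$peak_precision <- ev$precision

  ct <- contingency_by_class(cls,
    function(p) p$rna_class == "rRNA",
    function(p) p$dna_chrom == config$rdna_chrom)
  summary$rdna_odds_ratio <- odds_ratio(ct)
  summary$rdna_chisq_p <- chi_square_test(ct)$p.value

  if (nrow(prep)) {
    summary$premrna_interchromosomal <- interchromosomal_fraction(prep)
    d1 <- density_profile(nsap, ann$sizes, bin)
    d2 <- density_profile(prep, ann$sizes, bin)
    pc <- profile_correlation(d1, d2, "spearman")
    summary$density_spearman <- pc$rho
    ov <- overlap_peaksets(peaks_nsa, peaks_pre)
    summary$nsapeak_overlap_fraction <- ov$fraction
    summary$n_union_peaks <- length(union_peaks(peaks_nsa, peaks_pre))
  }

  if (length(peaks_nsa)) {
    pr <- permutation_test_points(peaks_nsa, nsap, ann$sizes,
                                  n_perm = n_perm, seed = seed + 2L)
    summary$reads_in_peaks_perm_p <- pr$p.value
  }

  if (run_imaging) {
    simA <- simulate_images(imaging_cells, coloc_probs[["nsapeak"]],
                            config, seed = seed + 3L)
    simB <- simulate_images(imaging_cells, coloc_probs[["non_nsapeak"]],
                            config, seed = seed + 4L)
    resA <- analyze_cells(simA$cells)
    resB <- analyze_cells(simB$cells)
    coloc <- rbind(cbind(probe = "nsaPeak", resA$spots),
                   cbind(probe = "non_nsaPeak", resB$spots))
    fwrite(coloc, file.path(out_dir, "coloc.tsv"), sep = "\t")
    summary$coloc_fraction_nsapeak <- mean(resA$spots$coloc)
    summary$coloc_fraction_non_nsapeak <- mean(resB$spots$coloc)
  }

  num <- vapply(summary, function(x) paste(format(x, scientific = FALSE,
                                                  digits = 10), collapse = ","),
                character(1))
  fwrite(data.table(metric = names(summary), value = num),
         file.path(out_dir, "summary.tsv"), sep = "\t")

  manifest <- list(
    package = "specklemap",
    version = as.character(utils::packageVersion("specklemap")),
    seed = seed, n_perm = n_perm, bin = bin,
    run_imaging = run_imaging, imaging_cells = imaging_cells,
    coloc_probs = as.list(coloc_probs),
    config = lapply(unclass(config), function(x)
      if (is.list(x)) lapply(x, unname) else unname(x)),
    outputs = c("chrom.sizes", "annotation.gtf", "pairs.tsv",
                "truth_peaks.synthetic.bed", "classified.tsv", "nsapeaks.bed",
                "premrna_peaks.bed", if (run_imaging) "coloc.tsv",
                "summary.tsv"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(summary)
}
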