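test_that("annotation simulation plants the full species set deterministically", {
  cfg <- small_config()
  a1 <- simulate_annotation(cfg, seed = 3)
  expect_equal(sum(a1$annotation$genes$rna_class == "nsaRNA"), 11L)
  expect_setequal(a1$annotation$genes$species[a1$annotation$genes$rna_class == "nsaRNA"],
                  nsa_species())
  expect_true("rDNA" %in% names(a1$sizes))
  # byte-identical GTF under one seed
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_annotation(a1$annotation, p1)
  write_annotation(simulate_annotation(cfg, seed = 3)$annotation, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(a1$annotation$genes$start,
                         simulate_annotation(cfg, seed = 4)$annotation$genes$start))
  # a chromosome too short for the largest gene errors
  tiny <- small_config()
  tiny$chroms <- c(chrA = 30000, chrB = 30000, chrC = 30000)
  expect_error(simulate_annotation(tiny, seed = 1), "too short|could not place")
})

test_that("simulated pair files are deterministic and re-parse with zero drops", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg, seed = 1)
  s1 <- simulate_pairs(cfg, ann$annotation, ann$sizes, seed = 2)
  s2 <- simulate_pairs(cfg, ann$annotation, ann$sizes, seed = 2)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(as.data.frame(s1$peaks), as.data.frame(s2$peaks))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(s1$pairs, p)
  expect_no_message(back <- read_pairs(p, ann$sizes))   # zero dropped records
  expect_equal(nrow(back), nrow(s1$pairs))
  b <- withr::local_tempfile(fileext = ".bed")
  write_bed(s1$peaks, b)
  expect_equal(length(read_bed(b, ann$sizes)), length(s1$peaks))
})

test_that("classification reproduces planted truth exactly at matched thresholds", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg, seed = 5)
  sim <- simulate_pairs(cfg, ann$annotation, ann$sizes, seed = 6)
  cls <- suppressMessages(classify_pairs(sim$pairs, ann$annotation,
                                         filter_params_from(cfg)))
  expect_identical(cls$rna_class, sim$truth$rna_class)
  expect_identical(cls$nascent, sim$truth$nascent)
  expect_identical(cls$species, sim$truth$species)
})

test_that("diffuse DNA ends are uniform per chromosome; speckled hit their target", {
  cfg <- small_config(scenario = "diffuse")
  ann <- simulate_annotation(cfg, seed = 1)
  sim <- simulate_pairs(cfg, ann$annotation, ann$sizes, seed = 7)
  expect_length(sim$peaks, 0L)
  keep <- !sim$truth$nascent & sim$pairs$dna_chrom != "rDNA"
  for (ch in c("chrA", "chrB")) {
    pos <- sim$pairs$dna_start[keep & sim$pairs$dna_chrom == ch]
    ks <- suppressWarnings(ks.test(pos, "punif", 1, cfg$chroms[[ch]]))
    expect_gt(ks$p.value, 0.01)
  }

  spk <- sim_config(n_premrna = 0L, n_rrna = 0L, n_other = 0L)
  ann2 <- simulate_annotation(spk, seed = 1)
  sim2 <- simulate_pairs(spk, ann2$annotation, ann2$sizes, seed = 8)
  nn <- !sim2$truth$nascent
  frac <- mean(sim2$truth$in_peak[nn])
  expect_lt(abs(frac - 0.72), 0.01)   # 15,000 pairs, binomial error bound
})

test_that("planted rDNA odds and interchromosomal rates are recovered", {
  cfg <- sim_config(n_nsarna = 8000L, n_premrna = 8000L, n_rrna = 2000L,
                    n_other = 4000L)
  ann <- simulate_annotation(cfg, seed = 1)
  sim <- simulate_pairs(cfg, ann$annotation, ann$sizes, seed = 9)
  t <- contingency_by_class(sim$pairs,
    function(p) sim$truth$rna_class == "rRNA",
    function(p) p$dna_chrom == "rDNA")
  or <- odds_ratio(t)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  expect_true(abs(log(or) - log(404)) < 2.6 * se)

  prem <- sim$pairs[sim$truth$rna_class == "p_pre_mRNA" & !sim$truth$nascent, ]
  expect_lt(abs(interchromosomal_fraction(prem) - 0.93), 0.015)
})

test_that("nascent fraction propagates end to end through the flag", {
  cfg <- small_config(nascent_fraction = 0.3)
  ann <- simulate_annotation(cfg, seed = 1)
  sim <- simulate_pairs(cfg, ann$annotation, ann$sizes, seed = 10)
  fl <- flag_nascent(sim$pairs, filter_params_from(cfg))
  expect_identical(fl$nascent, sim$truth$nascent)
  auto <- sim$truth$rna_class != "rRNA" & !sim$truth$probe
  expect_lt(abs(mean(sim$truth$nascent[auto]) - 0.3), 0.04)
})

test_that("planted colocalization probabilities bound the image construction", {
  cfg <- small_config()
  all_in <- simulate_images(4, 1.0, cfg, seed = 1)
  res <- analyze_cells(all_in$cells)
  expect_true(all(res$spots$coloc))
  none <- simulate_images(4, 0.0, cfg, seed = 2)
  res0 <- analyze_cells(none$cells)
  expect_true(!any(res0$spots$coloc))
  expect_true(all(res0$spots$distance > 3))
})

test_that("peak evaluation matches a brute-force Jaccard scan", {
  sizes <- oracle_sizes()
  a <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 1000), c(500, 1400)))
  expect_equal(evaluate_peaks(a, a), list(recall = 1, precision = 1))
  expect_equal(evaluate_peaks(a[0], a)$recall, 0)
  set.seed(20)
  for (rep in 1:10) {
    x <- random_intervals(6, sizes, max_len = 3e5)
    y <- random_intervals(5, sizes, max_len = 3e5)
    expect_equal(evaluate_peaks(x, y)$recall, oracle_jaccard_recall(x, y, 0.5))
  }
})

test_that("synthetic TADs plant alignable boundaries; compartments favour peaks", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg, seed = 1)
  sim <- simulate_pairs(cfg, ann$annotation, ann$sizes, seed = 2)
  tads <- simulate_tads(ann$sizes, sim$peaks, aligned_frac = 1, seed = 3)
  ba <- boundary_alignment(sim$peaks, tads, tolerance = 0)
  expect_equal(ba$n_aligned, ba$n_boundaries)  # every boundary planted
  tads0 <- simulate_tads(ann$sizes, sim$peaks, aligned_frac = 0, seed = 3)
  ba0 <- boundary_alignment(sim$peaks, tads0, tolerance = 0)
  expect_lt(ba0$n_aligned, ba$n_aligned)

  cmp <- simulate_compartments(ann$sizes, sim$peaks, seed = 4)
  wa <- window_association(cmp$A, sim$peaks, ann$sizes, window = 10000)
  expect_gt(odds_ratio(wa, correction = TRUE), 1)
})
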