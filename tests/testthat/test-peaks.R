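mk_mid_pairs <- function(chrom, mids, sizes) {
  # width-1 DNA ends so the midpoint equals the given position
  make_pairs(rep("chrB", length(mids)), 1, 30, chrom, mids, mids)
}

test_that("single-linkage clustering joins runs of nearby midpoints", {
  sizes <- tiny_sizes()
  pr <- mk_mid_pairs("chrA", c(100, 150, 500000), sizes)
  cl <- cluster_dna_ends(pr, sizes, peak_params(cluster_max_gap = 1000))
  expect_length(cl, 2L)
  expect_equal(S4Vectors::mcols(cl)$read_count, c(2L, 1L))
  expect_equal(start(cl), c(100, 500000))
  expect_equal(S4Vectors::mcols(cl)$span, c(50, 0))

  all_in <- cluster_dna_ends(mk_mid_pairs("chrA", c(10, 400, 900), sizes),
                             sizes, peak_params(cluster_max_gap = 1000))
  expect_length(all_in, 1L)
  expect_equal(S4Vectors::mcols(all_in)$read_count, 3L)
})

test_that("clustering equals the O(n^2) single-linkage oracle on random inputs", {
  set.seed(7)
  sizes <- chrom_sizes(c(c1 = 1e6))
  for (rep in 1:10) {
    pos <- sort(sample.int(1e6, 40))
    gap <- sample(c(100, 5000, 50000), 1)
    cl <- cluster_dna_ends(mk_mid_pairs("c1", pos, sizes), sizes,
                           peak_params(cluster_max_gap = gap))
    lab <- oracle_single_linkage(pos, gap)
    expect_equal(length(cl), length(unique(lab)))
    expect_equal(sum(S4Vectors::mcols(cl)$read_count), 40L)
    # spans match per oracle cluster
    osp <- sort(vapply(split(pos, lab), function(p) max(p) - min(p), numeric(1)))
    expect_equal(sort(S4Vectors::mcols(cl)$span), unname(osp))
  }
})

test_that("candidate peaks enforce both Fig-style thresholds, monotonically", {
  sizes <- chrom_sizes(c(c1 = 1e8))
  mk_cluster <- function(n, span, offset) {
    mk_mid_pairs("c1", offset + round(seq(0, span, length.out = n)), sizes)
  }
  pr <- rbind(mk_cluster(9, 6e5, 1),        # keep: 9 reads, 600 kb
              mk_cluster(8, 6e5, 2e6),      # drop: 8 reads
              mk_cluster(20, 4e5, 8e6))     # drop: 400 kb span
  pr$read_id <- sprintf("r%03d", seq_len(nrow(pr)))
  cl <- cluster_dna_ends(pr, sizes, peak_params(cluster_max_gap = 1e5))
  kept <- candidate_peaks(cl)
  expect_length(kept, 1L)
  expect_equal(S4Vectors::mcols(kept)$read_count, 9L)
  # monotone in both thresholds
  for (mr in c(1, 5, 9, 15)) {
    k1 <- length(candidate_peaks(cl, peak_params(min_reads = mr)))
    k2 <- length(candidate_peaks(cl, peak_params(min_reads = mr + 1)))
    expect_gte(k1, k2)
  }
  k3 <- length(candidate_peaks(cl, peak_params(min_cluster_span = 3e5)))
  k4 <- length(candidate_peaks(cl, peak_params(min_cluster_span = 5e5)))
  expect_gte(k3, k4)
})

test_that("broad-peak calling recovers a planted domain and ignores uniform noise", {
  set.seed(11)
  sizes <- chrom_sizes(c(c1 = 5e7, c2 = 5e7))
  # uniform background only: 10k reads over 100 Mb
  bg_pos <- sample.int(5e7, 10000, replace = TRUE)
  bg <- mk_mid_pairs(sample(c("c1", "c2"), 10000, replace = TRUE), bg_pos, sizes)
  bg$read_id <- sprintf("b%05d", 1:10000)
  expect_message(p0 <- call_broad_peaks(bg, sizes), "broad peak")
  expect_length(p0, 0L)

  # one planted 1-Mb region holding 30% of all reads
  planted <- mk_mid_pairs("c1", sample(20000001:21000000, 4286, replace = TRUE), sizes)
  planted$read_id <- sprintf("p%04d", 1:4286)
  pr <- rbind(bg, planted)
  pk <- suppressMessages(call_broad_peaks(pr, sizes))
  expect_length(pk, 1L)
  ov <- IRanges::intersect(ranges(pk), IRanges::IRanges(20000001, 21000000))
  expect_gte(sum(IRanges::width(ov)) / 1e6, 0.8)

  # duplicating every read leaves the peak intervals unchanged
  dup <- data.table::copy(pr)
  dup$read_id <- paste0(dup$read_id, "_d")
  pk2 <- suppressMessages(call_broad_peaks(rbind(pr, dup), sizes))
  expect_equal(as.data.frame(pk2)[, 1:3], as.data.frame(pk)[, 1:3])

  # invariant to record order
  pk3 <- suppressMessages(call_broad_peaks(pr[sample(nrow(pr))], sizes))
  expect_equal(as.data.frame(pk3)[, 1:3], as.data.frame(pk)[, 1:3])

  expect_warning(empty <- call_broad_peaks(pr[0], sizes), "no input")
  expect_length(empty, 0L)
})

test_that("reads-in-peaks counts match a brute-force membership scan", {
  set.seed(3)
  sizes <- oracle_sizes()
  full <- GenomicRanges::GRanges(c("c1", "c2"), IRanges::IRanges(1, c(2e6, 1e6)))
  pr <- mk_mid_pairs(sample(c("c1", "c2"), 50, replace = TRUE),
                     sample.int(1e6, 50), sizes)
  expect_equal(reads_in_peaks(pr, full, sizes)$fraction, 1)
  expect_equal(reads_in_peaks(pr, full[0], sizes)$fraction, 0)
  for (rep in 1:10) {
    pk <- random_intervals(8, sizes)
    got <- reads_in_peaks(pr, pk, sizes)
    expect_equal(got$count, oracle_points_in_intervals(dna_midpoints(pr, sizes), pk))
  }
})

test_that("peak-set overlap and union match brute force", {
  sizes <- oracle_sizes()
  a <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 5000), c(100, 5100)))
  expect_equal(overlap_peaksets(a, a)$fraction, 1)
  b <- GenomicRanges::GRanges("c2", IRanges::IRanges(1, 100))
  expect_equal(overlap_peaksets(a, b)$n, 0L)
  set.seed(5)
  for (rep in 1:10) {
    x <- random_intervals(12, sizes); y <- random_intervals(9, sizes)
    expect_equal(overlap_peaksets(x, y)$n, oracle_overlap_count(x, y))
  }
  u <- union_peaks(GenomicRanges::GRanges("c1", IRanges::IRanges(1, 100)),
                   GenomicRanges::GRanges("c1", IRanges::IRanges(51, 150)))
  expect_equal(as.data.frame(u)$start, 1)
  expect_equal(as.data.frame(u)$end, 150)
  dis <- union_peaks(GenomicRanges::GRanges("c1", IRanges::IRanges(1, 10)),
                     GenomicRanges::GRanges("c2", IRanges::IRanges(5, 15)))
  expect_length(dis, 2L)
  idn <- union_peaks(a, a[0])
  expect_equal(as.data.frame(idn)[, 1:3], as.data.frame(GenomicRanges::reduce(a))[, 1:3])
})

test_that("proximity counting uses nearest-edge offsets with an inclusive cap", {
  sizes <- oracle_sizes()
  iv <- GenomicRanges::GRanges("c1", IRanges::IRanges(1000, 2000))
  inside <- GenomicRanges::GRanges("c1", IRanges::IRanges(1500, 1500))
  expect_equal(proximity_count(iv, inside, 0), 1L)
  at201 <- GenomicRanges::GRanges("c1", IRanges::IRanges(2201, 2201))
  expect_equal(proximity_count(iv, at201, 200), 0L)
  at200 <- GenomicRanges::GRanges("c1", IRanges::IRanges(2200, 2200))
  expect_equal(proximity_count(iv, at200, 200), 1L)
  set.seed(9)
  for (rep in 1:10) {
    pts <- random_intervals(10, sizes, max_len = 2e4)
    tg <- random_points(25, sizes)
    md <- sample(c(0, 100, 10000), 1)
    expect_equal(proximity_count(pts, tg, md),
                 oracle_proximity_count(pts, tg, md))
  }
})

test_that("boundary alignment and tiling behave at identity, offset and runs", {
  a <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1e6, 5e6), c(2e6, 9e6)))
  idt <- boundary_alignment(a, a, tolerance = 0)
  expect_equal(idt$n_aligned, 4L)
  expect_equal(idt$n_tiled, 2L)

  off <- GenomicRanges::shift(a, 40001)
  expect_equal(boundary_alignment(a, off, tolerance = 40000)$n_aligned, 0L)

  # an a-peak spanning exactly three consecutive b intervals is tiled
  b3 <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(5e6, 6e6, 7e6) + c(0, 1, 1),
                                                      c(6e6, 7e6, 9e6)))
  res <- boundary_alignment(a[2], b3, tolerance = 0)
  expect_equal(res$n_tiled, 1L)

  set.seed(13)
  sizes <- oracle_sizes()
  for (rep in 1:10) {
    x <- random_intervals(8, sizes, max_len = 3e5)
    y <- random_intervals(10, sizes, max_len = 2e5)
    tol <- sample(c(0, 1e4, 4e4), 1)
    got <- boundary_alignment(x, y, tol)
    want <- oracle_boundary_alignment(x, y, tol)
    expect_equal(got$n_aligned, want$n_aligned)
    expect_equal(got$n_tiled, want$n_tiled)
  }
})
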