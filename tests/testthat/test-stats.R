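test_that("odds ratio is the cross-product ratio with documented edge handling", {
  expect_equal(odds_ratio(contingency_table(1, 1, 1, 1)), 1)
  # the printed single-cell table
  expect_equal(odds_ratio(contingency_table(170, 40, 110, 83)),
               170 * 83 / (40 * 110), tolerance = 1e-12)
  # row-scale invariance
  t1 <- contingency_table(3, 5, 7, 11)
  t2 <- contingency_table(12, 20, 7, 11)
  expect_equal(odds_ratio(t1), odds_ratio(t2))
  expect_warning(inf <- odds_ratio(contingency_table(5, 0, 3, 2)), "Inf")
  expect_identical(inf, Inf)
  expect_equal(odds_ratio(contingency_table(5, 0, 3, 2), correction = TRUE),
               (5.5 * 2.5) / (0.5 * 3.5))
})

test_that("chi-square test matches the closed form and flags zero margins", {
  t <- contingency_table(170, 40, 110, 83)
  res <- chi_square_test(t)
  n <- 403
  closed <- n * (170 * 83 - 40 * 110)^2 / (210 * 193 * 280 * 123)
  expect_equal(res$statistic, closed, tolerance = 1e-10)
  expect_lt(res$p.value, 5e-7)
  expect_equal(res$p.value, pchisq(closed, 1, lower.tail = FALSE))

  flat <- chi_square_test(contingency_table(10, 10, 10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  set.seed(2)
  for (rep in 1:20) {
    cells <- sample(1:50, 4)
    got <- chi_square_test(do.call(contingency_table, as.list(cells)))
    expect_equal(got$statistic, do.call(oracle_chisq_stat, as.list(cells)),
                 tolerance = 1e-10)
  }
  expect_error(chi_square_test(contingency_table(0, 0, 5, 5)), "margin")
})

test_that("Fisher's exact test agrees with hypergeometric enumeration", {
  expect_equal(fisher_exact(contingency_table(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact(contingency_table(5, 0, 0, 5)), 2 / choose(10, 5),
               tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:20) {
    cells <- sample(0:12, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    expect_equal(fisher_exact(do.call(contingency_table, as.list(cells))),
                 do.call(oracle_fisher_p, as.list(cells)), tolerance = 1e-8)
  }
})

test_that("chi-square and Fisher agree in rejection direction on solid tables", {
  set.seed(6)
  for (rep in 1:25) {
    cells <- sample(5:60, 4, replace = TRUE)
    t <- do.call(contingency_table, as.list(cells))
    p1 <- chi_square_test(t)$p.value
    p2 <- fisher_exact(t)
    expect_true((p1 < 0.05) == (p2 < 0.05) ||
                  abs(p1 - 0.05) < 0.03 || abs(p2 - 0.05) < 0.03)
  }
})

test_that("density profiles tile the genome and conserve counts", {
  sizes <- chrom_sizes(c(c1 = 250, c2 = 100))
  pts <- GenomicRanges::GRanges(c("c1", "c1", "c1", "c2"),
                                IRanges::IRanges(c(5, 20, 90, 40), c(5, 20, 90, 40)))
  dp <- density_profile(pts, sizes, bin = 100)
  expect_equal(sum(dp$counts), 4L)
  expect_equal(dp$counts[1], 3L)  # three points in c1:[1,100]
  expect_equal(as.data.frame(dp$bins)$width, c(100, 100, 50, 100))
  # bin = chromosome length: per-chromosome totals
  dp2 <- density_profile(pts, sizes, bin = 250)
  expect_equal(dp2$counts, c(3L, 1L))
})

test_that("profile correlation is exact on identity and strict on binning", {
  sizes <- chrom_sizes(c(c1 = 1000))
  p1 <- density_profile(GenomicRanges::GRanges("c1", IRanges::IRanges(1:20 * 40, 1:20 * 40)),
                        sizes, bin = 100)
  expect_equal(profile_correlation(p1, p1, "spearman")$rho, 1)
  p2 <- density_profile(GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1)),
                        sizes, bin = 50)
  expect_error(profile_correlation(p1, p2), "mismatch")
  # reversed strictly monotone counts give spearman -1
  a <- p1; a$counts <- 1:10
  b <- p1; b$counts <- 10:1
  expect_equal(profile_correlation(a, b, "spearman")$rho, -1)
})

test_that("interval shuffling preserves lengths, is seeded, and places uniformly", {
  sizes <- chrom_sizes(c(c1 = 1e6, c2 = 5e5))
  pk <- GenomicRanges::GRanges(c("c1", "c1", "c2"),
                               IRanges::IRanges(c(1, 2000, 10), c(1500, 2100, 500)))
  set.seed(1); s1 <- shuffle_intervals(pk, sizes)
  expect_equal(IRanges::width(s1), IRanges::width(pk))
  expect_equal(as.character(GenomicRanges::seqnames(s1)),
               as.character(GenomicRanges::seqnames(pk)))
  set.seed(1); s2 <- shuffle_intervals(pk, sizes)
  expect_identical(start(s1), start(s2))
  # no overlap among placed intervals
  expect_equal(length(GenomicRanges::reduce(s1)), 3L)

  too_long <- GenomicRanges::GRanges("c2", IRanges::IRanges(1, 6e5))
  expect_error(shuffle_intervals(too_long, sizes), "longer")

  # uniform placement: chi-square goodness of fit over 10,000 draws
  # (20 independent same-length chromosomes per shuffle, 500 shuffles)
  set.seed(8)
  sizes20 <- chrom_sizes(stats::setNames(rep(1e6, 20), sprintf("u%02d", 1:20)))
  tmpl <- GenomicRanges::GRanges(names(sizes20), IRanges::IRanges(1, 100))
  starts <- unlist(lapply(1:500, function(i)
    start(shuffle_intervals(tmpl, sizes20))))
  h <- table(cut(starts, breaks = seq(0, 1e6 - 99, length.out = 21)))
  expect_gt(chisq.test(h)$p.value, 0.001)
})

test_that("permutation p-values follow the add-one estimator", {
  sizes <- chrom_sizes(c(c1 = 1e7))
  pk <- GenomicRanges::GRanges("c1", IRanges::IRanges(4000001, 4100000))
  pos <- seq(4000001, 4100000, length.out = 200)
  pts <- GenomicRanges::GRanges("c1", IRanges::IRanges(pos, pos))
  stat <- function(p, x) sum(GenomicRanges::countOverlaps(x, p) > 0)
  res <- permutation_test(stat, pk, pts, sizes, n_perm = 200, seed = 42)
  # all 200 points inside the observed peak beats every shuffled placement
  expect_equal(res$observed, 200)
  expect_equal(res$p.value, 1 / 201)
  expect_length(res$null, 200L)
  res2 <- permutation_test(stat, pk, pts, sizes, n_perm = 200, seed = 42)
  expect_identical(res$null, res2$null)
  expect_error(permutation_test(stat, pk, pts, sizes, n_perm = 0), "n_perm")
})

test_that("the fast points-in-peaks permutation route matches the generic one draw for draw", {
  set.seed(21)
  sizes <- chrom_sizes(c(c1 = 2e6, c2 = 1e6))
  pk <- GenomicRanges::GRanges(c("c1", "c1", "c2"),
                               IRanges::IRanges(c(1e5, 9e5, 2e5),
                                                width = c(5e4, 8e4, 6e4)),
                               seqlengths = setNames(as.integer(sizes), names(sizes)))
  pts <- random_points(300, sizes)
  stat <- function(p, m) sum(GenomicRanges::countOverlaps(m, p) > 0) / length(m)
  g <- permutation_test(stat, pk, pts, sizes, n_perm = 50, seed = 99)
  f <- permutation_test_points(pk, pts, sizes, n_perm = 50, seed = 99)
  expect_equal(f$observed, g$observed)
  expect_identical(f$null, g$null)
  expect_equal(f$p.value, g$p.value)
})

test_that("window association tables match a per-window scan", {
  sizes <- chrom_sizes(c(c1 = 10000))
  A <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 5000))
  t <- window_association(A, A, sizes, window = 1000)
  expect_equal(t$b + t$c, 0)
  expect_warning(expect_identical(odds_ratio(t), Inf))
  B <- GenomicRanges::GRanges("c1", IRanges::IRanges(5001, 10000))
  expect_equal(window_association(A, B, sizes, window = 1000)$a, 0)
  set.seed(10)
  for (rep in 1:8) {
    x <- random_intervals(4, chrom_sizes(c(c1 = 10000)), max_len = 2000)
    y <- random_intervals(4, chrom_sizes(c(c1 = 10000)), max_len = 2000)
    t <- window_association(x, y, chrom_sizes(c(c1 = 10000)), window = 500)
    # brute force per window
    a <- b <- c <- d <- 0L
    for (w0 in seq(1, 10000, by = 500)) {
      win <- GenomicRanges::GRanges("c1", IRanges::IRanges(w0, w0 + 499))
      ia <- length(GenomicRanges::findOverlaps(win, x)) > 0
      ib <- length(GenomicRanges::findOverlaps(win, y)) > 0
      if (ia && ib) a <- a + 1L else if (ia) b <- b + 1L
      else if (ib) c <- c + 1L else d <- d + 1L
    }
    expect_equal(unlist(t[c("a", "b", "c", "d")]), c(a = a, b = b, c = c, d = d))
  }
})
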