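#' Construct a 2x2 contingency table
#'
#' Rows are condition 1 (yes/no), columns condition 2 (yes/no):
#' `a` = both, `b` = condition 1 only, `c` = condition 2 only, `d` = neither.
#'
#' @param a,b,c,d non-negative integer cell counts; total must be >= 1.
#' @return list of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == floor(cells)), sum(cells) >= 1)
  structure(as.list(cells), class = "contingency_table")
}

#' @export
as.matrix.contingency_table <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(cond1 = c("yes", "no"), cond2 = c("yes", "no")))
}

#' @export
print.contingency_table <- function(x, ...) {
  print(as.matrix(x)); invisible(x)
}

#' Sample (cross-product) odds ratio of a 2x2 table
#'
#' Returns `(a*d)/(b*c)`. When `b*c = 0` the ratio is `+Inf` with a warning,
#' unless `correction = TRUE` applies the Haldane-Anscombe correction
#' (adds 0.5 to every cell).
#'
#' @param t a [contingency_table()].
#' @param correction apply the Haldane-Anscombe 0.5 correction.
#' @return numeric odds ratio.
#' @export
odds_ratio <- function(t, correction = FALSE) {
  # doubles: integer cell products overflow on genome-window tables
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  if (correction) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  if (b * c == 0) {
    warning("odds_ratio: zero off-diagonal product; returning Inf")
    return(Inf)
  }
  (a * d) / (b * c)
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' One degree of freedom, upper-tail p; no continuity correction by default.
#'
#' @param t a [contingency_table()].
#' @param yates apply the Yates continuity correction.
#' @return list with `statistic` and `p.value`.
#' @export
chi_square_test <- function(t, yates = FALSE) {
  m <- as.matrix(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi_square_test: zero margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' @param t a [contingency_table()].
#' @return two-sided hypergeometric exact p-value.
#' @export
fisher_exact <- function(t) {
  stats::fisher.test(as.matrix(t), alternative = "two.sided")$p.value
}

#' Genome-binned density profile of a point set
#'
#' Counts point midpoints in fixed-width bins tiling every chromosome (the
#' last bin of each chromosome may be short). The total over bins equals the
#' number of points.
#'
#' @param points `GRanges` (midpoints of each range are used) or a pair table.
#' @param sizes `chrom_sizes`.
#' @param bin bin width in bp (>= 1).
#' @return list of class `density_profile`: `bin`, `bins` (GRanges), `counts`.
#' @export
density_profile <- function(points, sizes, bin) {
  stopifnot(bin >= 1)
  if (is.data.frame(points)) points <- dna_midpoints(points, sizes)
  mid <- floor((start(points) + end(points)) / 2)
  pts <- GRanges(seqnames(points), IRanges(mid, mid))
  bins <- tileGenome(.seqlengths(sizes), tilewidth = bin,
                     cut.last.tile.in.chrom = TRUE)
  structure(list(bin = bin, bins = bins,
                 counts = countOverlaps(bins, pts, ignore.strand = TRUE)),
            class = "density_profile")
}

#' Correlation between two density profiles
#'
#' Profiles must share the same binning. Spearman uses mid-ranks for ties,
#' the standard treatment for heavily tied count data.
#'
#' @param p1,p2 `density_profile` objects on identical bins.
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `rho` and `p.value`.
#' @export
profile_correlation <- function(p1, p2, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (p1$bin != p2$bin || length(p1$counts) != length(p2$counts) ||
      !identical(as.character(seqnames(p1$bins)), as.character(seqnames(p2$bins))) ||
      !identical(start(p1$bins), start(p2$bins)))
    stop("profile_correlation: binning mismatch")
  res <- suppressWarnings(
    stats::cor.test(p1$counts, p2$counts, method = method, exact = FALSE))
  list(rho = unname(res$estimate), p.value = res$p.value)
}

#' Chromosome-preserving uniform shuffle of an interval set
#'
#' The permutation null for interval association tests: each interval is
#' independently re-placed uniformly at random on its own chromosome,
#' preserving its length; placements overlapping an already-placed interval
#' are re-drawn (up to `max_attempts`, then an error). Uses the current RNG
#' state; seed via `set.seed()` or [permutation_test()].
#'
#' @param peaks `GRanges` to shuffle.
#' @param sizes `chrom_sizes`.
#' @param max_attempts re-draw limit per interval.
#' @return shuffled `GRanges` (metadata columns preserved).
#' @export
shuffle_intervals <- function(peaks, sizes, max_attempts = 1000L) {
  n <- length(peaks)
  if (n == 0L) return(peaks)
  ch <- as.character(seqnames(peaks))
  len <- unname(sizes[ch])
  w <- width(peaks)
  if (any(is.na(len)) || any(w > len))
    stop("shuffle_intervals: interval longer than its chromosome")
  ns <- .shuffle_starts(ch, len, w, max_attempts)
  out <- GRanges(ch, IRanges(ns, width = w), seqlengths = .seqlengths(sizes))
  mcols(out) <- mcols(peaks)
  out
}

# plain-vector core of the shuffle: sequential uniform placement with
# rejection against previously placed intervals on the same chromosome
.shuffle_starts <- function(ch, len, w, max_attempts = 1000L) {
  n <- length(ch)
  ns <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      s <- 1 + floor(stats::runif(1) * (len[i] - w[i] + 1))
      prev <- which(ch[seq_len(i - 1L)] == ch[i])
      if (!length(prev) ||
          all(s + w[i] - 1 < ns[prev] | s > ns[prev] + w[prev] - 1)) {
        ns[i] <- s; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("shuffle_intervals: could not place interval ", i,
           " without overlap after ", max_attempts, " attempts")
  }
  ns
}

#' Permutation test with a chromosome-preserving shuffled null
#'
#' Computes `observed = stat_fn(shuffleable, fixed)` and a null sample by
#' re-evaluating the statistic on shuffled copies of `shuffleable`
#' ([shuffle_intervals()]). The empirical p-value uses the add-one
#' (Phipson-Smyth) estimator `p = (1 + #{null >= observed}) / (1 + n_perm)`
#' for `tail = "greater"` (mirrored for `"less"`), so the smallest attainable
#' p with 1,000 permutations is 1/1001 and p is never 0.
#'
#' @param stat_fn deterministic function of `(intervals, fixed)` returning one
#'   number (e.g. reads-in-peaks fraction, peak-overlap count, aligned-boundary
#'   count).
#' @param shuffleable `GRanges` whose placement forms the null.
#' @param fixed the fixed operand passed through to `stat_fn`.
#' @param sizes `chrom_sizes`.
#' @param n_perm number of permutations (>= 1).
#' @param tail `"greater"` or `"less"`.
#' @param seed optional integer seed.
#' @return list of class `permutation_result`: observed, null (length
#'   `n_perm`), p.value, tail, n_perm, seed.
#' @export
permutation_test <- function(stat_fn, shuffleable, fixed, sizes,
                             n_perm = 1000L, tail = c("greater", "less"),
                             seed = NULL) {
  tail <- match.arg(tail)
  if (n_perm < 1L) stop("permutation_test: n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  observed <- stat_fn(shuffleable, fixed)
  null <- vapply(seq_len(n_perm), function(i)
    stat_fn(shuffle_intervals(shuffleable, sizes), fixed), numeric(1))
  p <- if (tail == "greater") (1 + sum(null >= observed)) / (1 + n_perm)
       else (1 + sum(null <= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null, p.value = p, tail = tail,
                 n_perm = n_perm, seed = seed), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s tail, %d permutations): observed = %g, p = %g\n",
              x$tail, x$n_perm, x$observed, x$p.value))
  invisible(x)
}

#' Fast permutation test for points-in-intervals statistics
#'
#' Specialisation of [permutation_test()] for the reads-in-peaks statistic:
#' the number (or fraction) of points falling inside a disjoint interval set,
#' against the chromosome-preserving shuffled null. The statistic and the
#' shuffle consume the random stream in exactly the same order as the generic
#' route, so under one seed both produce identical null samples - the
#' implementation is vector arithmetic (sorted positions + `findInterval`)
#' rather than per-permutation range objects, which matters when thousands of
#' placements are evaluated.
#'
#' @param peaks disjoint `GRanges` whose placement forms the null.
#' @param points `GRanges` of positions (midpoints are taken), or a pair
#'   table (DNA-end midpoints are used).
#' @param sizes `chrom_sizes`.
#' @param n_perm,tail,seed as in [permutation_test()].
#' @param statistic `"fraction"` of points in peaks, or raw `"count"`.
#' @return a `permutation_result`.
#' @export
permutation_test_points <- function(peaks, points, sizes, n_perm = 1000L,
                                    tail = c("greater", "less"), seed = NULL,
                                    statistic = c("fraction", "count")) {
  tail <- match.arg(tail)
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("permutation_test: n_perm must be >= 1")
  if (is.data.frame(points)) points <- dna_midpoints(points, sizes)
  if (length(peaks) && !isDisjoint(peaks))
    stop("permutation_test_points: peaks must be disjoint")
  if (!is.null(seed)) set.seed(seed)
  mid <- floor((start(points) + end(points)) / 2)
  bych <- lapply(split(mid, as.character(seqnames(points))), sort)
  ch <- as.character(seqnames(peaks))
  w <- width(peaks)
  len <- unname(sizes[ch])
  if (any(is.na(len)) || any(w > len))
    stop("shuffle_intervals: interval longer than its chromosome")
  idx_by_ch <- split(seq_along(ch), ch)
  count_in <- function(s) {
    tot <- 0
    e <- s + w - 1
    for (cc in names(idx_by_ch)) {
      v <- bych[[cc]]
      if (is.null(v)) next
      i <- idx_by_ch[[cc]]
      tot <- tot + sum(findInterval(e[i], v) - findInterval(s[i] - 1, v))
    }
    tot
  }
  denom <- if (statistic == "fraction") length(points) else 1
  observed <- count_in(start(peaks)) / denom
  null <- vapply(seq_len(n_perm), function(i)
    count_in(.shuffle_starts(ch, len, w)) / denom, numeric(1))
  p <- if (tail == "greater") (1 + sum(null >= observed)) / (1 + n_perm)
       else (1 + sum(null <= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null, p.value = p, tail = tail,
                 n_perm = n_perm, seed = seed), class = "permutation_result")
}

#' Window-level association table between two interval sets
#'
#' Splits the genome into fixed-width windows and classifies each window by
#' overlap (>= 1 bp) with sets A and B; the window-count 2x2 table feeds
#' [fisher_exact()] / [odds_ratio()].
#'
#' @param peaksA,peaksB `GRanges`.
#' @param sizes `chrom_sizes`.
#' @param window window width in bp.
#' @return A [contingency_table()] (a = windows overlapping both).
#' @export
window_association <- function(peaksA, peaksB, sizes, window = 1000L) {
  stopifnot(window >= 1)
  bins <- tileGenome(.seqlengths(sizes), tilewidth = window,
                     cut.last.tile.in.chrom = TRUE)
  inA <- countOverlaps(bins, peaksA, ignore.strand = TRUE) > 0L
  inB <- countOverlaps(bins, peaksB, ignore.strand = TRUE) > 0L
  contingency_table(sum(inA & inB), sum(inA & !inB),
                    sum(!inA & inB), sum(!inA & !inB))
}
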