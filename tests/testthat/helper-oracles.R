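# brute-force oracles, deliberately independent of the package's
# GenomicRanges-based implementations: plain loops over data.frames.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(data.table)
})

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), stringsAsFactors = FALSE)
}

# random non-degenerate interval set on a toy genome
random_intervals <- function(n, sizes, max_len = 1e5) {
  ch <- sample(names(sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- mapply(function(c, l) sample.int(max(1, sizes[[c]] - l), 1L), ch, len)
  GRanges(ch, IRanges(start, start + len - 1),
          seqlengths = setNames(as.integer(sizes), names(sizes)))
}

random_points <- function(n, sizes) {
  ch <- sample(names(sizes), n, replace = TRUE)
  pos <- vapply(ch, function(c) sample.int(sizes[[c]], 1L), 1L)
  GRanges(ch, IRanges(pos, pos))
}

oracle_overlap_count <- function(a, b) {
  A <- gr_to_df(a); B <- gr_to_df(b)
  n <- 0L
  for (i in seq_len(nrow(A))) {
    hit <- FALSE
    for (j in seq_len(nrow(B))) {
      if (A$chrom[i] == B$chrom[j] &&
          A$start[i] <= B$end[j] && B$start[j] <= A$end[i]) { hit <- TRUE; break }
    }
    if (hit) n <- n + 1L
  }
  n
}

oracle_points_in_intervals <- function(points, intervals) {
  P <- gr_to_df(points); I <- gr_to_df(intervals)
  n <- 0L
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(nrow(I))) {
      if (P$chrom[i] == I$chrom[j] &&
          P$start[i] >= I$start[j] && P$start[i] <= I$end[j]) { n <- n + 1L; break }
    }
  }
  n
}

# nearest-edge offset distance from each interval to its closest point
oracle_proximity_count <- function(points, targets, max_dist) {
  P <- gr_to_df(points); Tt <- gr_to_df(targets)
  n <- 0L
  for (i in seq_len(nrow(P))) {
    best <- Inf
    for (j in seq_len(nrow(Tt))) {
      if (P$chrom[i] != Tt$chrom[j]) next
      m <- Tt$start[j]
      d <- max(P$start[i] - m, m - P$end[i], 0)
      best <- min(best, d)
    }
    if (best <= max_dist) n <- n + 1L
  }
  n
}

oracle_boundary_alignment <- function(a, b, tol) {
  A <- gr_to_df(a); B <- gr_to_df(b)
  n_aligned <- 0L; n_tiled <- 0L
  for (i in seq_len(nrow(A))) {
    bb <- c(B$start[B$chrom == A$chrom[i]], B$end[B$chrom == A$chrom[i]])
    for (pos in c(A$start[i], A$end[i]))
      if (length(bb) && any(abs(bb - pos) <= tol)) n_aligned <- n_aligned + 1L
    # tiled: search every run of b-intervals inside the peak
    Bi <- B[B$chrom == A$chrom[i] & B$start >= A$start[i] - tol &
              B$end <= A$end[i] + tol, , drop = FALSE]
    Bi <- Bi[order(Bi$start), , drop = FALSE]
    tiled <- FALSE
    if (nrow(Bi) > 0 &&
        abs(Bi$start[1] - A$start[i]) <= tol &&
        abs(Bi$end[nrow(Bi)] - A$end[i]) <= tol) {
      ok <- TRUE
      if (nrow(Bi) > 1)
        for (k in 2:nrow(Bi))
          if (Bi$start[k] - Bi$end[k - 1] - 1 > tol) ok <- FALSE
      tiled <- ok
    }
    if (tiled) n_tiled <- n_tiled + 1L
  }
  list(n_aligned = n_aligned, n_tiled = n_tiled)
}

# O(n^2) single-linkage clustering of positions on one chromosome
oracle_single_linkage <- function(pos, gap) {
  n <- length(pos)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= gap && lab[i] != lab[j]) {
        lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

oracle_chisq_stat <- function(a, b, c, d) {
  O <- c(a, b, c, d)
  n <- sum(O)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  E <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  sum((O - E)^2 / E)
}

oracle_ks_stat <- function(x, y) {
  g <- sort(unique(c(x, y)))
  Fx <- vapply(g, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(g, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# two-sided Fisher exact p by full enumeration over fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  as <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(as, function(x)
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)), numeric(1))
  p_obs <- probs[as == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_jaccard_recall <- function(called, truth, min_j) {
  C <- gr_to_df(called); Tt <- gr_to_df(truth)
  rec <- 0L
  for (i in seq_len(nrow(Tt))) {
    best <- 0
    for (j in seq_len(nrow(C))) {
      if (Tt$chrom[i] != C$chrom[j]) next
      inter <- max(0, min(Tt$end[i], C$end[j]) - max(Tt$start[i], C$start[j]) + 1)
      uni <- (Tt$end[i] - Tt$start[i] + 1) + (C$end[j] - C$start[j] + 1) - inter
      best <- max(best, inter / uni)
    }
    if (best >= min_j) rec <- rec + 1L
  }
  rec / nrow(Tt)
}

# junction rule by direct enumeration of every transcript junction
oracle_p_pre <- function(pairs, annotation, k) {
  out <- logical(nrow(pairs))
  ex <- merge(annotation$exons,
              annotation$genes[, c("gene_id", "rna_class")], by = "gene_id")
  ex <- ex[ex$rna_class == "coding", ]
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$rna_start[i]; e <- pairs$rna_end[i]
    for (tx in unique(ex$transcript_id)) {
      et <- ex[ex$transcript_id == tx, ]
      et <- et[order(et$start), ]
      if (et$chrom[1] != pairs$rna_chrom[i]) next
      if (et$strand[1] != pairs$rna_strand[i]) next
      if (nrow(et) < 2) next
      for (j in seq_len(nrow(et) - 1)) {
        ilo <- et$end[j] + 1; ihi <- et$start[j + 1] - 1
        # exon left of intron
        exon_cov <- max(0, min(e, et$end[j]) - max(s, et$start[j]) + 1)
        intron_cov <- max(0, min(e, ihi) - ilo + 1)
        if (exon_cov >= 1 && s <= et$end[j] && e > et$end[j] && intron_cov >= k)
          out[i] <- TRUE
        # exon right of intron
        exon_cov <- max(0, min(e, et$end[j + 1]) - max(s, et$start[j + 1]) + 1)
        intron_cov <- max(0, ihi - max(s, ilo) + 1)
        if (exon_cov >= 1 && e >= et$start[j + 1] && s < et$start[j + 1] &&
            intron_cov >= k)
          out[i] <- TRUE
      }
    }
  }
  out
}
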