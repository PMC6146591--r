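#' Peak-calling parameters
#'
#' @param cluster_max_gap single-linkage joining distance (bp) between
#'   consecutive DNA-end midpoints for candidate clustering.
#' @param min_reads minimum reads per retained cluster/peak.
#' @param min_cluster_span minimum candidate-cluster span (bp, distance
#'   between extreme member midpoints). The candidate-peak threshold pair
#'   (`min_reads` = 9 reads, `min_cluster_span` = 500 kb) reproduces the
#'   two axis cutoffs of the candidate-peak scatter analysis.
#' @param window genome tiling bin width (bp) for broad-peak calling.
#' @param enrichment_fold a bin is marked enriched when its DNA-end count
#'   exceeds `max(1, enrichment_fold x genome-mean count per bin)`.
#' @param merge_gap marked bins closer than this (bp) are merged into one
#'   broad peak.
#' @param min_peak_span minimum span (bp) of a merged broad peak. Defaults to
#'   100 kb, the smallest broad-domain size the method is meant to report;
#'   the 500-kb `min_cluster_span` applies to the candidate-peak path only.
#' @return list of class `peak_params`.
#' @export
peak_params <- function(cluster_max_gap = 100000L, min_reads = 9L,
                        min_cluster_span = 500000L, window = 25000L,
                        enrichment_fold = 4, merge_gap = 100000L,
                        min_peak_span = 100000L) {
  p <- list(cluster_max_gap = cluster_max_gap, min_reads = min_reads,
            min_cluster_span = min_cluster_span, window = window,
            enrichment_fold = enrichment_fold, merge_gap = merge_gap,
            min_peak_span = min_peak_span)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "peak_params")
}

#' DNA-end midpoints of a pair table
#'
#' Reduces each DNA-end interval to its midpoint; reads are short relative to
#' the 100 kb - 13 Mb domain scale, so the midpoint carries all usable
#' positional information.
#'
#' @param pairs pair table.
#' @param sizes `chrom_sizes` (sets seqlengths on the result).
#' @return width-1 `GRanges` of midpoints, one per pair.
#' @export
dna_midpoints <- function(pairs, sizes) {
  mid <- floor((pairs$dna_start + pairs$dna_end) / 2)
  GRanges(pairs$dna_chrom, IRanges(mid, mid), seqlengths = .seqlengths(sizes))
}

#' Single-linkage clustering of DNA-end midpoints
#'
#' Per chromosome, consecutive sorted midpoints at most `cluster_max_gap`
#' apart join the same cluster; every read belongs to exactly one cluster.
#'
#' @param pairs pair table (nascent-filtered and class-selected upstream).
#' @param sizes `chrom_sizes`.
#' @param params [peak_params()].
#' @return `GRanges` of clusters spanning the min..max member midpoints, with
#'   `read_count`, `span` (max - min midpoint, bp) and a `read_ids` list
#'   column.
#' @export
cluster_dna_ends <- function(pairs, sizes, params = peak_params()) {
  mids <- dna_midpoints(pairs, sizes)
  if (length(mids) == 0L) return(GRanges(seqlengths = .seqlengths(sizes)))
  dt <- data.table(chrom = as.character(seqnames(mids)), pos = start(mids),
                   read_id = pairs$read_id)
  setorder(dt, chrom, pos)
  dt[, new_cluster := c(TRUE, diff(pos) > params$cluster_max_gap), by = chrom]
  dt[, cid := cumsum(new_cluster)]
  cl <- dt[, .(chrom = chrom[1L], start = min(pos), end = max(pos),
               read_count = .N, read_ids = list(read_id)), by = cid]
  setorder(cl, chrom, start)
  gr <- GRanges(cl$chrom, IRanges(cl$start, cl$end), seqlengths = .seqlengths(sizes))
  mcols(gr)$read_count <- cl$read_count
  mcols(gr)$span <- cl$end - cl$start
  mcols(gr)$read_ids <- cl$read_ids
  gr
}

#' Candidate peaks from midpoint clusters
#'
#' Retains clusters with at least `min_reads` reads and a span of at least
#' `min_cluster_span` bp - the quadrant of the read-count x cluster-size
#' plane where stable-interaction candidate peaks concentrate.
#'
#' @param clusters output of [cluster_dna_ends()].
#' @param params [peak_params()].
#' @return filtered `GRanges`.
#' @export
candidate_peaks <- function(clusters, params = peak_params()) {
  clusters[mcols(clusters)$read_count >= params$min_reads &
             mcols(clusters)$span >= params$min_cluster_span]
}

#' Call broad enrichment domains (nsaPeaks and analogues)
#'
#' Deterministic windowed enrichment-merge procedure over sparse DNA-end
#' midpoints: tile the genome in `window`-bp bins; mark bins whose midpoint
#' count exceeds `max(1, enrichment_fold x genome-mean count per bin)`; merge
#' marked bins within `merge_gap`; retain merged regions with at least
#' `min_reads` reads, at least `min_peak_span` bp span, and an overall
#' density still exceeding the same enrichment rule over the full region
#' span. The region-level density requirement is what separates true broad
#' domains (nearly every bin enriched) from chance pairs of marginal noise
#' bins bridged by the merge step, and calibrates the caller so a uniform
#' read cloud yields no peaks. The enrichment ratios are scale-invariant:
#' duplicating every read leaves the peak intervals unchanged (whenever the
#' threshold floor of one read is not active).
#'
#' @param pairs pair table (non-nascent, class-selected).
#' @param sizes `chrom_sizes`.
#' @param params [peak_params()].
#' @return sorted non-overlapping `GRanges` with `name` and `read_count`.
#' @export
call_broad_peaks <- function(pairs, sizes, params = peak_params()) {
  if (nrow(pairs) == 0L) {
    warning("call_broad_peaks: no input pairs; returning empty peak set")
    return(GRanges(seqlengths = .seqlengths(sizes)))
  }
  mids <- dna_midpoints(pairs, sizes)
  bins <- tileGenome(.seqlengths(sizes), tilewidth = params$window,
                     cut.last.tile.in.chrom = TRUE)
  counts <- countOverlaps(bins, mids)
  thresh <- max(1, params$enrichment_fold * length(mids) / length(bins))
  marked <- bins[counts > thresh]
  merged <- reduce(marked, min.gapwidth = params$merge_gap + 1L)
  if (length(merged)) {
    mcols(merged)$read_count <- countOverlaps(merged, mids)
    dens_ok <- mcols(merged)$read_count >
      thresh * width(merged) / params$window
    merged <- merged[dens_ok &
                       mcols(merged)$read_count >= params$min_reads &
                       width(merged) >= params$min_peak_span]
  }
  merged <- sort(merged)
  if (length(merged))
    mcols(merged)$name <- sprintf("peak_%03d", seq_along(merged))
  message("call_broad_peaks: ", length(mids), " reads -> ", length(merged),
          " broad peak(s)")
  merged
}

#' Reads falling inside a peak set
#'
#' @param pairs pair table.
#' @param peaks `GRanges` peak set.
#' @param sizes `chrom_sizes`.
#' @return list with `count` and `fraction` of pairs whose DNA-end midpoint
#'   lies inside any peak.
#' @export
reads_in_peaks <- function(pairs, peaks, sizes) {
  if (nrow(pairs) == 0L) return(list(count = 0L, fraction = 0))
  mids <- dna_midpoints(pairs, sizes)
  n <- sum(countOverlaps(mids, peaks, ignore.strand = TRUE) > 0L)
  list(count = n, fraction = n / length(mids))
}

#' Count peaks of one set overlapping another
#'
#' A peak of `a` counts as overlapping when it shares at least 1 bp with any
#' peak of `b`.
#'
#' @param a,b `GRanges` peak sets.
#' @return list with `n` (overlapping peaks of `a`) and `fraction` (of `a`).
#' @export
overlap_peaksets <- function(a, b) {
  # disjoint-chromosome comparisons are legitimate; silence seqlevel chatter
  n <- sum(suppressWarnings(countOverlaps(a, b, ignore.strand = TRUE)) > 0L)
  list(n = n, fraction = if (length(a)) n / length(a) else 0)
}

#' Union of two peak sets
#'
#' Interval union; overlapping or bookended intervals are merged.
#'
#' @param a,b `GRanges` on the same genome.
#' @return merged, sorted `GRanges`.
#' @export
union_peaks <- function(a, b) {
  u <- reduce(sort(suppressWarnings(c(granges(a), granges(b)))),
              ignore.strand = TRUE)  # inputs may carry disjoint seqlevels
  if (length(u)) mcols(u)$name <- sprintf("union_%03d", seq_along(u))
  u
}

#' Count intervals with a nearby target point
#'
#' Number of `points` intervals whose nearest target midpoint lies within
#' `max_dist` of the interval. Distance is the nearest-edge offset: a target
#' inside the interval has distance 0, the base immediately adjacent has
#' distance 1, so a target 201 bp away is not counted at `max_dist = 200`.
#'
#' @param points `GRanges` intervals (e.g. ChIP narrow peaks).
#' @param targets `GRanges` of target positions (e.g. DNA-end midpoints), or a
#'   pair table (midpoints are taken).
#' @param max_dist maximum distance in bp (>= 0).
#' @param sizes `chrom_sizes`, required when `targets` is a pair table.
#' @return integer count.
#' @export
proximity_count <- function(points, targets, max_dist, sizes = NULL) {
  stopifnot(max_dist >= 0)
  if (is.data.frame(targets)) targets <- dna_midpoints(targets, sizes)
  if (length(points) == 0L || length(targets) == 0L) return(0L)
  d <- rep(Inf, length(points))
  tch <- as.character(seqnames(targets))
  pch <- as.character(seqnames(points))
  for (ch in unique(pch)) {
    tp <- sort(start(targets)[tch == ch])
    if (length(tp) == 0L) next
    idx <- which(pch == ch)
    s <- start(points)[idx]; e <- end(points)[idx]
    # nearest target position per interval via sorted neighbour lookup
    lo <- findInterval(s, tp)              # last target < start (or inside)
    hi <- pmin(lo + 1L, length(tp))
    lo <- pmax(lo, 1L)
    inside <- findInterval(e, tp) > findInterval(s - 1L, tp)
    dd <- pmin(pmax(s - tp[lo], tp[lo] - e, 0),
               pmax(s - tp[hi], tp[hi] - e, 0))
    dd[inside] <- 0
    d[idx] <- dd
  }
  sum(d <= max_dist)
}

#' Boundary alignment between two peak sets
#'
#' Each start/end of `a` counts as aligned when it lies within `tolerance` bp
#' of any start or end of `b` on the same chromosome. A peak of `a` is
#' "tiled" by `b` when both of its boundaries align and the `b` intervals in
#' between partition it into consecutive intervals (internal gaps no larger
#' than `tolerance`) - i.e. the peak coincides with one interval of `b` or
#' several consecutive ones.
#'
#' @param a,b `GRanges` peak sets (e.g. nsaPeaks vs TADs).
#' @param tolerance alignment tolerance in bp; defaults to 40 kb, one Hi-C
#'   bin, since TAD boundaries are bin-quantised.
#' @return list with `n_aligned` (aligned boundaries of `a`),
#'   `n_boundaries` (2 x number of peaks of `a`) and `n_tiled`.
#' @export
boundary_alignment <- function(a, b, tolerance = 40000L) {
  stopifnot(tolerance >= 0)
  ach <- as.character(seqnames(a)); bch <- as.character(seqnames(b))
  n_aligned <- 0L; n_tiled <- 0L
  for (ch in unique(ach)) {
    ai <- which(ach == ch); bi <- which(bch == ch)
    bb <- sort(c(start(b)[bi], end(b)[bi]))
    for (i in ai) {
      for (pos in c(start(a)[i], end(a)[i])) {
        if (length(bb) && min(abs(bb - pos)) <= tolerance)
          n_aligned <- n_aligned + 1L
      }
      if (length(bi) == 0L) next
      bs <- start(b)[bi]; be <- end(b)[bi]
      run <- which(bs >= start(a)[i] - tolerance & be <= end(a)[i] + tolerance)
      if (length(run) == 0L) next
      run <- run[order(bs[run])]
      gaps_ok <- length(run) == 1L ||
        all(bs[run][-1L] - be[run][-length(run)] - 1L <= tolerance)
      if (gaps_ok &&
          abs(bs[run][1L] - start(a)[i]) <= tolerance &&
          abs(be[run][length(run)] - end(a)[i]) <= tolerance)
        n_tiled <- n_tiled + 1L
    }
  }
  list(n_aligned = n_aligned, n_boundaries = 2L * length(a), n_tiled = n_tiled)
}
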