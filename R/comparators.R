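# synthetic external comparators. Real analyses consume TADs and A/B
# compartments as BED computed elsewhere (Hi-C callers); these helpers exist
# only so the boundary-alignment and window-association analyses run offline
# on synthetic data. Everything they emit is labelled synthetic.

#' Simulate a TAD partition with controllable boundary alignment
#'
#' Partitions each autosome into contiguous domains with lengths uniform in
#' `tad_range`; each boundary of `peaks` then replaces its nearest cut with
#' probability `aligned_frac`, planting the boundary-alignment signal.
#'
#' @param sizes `chrom_sizes`.
#' @param peaks `GRanges` whose boundaries are partially planted.
#' @param aligned_frac probability a peak boundary is planted as a TAD
#'   boundary.
#' @param tad_range domain length range (bp).
#' @param chroms chromosomes to partition (default: all but the rDNA unit).
#' @param seed integer seed.
#' @return `GRanges` of synthetic TADs tiling each chromosome.
#' @export
simulate_tads <- function(sizes, peaks, aligned_frac = 0.5,
                          tad_range = c(2e5, 2e6),
                          chroms = setdiff(names(sizes), "rDNA"),
                          seed = 1L) {
  set.seed(seed)
  out <- list()
  pch <- as.character(seqnames(peaks))
  for (ch in chroms) {
    len <- unname(sizes[[ch]])
    cuts <- numeric(0); pos <- 0
    repeat {
      pos <- pos + floor(stats::runif(1, tad_range[1], tad_range[2]))
      if (pos >= len) break
      cuts <- c(cuts, pos)
    }
    pb <- sort(unique(c(start(peaks)[pch == ch] - 1, end(peaks)[pch == ch])))
    pb <- pb[pb > 0 & pb < len]
    planted <- numeric(0)
    for (b in pb) {
      if (stats::runif(1) < aligned_frac) {
        if (length(cuts)) cuts <- cuts[-which.min(abs(cuts - b))]
        planted <- c(planted, b)
      }
    }
    cuts <- sort(unique(c(cuts, planted)))
    bnd <- c(0, cuts, len)
    out[[ch]] <- data.table(chrom = ch, start = bnd[-length(bnd)] + 1,
                            end = bnd[-1])
  }
  dt <- rbindlist(out)
  gr <- GRanges(dt$chrom, IRanges(dt$start, dt$end),
                seqlengths = .seqlengths(sizes))
  mcols(gr)$name <- sprintf("tad_%04d", seq_along(gr))
  gr
}

#' Simulate an A/B compartment partition biased toward a peak set
#'
#' Segments each autosome (lengths uniform in `seg_range`) and labels each
#' segment A with probability `p_a_peak` when it overlaps `peaks`, otherwise
#' `p_a_bg`; adjacent same-label segments are merged.
#'
#' @param sizes `chrom_sizes`.
#' @param peaks `GRanges` (e.g. planted domains or called nsaPeaks).
#' @param p_a_peak,p_a_bg A-label probabilities inside / outside peaks.
#' @param seg_range segment length range (bp).
#' @param chroms chromosomes to partition.
#' @param seed integer seed.
#' @return list with `A` and `B`, each a merged `GRanges`.
#' @export
simulate_compartments <- function(sizes, peaks, p_a_peak = 0.9, p_a_bg = 0.45,
                                  seg_range = c(1e6, 5e6),
                                  chroms = setdiff(names(sizes), "rDNA"),
                                  seed = 1L) {
  set.seed(seed)
  segs <- list()
  for (ch in chroms) {
    len <- unname(sizes[[ch]])
    cuts <- numeric(0); pos <- 0
    repeat {
      pos <- pos + floor(stats::runif(1, seg_range[1], seg_range[2]))
      if (pos >= len) break
      cuts <- c(cuts, pos)
    }
    bnd <- c(0, cuts, len)
    segs[[ch]] <- data.table(chrom = ch, start = bnd[-length(bnd)] + 1,
                             end = bnd[-1])
  }
  dt <- rbindlist(segs)
  gr <- GRanges(dt$chrom, IRanges(dt$start, dt$end),
                seqlengths = .seqlengths(sizes))
  inpk <- countOverlaps(gr, peaks, ignore.strand = TRUE) > 0L
  isA <- stats::runif(length(gr)) < ifelse(inpk, p_a_peak, p_a_bg)
  list(A = reduce(gr[isA]), B = reduce(gr[!isA]))
}
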