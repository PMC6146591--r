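#' Default nsaRNA species list
#'
#' The nuclear speckle-associated noncoding RNA species used for pair
#' classification: the spliceosomal snRNAs of the major and minor spliceosome,
#' 7SK and Malat1.
#' @return character vector of species names.
#' @export
nsa_species <- function() {
  c("U1", "U2", "U4", "U4atac", "U5", "U6", "U6atac", "U11", "U12",
    "7SK", "Malat1")
}

#' Filter parameters for pair classification
#'
#' @param nascent_distance maximum same-chromosome gap (nt, inclusive) between
#'   the RNA and DNA ends for a pair to be flagged as putatively nascent.
#' @param min_intron_overlap minimum number of intronic nucleotides the RNA end
#'   must cover across an exon-intron junction to count as posttranscriptional
#'   pre-mRNA.
#' @param species nsaRNA species names.
#' @param rdna_chrom name of the rDNA repeating-unit pseudo-chromosome.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(nascent_distance = 2000L,
                          min_intron_overlap = 10L,
                          species = nsa_species(),
                          rdna_chrom = "rDNA") {
  stopifnot(nascent_distance >= 0, min_intron_overlap >= 1)
  structure(list(nascent_distance = as.integer(nascent_distance),
                 min_intron_overlap = as.integer(min_intron_overlap),
                 species = species, rdna_chrom = rdna_chrom),
            class = "filter_params")
}

#' Same-chromosome gap between the two ends of each pair
#'
#' Number of bases strictly between the RNA-end and DNA-end intervals;
#' overlapping or bookended intervals have gap 0. `NA` for interchromosomal
#' pairs.
#' @param pairs pair table.
#' @return numeric vector of gaps.
#' @export
pair_gap <- function(pairs) {
  gap <- pmax(0, pmax(pairs$rna_start, pairs$dna_start) -
                 pmin(pairs$rna_end, pairs$dna_end) - 1)
  gap[pairs$rna_chrom != pairs$dna_chrom] <- NA_real_
  gap
}

#' Flag putative nascent-transcript pairs
#'
#' A pair is flagged when both ends lie on the same chromosome and the gap
#' between them is at most `nascent_distance` (inclusive; overlap counts as
#' gap 0). Such pairs likely reflect an RNA still tethered at its own
#' transcription locus rather than a spatial contact, and downstream peak
#' calling operates on the unflagged pairs.
#'
#' @param pairs pair table.
#' @param params [filter_params()].
#' @return `pairs` with a logical `nascent` column set. Idempotent and
#'   order-independent.
#' @export
flag_nascent <- function(pairs, params = filter_params()) {
  pairs <- as.data.table(pairs)
  gap <- pair_gap(pairs)
  pairs$nascent <- !is.na(gap) & gap <= params$nascent_distance
  pairs[]
}

.rna_granges <- function(pairs) {
  GRanges(pairs$rna_chrom, IRanges(pairs$rna_start, pairs$rna_end),
          strand = ifelse(pairs$rna_strand %in% c("+", "-"), pairs$rna_strand, "*"))
}

# junction table: one row per exon-intron junction of every multi-exon
# transcript; `exon_left` TRUE when the exon precedes the intron in genomic
# coordinates. jpos = last exon base (exon_left) / first exon base (!exon_left).
.junction_table <- function(annotation) {
  e <- annotation$exons
  if (nrow(e) == 0L) return(data.table())
  g <- annotation$genes
  e <- e[gene_id %in% g$gene_id[g$rna_class == "coding"]]
  if (nrow(e) == 0L) return(data.table())
  setorder(e, transcript_id, start)
  jl <- e[, if (.N > 1L) .(
    chrom = chrom[1L], strand = strand[1L], gene_id = gene_id[1L],
    exon_end = end[-.N],          # junction with intron to the right
    intron_end = start[-1L] - 1L  # last intron base
  ), by = transcript_id]
  if (nrow(jl) == 0L) return(data.table())
  left <- jl[, .(transcript_id, gene_id, chrom, strand,
                 exon_left = TRUE, jexon = exon_end,
                 intron_lo = exon_end + 1L, intron_hi = intron_end)]
  right <- jl[, .(transcript_id, gene_id, chrom, strand,
                  exon_left = FALSE, jexon = intron_end + 1L,
                  intron_lo = exon_end + 1L, intron_hi = intron_end)]
  rbind(left, right)
}

#' Posttranscriptional pre-mRNA call for the RNA end of each pair
#'
#' TRUE when, for some transcript of a coding gene on the strand of the RNA
#' end, the RNA-end interval covers at least 1 nt of an exon and at least
#' `min_intron_overlap` nt of the adjacent intron across a single exon-intron
#' junction. Reads that straddle a junction this way come from incompletely
#' spliced transcripts; combined with the nascent filter they identify
#' posttranscriptional pre-mRNA detached from its transcription site.
#'
#' @param pairs pair table.
#' @param annotation `gene_annotation`.
#' @param params [filter_params()].
#' @return logical vector, one element per pair.
#' @export
is_p_pre_mRNA <- function(pairs, annotation, params = filter_params()) {
  n <- nrow(pairs)
  out <- rep(FALSE, n)
  jt <- .junction_table(annotation)
  if (n == 0L || nrow(jt) == 0L) return(out)
  k <- params$min_intron_overlap
  jgr <- GRanges(jt$chrom, IRanges(pmin(jt$jexon, jt$intron_lo),
                                   pmax(jt$jexon, jt$intron_hi)))
  rgr <- GRanges(pairs$rna_chrom, IRanges(pairs$rna_start, pairs$rna_end))
  hits <- suppressWarnings(findOverlaps(rgr, jgr))
  if (length(hits) == 0L) return(out)
  qi <- queryHits(hits); si <- subjectHits(hits)
  s <- pairs$rna_start[qi]; e <- pairs$rna_end[qi]
  strand_ok <- pairs$rna_strand[qi] == jt$strand[si]
  ok <- ifelse(jt$exon_left[si],
               # exon [.., jexon], intron [intron_lo, intron_hi] to the right
               s <= jt$jexon[si] &
                 (pmin(e, jt$intron_hi[si]) - jt$intron_lo[si] + 1L) >= k,
               # intron [intron_lo, intron_hi], exon [jexon, ..] to the right
               e >= jt$jexon[si] &
                 (jt$intron_hi[si] - pmax(s, jt$intron_lo[si]) + 1L) >= k)
  out[unique(qi[strand_ok & ok])] <- TRUE
  out
}

#' Classify RNA-DNA pairs by RNA type
#'
#' Assigns each pair one RNA class with precedence
#' nsaRNA > rRNA > p_pre_mRNA > other:
#' * `nsaRNA` - the RNA end overlaps an exon of a gene in the configured
#'   species list (strand-ignored; the species is recorded, and a pair counts
#'   once regardless of how many annotated copies it overlaps);
#' * `rRNA` - the RNA end overlaps an rRNA gene or maps to the rDNA
#'   pseudo-chromosome;
#' * `p_pre_mRNA` - the exon-intron junction rule of [is_p_pre_mRNA()] fires;
#' * `other` - anything else.
#' Also sets the `nascent` flag via [flag_nascent()].
#'
#' @param pairs pair table.
#' @param annotation `gene_annotation`.
#' @param params [filter_params()].
#' @return `pairs` with `rna_class`, `species` and `nascent` columns.
#' @export
classify_pairs <- function(pairs, annotation, params = filter_params()) {
  pairs <- flag_nascent(pairs, params)
  n <- nrow(pairs)
  cls <- rep("other", n)
  species <- rep(NA_character_, n)
  if (n == 0L) {
    pairs$rna_class <- character(0); pairs$species <- character(0)
    return(pairs[])
  }
  rgr <- GRanges(pairs$rna_chrom, IRanges(pairs$rna_start, pairs$rna_end))

  ex <- merge(annotation$exons,
              annotation$genes[, c("gene_id", "rna_class", "species")],
              by = "gene_id", sort = FALSE, suffixes = c("", ".g"))
  # nsaRNA: exon overlap of species-list genes, species-list order as tiebreak
  nex <- ex[rna_class == "nsaRNA"]
  if (nrow(nex)) {
    nex[, sp_rank := match(species, params$species)]
    setorder(nex, sp_rank)
    h <- suppressWarnings(
      findOverlaps(rgr, GRanges(nex$chrom, IRanges(nex$start, nex$end))))
    if (length(h)) {
      first <- !duplicated(queryHits(h))
      cls[queryHits(h)[first]] <- "nsaRNA"
      species[queryHits(h)[first]] <- nex$species[subjectHits(h)[first]]
    }
  }
  # rRNA: rRNA gene overlap or the rDNA pseudo-chromosome
  rex <- ex[rna_class == "rRNA"]
  is_rrna <- pairs$rna_chrom == params$rdna_chrom
  if (nrow(rex)) {
    h <- suppressWarnings(
      findOverlaps(rgr, GRanges(rex$chrom, IRanges(rex$start, rex$end))))
    is_rrna[unique(queryHits(h))] <- TRUE
  }
  take <- is_rrna & cls == "other"
  cls[take] <- "rRNA"
  species[take] <- NA_character_
  # p-pre-mRNA
  ppre <- is_p_pre_mRNA(pairs, annotation, params)
  multi <- ppre & cls != "other"
  if (any(multi))
    message("classify: ", sum(multi),
            " pair(s) overlapped genes of multiple classes; resolved by precedence")
  cls[ppre & cls == "other"] <- "p_pre_mRNA"
  pairs$rna_class <- cls
  pairs$species <- species
  pairs[]
}

#' Build a 2x2 contingency table from pair predicates
#'
#' Cells: a = both predicates true, b = RNA predicate only, c = DNA predicate
#' only, d = neither; a+b+c+d equals the number of pairs.
#'
#' @param pairs pair table (non-empty).
#' @param rna_predicate,dna_predicate functions mapping the pair table to a
#'   logical vector (e.g. membership tests on `rna_class` or `dna_chrom`).
#' @return A [contingency_table()].
#' @export
contingency_by_class <- function(pairs, rna_predicate, dna_predicate) {
  if (nrow(pairs) == 0L) stop("contingency_by_class: zero pairs")
  r <- rna_predicate(pairs)
  d <- dna_predicate(pairs)
  stopifnot(length(r) == nrow(pairs), length(d) == nrow(pairs))
  contingency_table(sum(r & d), sum(r & !d), sum(!r & d), sum(!r & !d))
}

#' Fraction of interchromosomal pairs
#'
#' @param pairs non-empty pair table.
#' @return proportion of pairs whose RNA and DNA ends lie on different
#'   chromosomes.
#' @export
interchromosomal_fraction <- function(pairs) {
  if (nrow(pairs) == 0L) stop("interchromosomal_fraction: empty input")
  mean(pairs$rna_chrom != pairs$dna_chrom)
}
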