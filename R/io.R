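#' @import GenomicRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<- seqnames
#' @importFrom data.table data.table as.data.table setorder rbindlist fread fwrite :=
NULL

# on-disk dialects are 0-based half-open (BED convention); everything in memory
# is 1-based inclusive, the GRanges convention. Conversion happens only here.

#' Construct a chromosome-sizes table
#'
#' An ordered, named map from chromosome name to length in bp. Order is
#' preserved through every downstream operation and output.
#'
#' @param lengths named numeric/integer vector of chromosome lengths (bp).
#' @return A named integer-valued numeric vector of class `chrom_sizes`.
#' @export
chrom_sizes <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "")) stop("chromosome lengths must be named")
  if (anyDuplicated(nm)) stop("duplicated chromosome names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  len <- as.numeric(lengths)
  if (any(is.na(len)) || any(len < 1) || any(len != floor(len)))
    stop("chromosome lengths must be positive integers")
  structure(stats::setNames(len, nm), class = "chrom_sizes")
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name, length in bp. File order
#' is preserved.
#'
#' @param path path to the file.
#' @return A `chrom_sizes` object.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty chrom.sizes file: ", path)
    return(chrom_sizes(stats::setNames(numeric(0), character(0))))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop("chrom.sizes format error at line ", bad[1L], ": expected two columns")
  nm <- vapply(parts, `[`, "", 1L)
  lenc <- vapply(parts, `[`, "", 2L)
  len <- suppressWarnings(as.numeric(lenc))
  bad <- which(is.na(len) | len < 1 | len != floor(len))
  if (length(bad))
    stop("chrom.sizes format error at line ", bad[1L],
         ": non-integer or non-positive length '", lenc[bad[1L]], "'")
  chrom_sizes(stats::setNames(len, nm))
}

#' Write a chrom.sizes file
#' @param sizes a `chrom_sizes` object.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

# seqlengths-bearing Seqinfo-style vector for building GRanges
.seqlengths <- function(sizes) stats::setNames(as.integer(sizes), names(sizes))

.check_frac_dropped <- function(n_bad, n_total, what, path) {
  # wrong-dialect guard: fail on >1% malformed records, with an absolute floor
  # of five so a stray bad line in a tiny file is dropped, not fatal
  if (n_total > 0 && n_bad / n_total > 0.01 && n_bad >= 5)
    stop(sprintf("%.1f%% of records in '%s' are malformed %s records (> 1%%); wrong file type?",
                 100 * n_bad / n_total, path, what))
  if (n_bad > 0)
    message(sprintf("read %s: dropped %d of %d malformed record(s) from '%s'",
                    what, n_bad, n_total, path))
}

#' Read an RNA-DNA pair file
#'
#' Eleven tab-separated columns: rna_chrom, rna_start, rna_end, dna_chrom,
#' dna_start, dna_end, read_id, score (ignored), rna_strand, dna_strand,
#' annotation (ignored). Coordinates on disk are 0-based half-open; in memory
#' they are 1-based inclusive. Lines starting with `#` are skipped. If the
#' optional classification columns 12-14 (rna_class, species, nascent) are
#' present they are carried along. Records failing validation against `sizes`
#' are dropped and counted; more than 1% malformed records is a hard error.
#'
#' @param path path to the pair file.
#' @param sizes `chrom_sizes` the records must respect.
#' @return A `data.table` with one row per pair: read_id, rna_chrom, rna_start,
#'   rna_end, rna_strand, dna_chrom, dna_start, dna_end, dna_strand
#'   (+ rna_class, species, nascent when present in the file).
#' @export
read_pairs <- function(path, sizes) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    warning("no pair records in ", path)
    return(empty_pairs())
  }
  dt <- fread(text = lines, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(dt) < 11L)
    stop("pair file '", path, "' has ", ncol(dt), " columns; expected >= 11")
  classified <- ncol(dt) >= 14L
  out <- data.table(
    read_id   = dt[[7L]],
    rna_chrom = dt[[1L]],
    rna_start = suppressWarnings(as.numeric(dt[[2L]])) + 1,
    rna_end   = suppressWarnings(as.numeric(dt[[3L]])),
    rna_strand = dt[[9L]],
    dna_chrom = dt[[4L]],
    dna_start = suppressWarnings(as.numeric(dt[[5L]])) + 1,
    dna_end   = suppressWarnings(as.numeric(dt[[6L]])),
    dna_strand = dt[[10L]]
  )
  if (classified) {
    out[, `:=`(rna_class = dt[[12L]], species = dt[[13L]],
               nascent = dt[[14L]] %in% c("TRUE", "true", "1"))]
    out[species == ".", species := NA_character_]
  }
  ok <- .valid_end(out$rna_chrom, out$rna_start, out$rna_end, sizes) &
        .valid_end(out$dna_chrom, out$dna_start, out$dna_end, sizes) &
        out$rna_strand %in% c("+", "-", ".") &
        out$dna_strand %in% c("+", "-", ".") &
        !is.na(out$read_id) & nzchar(out$read_id)
  .check_frac_dropped(sum(!ok), nrow(out), "pair", path)
  out <- out[ok]
  if (anyDuplicated(out$read_id))
    stop("duplicate read_id values in '", path, "'")
  out[]
}

.valid_end <- function(chrom, start, end, sizes) {
  len <- unname(sizes[chrom])
  !is.na(start) & !is.na(end) & !is.na(len) &
    start >= 1 & start <= end & end <= len
}

#' @keywords internal
empty_pairs <- function() {
  data.table(read_id = character(), rna_chrom = character(),
             rna_start = numeric(), rna_end = numeric(), rna_strand = character(),
             dna_chrom = character(), dna_start = numeric(), dna_end = numeric(),
             dna_strand = character())
}

#' Write an RNA-DNA pair file
#'
#' Inverse of [read_pairs()]; emits the 11-column dialect (plus the three
#' classification columns when `pairs` carries them).
#'
#' @param pairs pair table as returned by [read_pairs()] or the simulator.
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  dt <- data.table(
    pairs$rna_chrom, format(pairs$rna_start - 1, scientific = FALSE, trim = TRUE),
    format(pairs$rna_end, scientific = FALSE, trim = TRUE),
    pairs$dna_chrom, format(pairs$dna_start - 1, scientific = FALSE, trim = TRUE),
    format(pairs$dna_end, scientific = FALSE, trim = TRUE),
    pairs$read_id, ".", pairs$rna_strand, pairs$dna_strand, "."
  )
  if (!is.null(pairs$rna_class)) {
    sp <- pairs$species
    sp[is.na(sp)] <- "."
    dt <- cbind(dt, data.table(pairs$rna_class, sp,
                               ifelse(isTRUE_vec(pairs$nascent), "TRUE", "FALSE")))
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read a BED3+ file into a peak set
#'
#' Columns: chrom, start, end, optional name, optional read_count. 0-based
#' half-open on disk. Empty (start >= end) or out-of-bounds intervals are
#' dropped and counted, with the same 1% hard-error rule as [read_pairs()].
#'
#' @param path path to the BED file.
#' @param sizes `chrom_sizes` used for bounds validation.
#' @return A `GRanges`, sorted as in the file, with `name`/`read_count`
#'   metadata columns when present.
#' @export
read_bed <- function(path, sizes) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)]
  if (length(lines) == 0L) {
    warning("no intervals in ", path)
    return(GRanges(seqlengths = .seqlengths(sizes)))
  }
  dt <- fread(text = lines, header = FALSE, sep = "\t", colClasses = "character")
  start <- suppressWarnings(as.numeric(dt[[2L]])) + 1
  end <- suppressWarnings(as.numeric(dt[[3L]]))
  ok <- .valid_end(dt[[1L]], start, end, sizes)
  .check_frac_dropped(sum(!ok), nrow(dt), "BED", path)
  gr <- GRanges(dt[[1L]][ok], IRanges(start[ok], end[ok]),
                seqlengths = .seqlengths(sizes))
  if (ncol(dt) >= 4L) mcols(gr)$name <- dt[[4L]][ok]
  if (ncol(dt) >= 5L) mcols(gr)$read_count <- as.numeric(dt[[5L]][ok])
  gr
}

#' Write a peak set as BED3+
#'
#' @param peaks a `GRanges`; `name` and `read_count` metadata columns become
#'   BED columns 4 and 5.
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  cols <- list(as.character(seqnames(peaks)),
               format(start(peaks) - 1, scientific = FALSE, trim = TRUE),
               format(end(peaks), scientific = FALSE, trim = TRUE))
  if (!is.null(mcols(peaks)$name)) {
    cols <- c(cols, list(mcols(peaks)$name))
    if (!is.null(mcols(peaks)$read_count))
      cols <- c(cols, list(format(mcols(peaks)$read_count, scientific = FALSE, trim = TRUE)))
  }
  fwrite(as.data.table(cols), path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene annotation (GTF subset)
#'
#' Expects `gene` and `exon` features carrying `gene_id`, `transcript_id`
#' (exons), `rna_class` and, for nsaRNA genes, `species` attributes. GTF is
#' 1-based inclusive, matching the in-memory convention. An exon whose gene has
#' no `gene` line is a format error; an unknown `rna_class` token falls back to
#' `"other"` with a warning.
#'
#' @param path path to the GTF file.
#' @param species_list valid nsaRNA species names.
#' @return A `gene_annotation` object: list of `genes` and `exons` data.tables.
#' @export
read_annotation <- function(path,
                            species_list = nsa_species()) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- mcols(gr)
  typ <- as.character(md$type)
  if (is.null(md$gene_id)) stop("GTF lacks gene_id attributes: ", path)
  rna_class <- if (is.null(md$rna_class)) rep(NA_character_, length(gr)) else md$rna_class
  species <- if (is.null(md$species)) rep(NA_character_, length(gr)) else md$species

  gidx <- typ == "gene"
  eidx <- typ == "exon"
  genes <- data.table(
    gene_id = md$gene_id[gidx],
    rna_class = rna_class[gidx],
    species = species[gidx],
    chrom = as.character(seqnames(gr))[gidx],
    start = start(gr)[gidx], end = end(gr)[gidx],
    strand = as.character(strand(gr))[gidx]
  )
  unknown <- !genes$rna_class %in% c("nsaRNA", "rRNA", "coding", "other")
  if (any(unknown)) {
    warning("unknown rna_class for gene(s) ",
            paste(utils::head(genes$gene_id[unknown], 5), collapse = ", "),
            "; classified as 'other'")
    genes[unknown, rna_class := "other"]
  }
  badsp <- genes$rna_class == "nsaRNA" & !genes$species %in% species_list
  if (any(badsp))
    stop("nsaRNA gene(s) with species outside the configured list: ",
         paste(genes$gene_id[badsp], collapse = ", "))
  exons <- data.table(
    gene_id = md$gene_id[eidx],
    transcript_id = md$transcript_id[eidx],
    chrom = as.character(seqnames(gr))[eidx],
    start = start(gr)[eidx], end = end(gr)[eidx],
    strand = as.character(strand(gr))[eidx]
  )
  orphan <- !exons$gene_id %in% genes$gene_id
  if (any(orphan))
    stop("exon(s) without a parent gene record: ",
         paste(unique(exons$gene_id[orphan]), collapse = ", "))
  gene_annotation(genes, exons)
}

#' Construct a gene annotation
#'
#' @param genes data.table: gene_id, rna_class, species, chrom, start, end, strand.
#' @param exons data.table: gene_id, transcript_id, chrom, start, end, strand.
#' @return A `gene_annotation` object. Exons of each transcript are sorted in
#'   genomic order and must be non-overlapping.
#' @export
gene_annotation <- function(genes, exons) {
  genes <- as.data.table(genes)
  exons <- as.data.table(exons)
  setorder(exons, gene_id, transcript_id, start)
  if (nrow(exons)) {
    ov <- exons[, any(start[-1L] <= end[-.N]), by = transcript_id]$V1
    if (any(ov)) stop("overlapping exons within a transcript")
  }
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,", nrow(x$exons), "exons;",
      "classes:", paste(sprintf("%s=%d", names(table(x$genes$rna_class)),
                                table(x$genes$rna_class)), collapse = " "), "\n")
  invisible(x)
}

#' Write a gene annotation as GTF
#' @param annotation a `gene_annotation`.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  attr_g <- sprintf('gene_id "%s"; rna_class "%s";%s', g$gene_id, g$rna_class,
                    ifelse(is.na(g$species), "", sprintf(' species "%s";', g$species)))
  gl <- sprintf("%s\tspecklemap\tgene\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, as.integer(g$start), as.integer(g$end), g$strand, attr_g)
  e <- merge(annotation$exons, g[, c("gene_id", "rna_class", "species")],
             by = "gene_id", sort = FALSE)
  attr_e <- sprintf('gene_id "%s"; transcript_id "%s"; rna_class "%s";%s',
                    e$gene_id, e$transcript_id, e$rna_class,
                    ifelse(is.na(e$species), "", sprintf(' species "%s";', e$species)))
  el <- sprintf("%s\tspecklemap\texon\t%d\t%d\t.\t%s\t.\t%s",
                e$chrom, as.integer(e$start), as.integer(e$end), e$strand, attr_e)
  # each gene line followed by its exon lines, in gene-table order: deterministic
  rank <- c(match(g$gene_id, g$gene_id), match(e$gene_id, g$gene_id))
  sub <- c(rep(0L, nrow(g)), rep(1L, nrow(e)))
  pos <- c(rep(0L, nrow(g)), as.integer(e$start))
  writeLines(c(gl, el)[order(rank, sub, pos)], path)
  invisible(path)
}
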