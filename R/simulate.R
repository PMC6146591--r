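#' Simulation configuration
#'
#' Defines the synthetic study conditions: a toy genome of four autosome
#' stand-ins plus the rDNA repeating unit, planted speckle-proximal domains,
#' per-class pair counts, and imaging parameters. Defaults emulate the
#' landmark fractions of the HEK MARGI analysis: ~15,000 nsaRNA pairs with
#' 72% of non-nascent DNA ends inside planted domains ("speckled"), a 93%
#' interchromosomal rate for posttranscriptional pre-mRNA pairs, a 404-fold
#' rRNA-to-rDNA odds increase, and 1-3 FISH spots / 20-35 SC35 clusters per
#' nucleus. The "diffuse" scenario plants no domains and draws DNA ends
#' uniformly - the sporadic-interaction contrast.
#'
#' @param scenario `"speckled"` (stable interactions, planted domains) or
#'   `"diffuse"` (sporadic, uniform).
#' @param chroms named lengths of the autosome stand-ins.
#' @param rdna_chrom,rdna_length name and length of the rDNA repeating-unit
#'   pseudo-chromosome.
#' @param n_planted_peaks number of planted domains (speckled only).
#' @param peak_length_range planted-domain length bounds (bp); lengths are
#'   drawn log-uniformly, then rescaled so the domains cover
#'   `peak_genome_fraction` of the autosomal genome.
#' @param peak_genome_fraction fraction of the autosomal genome covered by
#'   planted domains.
#' @param peak_min_separation minimum gap between planted domains (bp).
#' @param n_nsarna,n_premrna,n_rrna,n_other per-class pair counts.
#' @param in_peak_prob probability that a non-nascent nsaRNA / pre-mRNA DNA
#'   end falls inside a planted domain (speckled).
#' @param interchromosomal_prob probability that a non-nascent pre-mRNA DNA
#'   end targets a different chromosome than its gene.
#' @param nascent_fraction fraction of pairs per autosomal class whose DNA
#'   end is planted within the nascent distance of the RNA end.
#' @param rrna_rdna_prob probability that an rRNA DNA end maps to rDNA.
#' @param rdna_odds planted odds ratio of the rRNA-vs-rest x rDNA-vs-genome
#'   contingency; sets the background rDNA rate of the non-rRNA classes.
#' @param background_sdlog log-SD of the shared per-megabase background
#'   weight field (speckled); 0 gives a uniform background. The shared field
#'   makes the nsaRNA and pre-mRNA density profiles co-vary genome-wide, as
#'   the two signals do in real nuclei.
#' @param background_block block width (bp) of the background field.
#' @param read_len length (bp) of each RNA/DNA end interval.
#' @param nascent_distance,min_intron_overlap filter thresholds the truth
#'   labels are generated against.
#' @param species nsaRNA species list; one gene is planted per species.
#' @param n_coding number of multi-exon coding genes.
#' @param boundary_probes append deterministic boundary-probe pairs at gaps
#'   1999/2000/2001 nt and intron overlaps of `min_intron_overlap` and
#'   `min_intron_overlap - 1` nt.
#' @param imaging list of imaging parameters (see Details in the package
#'   vignette): stack `dim`, nucleus `semi_axes`, cluster/spot count ranges,
#'   blob sigmas and amplitudes, background level and noise SD, placement
#'   separations, `cells_per_image`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(scenario = c("speckled", "diffuse"),
                       chroms = c(chrA = 60e6, chrB = 60e6, chrC = 55e6, chrD = 55e6),
                       rdna_chrom = "rDNA", rdna_length = 43000,
                       n_planted_peaks = 10L,
                       peak_length_range = c(1e5, 1.3e7),
                       peak_genome_fraction = 0.09,
                       peak_min_separation = 1e6,
                       n_nsarna = 15000L, n_premrna = 15000L,
                       n_rrna = 2000L, n_other = 5000L,
                       in_peak_prob = 0.72,
                       interchromosomal_prob = 0.93,
                       nascent_fraction = 0.1,
                       rrna_rdna_prob = 0.5, rdna_odds = 404,
                       background_sdlog = 0.8, background_block = 1e6,
                       read_len = 30L,
                       nascent_distance = 2000L, min_intron_overlap = 10L,
                       species = nsa_species(), n_coding = 40L,
                       boundary_probes = TRUE,
                       imaging = list()) {
  scenario <- match.arg(scenario)
  img <- utils::modifyList(list(
    dim = c(y = 80L, x = 80L, z = 16L),
    semi_axes = c(34, 34, 6.5),
    n_clusters = c(20L, 35L), n_spots = c(1L, 3L),
    cluster_sigma = 1.2, spot_sigma = 1.0,
    cluster_amp = 120, spot_amp = 150,
    background = 10, noise_sd = 2,
    min_cluster_sep = 6, min_spot_sep = 6,
    coloc_offset = 1, noncoloc_min_dist = 8,
    nucleus_margin = 3, cells_per_image = 8L), imaging)
  probs <- c(in_peak_prob, interchromosomal_prob, nascent_fraction, rrna_rdna_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(c(n_nsarna, n_premrna, n_rrna, n_other) >= 0))
  structure(list(
    scenario = scenario, chroms = chroms, rdna_chrom = rdna_chrom,
    rdna_length = rdna_length, n_planted_peaks = n_planted_peaks,
    peak_length_range = peak_length_range,
    peak_genome_fraction = peak_genome_fraction,
    peak_min_separation = peak_min_separation,
    n_nsarna = n_nsarna, n_premrna = n_premrna, n_rrna = n_rrna,
    n_other = n_other, in_peak_prob = in_peak_prob,
    interchromosomal_prob = interchromosomal_prob,
    nascent_fraction = nascent_fraction, rrna_rdna_prob = rrna_rdna_prob,
    rdna_odds = rdna_odds, background_sdlog = background_sdlog,
    background_block = background_block, read_len = read_len,
    nascent_distance = nascent_distance,
    min_intron_overlap = min_intron_overlap, species = species,
    n_coding = n_coding, boundary_probes = boundary_probes,
    imaging = img), class = "sim_config")
}

# plausible gene lengths (bp) for the nsaRNA species loci
.species_lengths <- c(U1 = 164, U2 = 188, U4 = 145, U4atac = 130, U5 = 116,
                      U6 = 107, U6atac = 125, U11 = 135, U12 = 150,
                      `7SK` = 331, Malat1 = 8700)

#' Simulate a toy annotated genome
#'
#' Plants one single-exon gene per configured nsaRNA species, `n_coding`
#' multi-exon coding genes (introns far exceed the junction-rule threshold),
#' and an rRNA gene on the rDNA pseudo-chromosome. Placement is uniform with
#' rejection against overlap; byte-identical output under a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `annotation` (a `gene_annotation`) and `sizes`
#'   (`chrom_sizes` including the rDNA unit).
#' @export
simulate_annotation <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  sizes <- chrom_sizes(c(config$chroms,
                         stats::setNames(config$rdna_length, config$rdna_chrom)))
  autos <- names(config$chroms)
  margin <- 10000L
  placed <- data.table(chrom = character(), start = numeric(), end = numeric())
  place_gene <- function(chrom, len) {
    lo <- margin + 1; hi <- config$chroms[[chrom]] - margin - len
    if (hi < lo) stop("chromosome ", chrom, " too short for a gene of ", len, " bp")
    for (att in 1:1000) {
      s <- floor(stats::runif(1, lo, hi + 1))
      prev <- placed[chrom, on = "chrom", nomatch = NULL]
      if (nrow(prev) == 0L || all(s + len - 1 + 5000 < prev$start |
                                  s > prev$end + 5000)) {
        placed <<- rbind(placed, data.table(chrom = chrom, start = s,
                                            end = s + len - 1))
        return(c(s, s + len - 1))
      }
    }
    stop("could not place gene without overlap")
  }
  genes <- list(); exons <- list()
  # nsaRNA species loci, round-robin over autosomes
  for (i in seq_along(config$species)) {
    sp <- config$species[i]
    len <- unname(.species_lengths[sp])
    if (is.na(len)) len <- 200
    chrom <- autos[(i - 1L) %% length(autos) + 1L]
    pos <- place_gene(chrom, len)
    strand <- sample(c("+", "-"), 1L)
    gid <- paste0("nsa_", sp)
    genes[[length(genes) + 1L]] <- data.table(
      gene_id = gid, rna_class = "nsaRNA", species = sp, chrom = chrom,
      start = pos[1], end = pos[2], strand = strand)
    exons[[length(exons) + 1L]] <- data.table(
      gene_id = gid, transcript_id = paste0(gid, ".t1"), chrom = chrom,
      start = pos[1], end = pos[2], strand = strand)
  }
  # multi-exon coding genes
  for (i in seq_len(config$n_coding)) {
    n_ex <- sample(5:8, 1L)
    ex_len <- sample(120:300, n_ex, replace = TRUE)
    in_len <- sample(800:4000, n_ex - 1L, replace = TRUE)
    stopifnot(all(in_len >= 2L * config$min_intron_overlap))
    glen <- sum(ex_len) + sum(in_len)
    chrom <- autos[(i - 1L) %% length(autos) + 1L]
    pos <- place_gene(chrom, glen)
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene_%03d", i)
    es <- pos[1] + c(0, cumsum(ex_len[-n_ex] + in_len))
    genes[[length(genes) + 1L]] <- data.table(
      gene_id = gid, rna_class = "coding", species = NA_character_,
      chrom = chrom, start = pos[1], end = pos[2], strand = strand)
    exons[[length(exons) + 1L]] <- data.table(
      gene_id = gid, transcript_id = paste0(gid, ".t1"), chrom = chrom,
      start = es, end = es + ex_len - 1L, strand = strand)
  }
  # rRNA gene on the rDNA repeating unit
  genes[[length(genes) + 1L]] <- data.table(
    gene_id = "rRNA_45S", rna_class = "rRNA", species = NA_character_,
    chrom = config$rdna_chrom, start = 2001, end = 15000, strand = "+")
  exons[[length(exons) + 1L]] <- data.table(
    gene_id = "rRNA_45S", transcript_id = "rRNA_45S.t1",
    chrom = config$rdna_chrom, start = 2001, end = 15000, strand = "+")
  list(annotation = gene_annotation(rbindlist(genes), rbindlist(exons)),
       sizes = sizes)
}

# planted domains: log-uniform lengths rescaled to a fixed genome fraction,
# placed with rejection to keep a minimum separation
.plant_peaks <- function(config) {
  n <- config$n_planted_peaks
  if (config$scenario == "diffuse" || n == 0L)
    return(GRanges(seqlengths = .seqlengths(
      chrom_sizes(c(config$chroms,
                    stats::setNames(config$rdna_length, config$rdna_chrom))))))
  lo <- config$peak_length_range[1]; hi <- config$peak_length_range[2]
  L <- exp(stats::runif(n, log(lo), log(hi)))
  L <- round(pmin(pmax(L * config$peak_genome_fraction * sum(config$chroms) / sum(L),
                       lo), hi))
  chroms <- config$chroms
  placed <- data.table(chrom = character(), start = numeric(), end = numeric())
  sep <- config$peak_min_separation
  for (i in order(-L)) {   # largest first eases placement
    ok <- FALSE
    for (att in 1:1000) {
      ch <- sample(names(chroms), 1L, prob = chroms)
      if (chroms[[ch]] < L[i] + 2) next
      s <- floor(stats::runif(1, 1, chroms[[ch]] - L[i] + 1))
      prev <- placed[chrom == ch]
      if (nrow(prev) == 0L ||
          all(s + L[i] - 1 + sep < prev$start | s > prev$end + sep)) {
        placed <- rbind(placed, data.table(chrom = ch, start = s, end = s + L[i] - 1))
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place planted peaks without overlap")
  }
  setorder(placed, chrom, start)
  gr <- GRanges(placed$chrom, IRanges(placed$start, placed$end),
                seqlengths = .seqlengths(chrom_sizes(
                  c(config$chroms,
                    stats::setNames(config$rdna_length, config$rdna_chrom)))))
  mcols(gr)$name <- sprintf("planted_%02d", seq_along(gr))
  gr
}

# shared background weight field: per-block log-normal weights (mean 1)
.background_field <- function(config) {
  blocks <- lapply(names(config$chroms), function(ch) {
    len <- config$chroms[[ch]]
    s <- seq(1, len, by = config$background_block)
    data.table(chrom = ch, start = s, end = pmin(s + config$background_block - 1, len))
  })
  bf <- rbindlist(blocks)
  sdlog <- if (config$scenario == "speckled") config$background_sdlog else 0
  bf[, weight := if (sdlog > 0) stats::rlnorm(.N, -sdlog^2 / 2, sdlog) else 1]
  bf[, mass := weight * (end - start + 1)]
  bf
}

#' Simulate RNA-DNA pairs with planted truth
#'
#' Draws RNA ends inside class-appropriate genes (pre-mRNA RNA ends straddle
#' an exon-intron junction with at least `min_intron_overlap` intronic nt;
#' "other" RNA ends are intergenic), then places DNA ends according to the
#' scenario: nascent pairs within the nascent distance of the RNA end,
#' speckled nsaRNA/pre-mRNA ends inside planted domains with probability
#' `in_peak_prob`, everything else on the (optionally weighted) background -
#' which excludes the planted domains, so the planted in-domain fraction is
#' exact. Truth labels are consistent with the emitted records by
#' construction: intended non-nascent placements are re-drawn until they obey
#' the distance rule, and intergenic placements until they overlap no gene.
#'
#' @param config a [sim_config()].
#' @param annotation,sizes from [simulate_annotation()] (same config).
#' @param seed integer seed.
#' @return list with `pairs` (pair table), `truth` (read_id, rna_class,
#'   species, nascent, in_peak), `peaks` (planted domains, `GRanges`) and
#'   `background` (the weight field).
#' @export
simulate_pairs <- function(config, annotation, sizes, seed = 1L) {
  set.seed(seed)
  rl <- config$read_len
  nd <- config$nascent_distance
  nf <- config$nascent_fraction
  ipp <- if (config$scenario == "speckled") config$in_peak_prob else 0
  peaks <- .plant_peaks(config)
  bf <- .background_field(config)
  genes <- annotation$genes
  gene_gr <- GRanges(genes$chrom, IRanges(genes$start, genes$end))

  # background rDNA rate reproducing the configured odds ratio in expectation
  odds_r <- config$rrna_rdna_prob / (1 - config$rrna_rdna_prob)
  qp <- (odds_r / config$rdna_odds) / (1 + odds_r / config$rdna_odds)

  draw_bg <- function(n, chrom = NULL) {
    # start positions of background DNA ends, outside planted domains
    if (n == 0L) return(data.table(chrom = character(), start = numeric()))
    pool <- if (is.null(chrom)) bf else bf[chrom, on = "chrom"]
    out_ch <- character(n); out_s <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      ri <- sample.int(nrow(pool), length(todo), replace = TRUE, prob = pool$mass)
      s <- floor(stats::runif(length(todo), pool$start[ri],
                              pmax(pool$start[ri] + 1, pool$end[ri] - rl + 1)))
      mid <- s + floor((rl - 1) / 2)
      bad <- countOverlaps(GRanges(pool$chrom[ri], IRanges(mid, mid)), peaks) > 0L
      out_ch[todo[!bad]] <- pool$chrom[ri[!bad]]
      out_s[todo[!bad]] <- s[!bad]
      todo <- todo[bad]
    }
    data.table(chrom = out_ch, start = out_s)
  }

  gap_to <- function(rs, re, ds, de, same) {
    ifelse(same, pmax(0, pmax(rs, ds) - pmin(re, de) - 1), NA_real_)
  }

  place_nascent <- function(rchrom, rs, re) {
    n <- length(rs)
    gap <- sample.int(nd + 1L, n, replace = TRUE) - 1L
    side <- sample(c(-1L, 1L), n, replace = TRUE)
    ds <- ifelse(side == 1L, re + gap + 1, rs - gap - 1 - rl + 1)
    clen <- unname(sizes[rchrom])
    flip <- ds < 1 | ds + rl - 1 > clen
    ds[flip] <- ifelse(side[flip] == 1L,
                       rs[flip] - gap[flip] - 1 - rl + 1,
                       re[flip] + gap[flip] + 1)
    data.table(chrom = rchrom, start = ds)
  }

  # re-draw same-chromosome placements violating the non-nascent guarantee
  enforce_far <- function(dt, rchrom, rs, re, redraw) {
    for (it in 1:100) {
      gap <- gap_to(rs, re, dt$start, dt$start + rl - 1, rchrom == dt$chrom)
      bad <- which(!is.na(gap) & gap <= nd)
      if (!length(bad)) return(dt)
      dt[bad, c("chrom", "start") := redraw(bad)]
    }
    stop("could not place non-nascent DNA ends away from their RNA ends")
  }

  peak_draw <- function(n, chrom = NULL) {
    pk <- if (is.null(chrom)) peaks else peaks[as.character(seqnames(peaks)) == chrom]
    pi <- sample.int(length(pk), n, replace = TRUE, prob = width(pk))
    s <- floor(stats::runif(n, start(pk)[pi], end(pk)[pi] - rl + 1))
    data.table(chrom = as.character(seqnames(pk))[pi], start = s)
  }

  out <- list(); truth <- list()
  add <- function(cls, species, rchrom, rs, rstrand, dchrom, dstart, nascent) {
    out[[length(out) + 1L]] <<- data.table(
      rna_chrom = rchrom, rna_start = rs, rna_end = rs + rl - 1,
      rna_strand = rstrand, dna_chrom = dchrom, dna_start = dstart,
      dna_end = dstart + rl - 1,
      dna_strand = sample(c("+", "-"), length(rs), replace = TRUE))
    truth[[length(truth) + 1L]] <<- data.table(
      rna_class = cls, species = species, nascent = nascent)
  }

  ## nsaRNA pairs ------------------------------------------------------------
  n1 <- config$n_nsarna
  if (n1 > 0L) {
    sg <- genes[rna_class == "nsaRNA"]
    gi <- sample.int(nrow(sg), n1, replace = TRUE)
    rs <- floor(stats::runif(n1, sg$start[gi], sg$end[gi] - rl + 2))
    rchrom <- sg$chrom[gi]
    nasc <- stats::runif(n1) < nf
    inpk <- !nasc & stats::runif(n1) < ipp
    p_rdna <- if (1 - ipp > 0) qp / ((1 - nf) * (1 - ipp)) else 0
    rdna <- !nasc & !inpk & stats::runif(n1) < p_rdna
    bg <- !nasc & !inpk & !rdna
    d <- data.table(chrom = rep(NA_character_, n1), start = rep(NA_real_, n1))
    if (any(nasc)) d[which(nasc), c("chrom", "start") :=
                       place_nascent(rchrom[nasc], rs[nasc], rs[nasc] + rl - 1)]
    if (any(inpk)) {
      d[which(inpk), c("chrom", "start") := peak_draw(sum(inpk))]
      wi <- which(inpk)
      d[wi, c("chrom", "start") :=
          enforce_far(d[wi], rchrom[wi], rs[wi], rs[wi] + rl - 1,
                      function(bad) peak_draw(length(bad)))]
    }
    if (any(rdna)) d[which(rdna), `:=`(chrom = config$rdna_chrom,
      start = floor(stats::runif(sum(rdna), 1, config$rdna_length - rl + 1)))]
    if (any(bg)) {
      wi <- which(bg)
      d[wi, c("chrom", "start") := draw_bg(length(wi))]
      d[wi, c("chrom", "start") :=
          enforce_far(d[wi], rchrom[wi], rs[wi], rs[wi] + rl - 1,
                      function(bad) draw_bg(length(bad)))]
    }
    add("nsaRNA", sg$species[gi], rchrom, rs, sg$strand[gi], d$chrom, d$start, nasc)
  }

  ## posttranscriptional pre-mRNA pairs --------------------------------------
  n2 <- config$n_premrna
  jt <- .junction_table(annotation)
  if (n2 > 0L) {
    stopifnot(nrow(jt) > 0L)
    ji <- sample.int(nrow(jt), n2, replace = TRUE)
    iov <- sample(seq(config$min_intron_overlap, rl - 1L), n2, replace = TRUE)
    rs <- ifelse(jt$exon_left[ji],
                 jt$jexon[ji] - (rl - iov) + 1L,   # exon then intron (genomic)
                 jt$jexon[ji] - iov)               # intron then exon
    rchrom <- jt$chrom[ji]
    rstrand <- jt$strand[ji]
    nasc <- stats::runif(n2) < nf
    rdna <- !nasc & stats::runif(n2) < qp / (1 - nf)
    inter <- !nasc & !rdna & stats::runif(n2) < config$interchromosomal_prob
    same <- !nasc & !rdna & !inter
    inpk <- (inter | same) & stats::runif(n2) < ipp
    d <- data.table(chrom = rep(NA_character_, n2), start = rep(NA_real_, n2))
    if (any(nasc)) d[which(nasc), c("chrom", "start") :=
                       place_nascent(rchrom[nasc], rs[nasc], rs[nasc] + rl - 1)]
    if (any(rdna)) d[which(rdna), `:=`(chrom = config$rdna_chrom,
      start = floor(stats::runif(sum(rdna), 1, config$rdna_length - rl + 1)))]
    pk_ch <- unique(as.character(seqnames(peaks)))
    wi <- which(inter | same)
    if (length(wi)) {
      # target chromosome honouring the interchromosomal draw; interchromosomal
      # targets are drawn length-proportionally among the other autosomes
      autos <- names(config$chroms)
      tch <- rchrom[wi]
      iw <- inter[wi]
      if (any(iw)) {
        # draw from all autosomes, redraw collisions with the gene chromosome
        todo <- which(iw)
        while (length(todo)) {
          cand <- sample(autos, length(todo), replace = TRUE, prob = config$chroms)
          ok <- cand != rchrom[wi[todo]]
          tch[todo[ok]] <- cand[ok]
          todo <- todo[!ok]
        }
      }
      use_pk <- inpk[wi] & tch %in% pk_ch
      draw_for <- function(sub_idx) {
        # sub_idx indexes wi; vectorised per target chromosome
        res <- data.table(chrom = character(length(sub_idx)),
                          start = numeric(length(sub_idx)))
        for (ch in unique(tch[sub_idx])) {
          here <- tch[sub_idx] == ch
          pk_here <- use_pk[sub_idx][here]
          if (any(pk_here))
            res[which(here)[pk_here], c("chrom", "start") :=
                  peak_draw(sum(pk_here), chrom = ch)]
          if (any(!pk_here))
            res[which(here)[!pk_here], c("chrom", "start") :=
                  draw_bg(sum(!pk_here), chrom = ch)]
        }
        res
      }
      d[wi, c("chrom", "start") := draw_for(seq_along(wi))]
      d[wi, c("chrom", "start") :=
          enforce_far(d[wi], rchrom[wi], rs[wi], rs[wi] + rl - 1, draw_for)]
    }
    add("p_pre_mRNA", rep(NA_character_, n2), rchrom, rs, rstrand,
        d$chrom, d$start, nasc)
  }

  ## rRNA pairs ---------------------------------------------------------------
  n3 <- config$n_rrna
  if (n3 > 0L) {
    rg <- genes[rna_class == "rRNA"][1L]
    rs <- floor(stats::runif(n3, rg$start, rg$end - rl + 2))
    rdna <- stats::runif(n3) < config$rrna_rdna_prob
    d <- data.table(chrom = rep(NA_character_, n3), start = rep(NA_real_, n3))
    if (any(rdna)) d[which(rdna), `:=`(chrom = config$rdna_chrom,
      start = floor(stats::runif(sum(rdna), 1, config$rdna_length - rl + 1)))]
    if (any(!rdna)) d[which(!rdna), c("chrom", "start") := draw_bg(sum(!rdna))]
    # nascent truth for rDNA-rDNA pairs follows from the coordinates
    nasc <- !is.na(gap_to(rs, rs + rl - 1, d$start, d$start + rl - 1,
                          d$chrom == rg$chrom)) &
            gap_to(rs, rs + rl - 1, d$start, d$start + rl - 1,
                   d$chrom == rg$chrom) <= nd
    add("rRNA", rep(NA_character_, n3), rep(rg$chrom, n3), rs,
        rep(rg$strand, n3), d$chrom, d$start, nasc)
  }

  ## other (intergenic) pairs --------------------------------------------------
  n4 <- config$n_other
  if (n4 > 0L) {
    draw_intergenic <- function(n) {
      res <- data.table(chrom = character(n), start = numeric(n))
      todo <- seq_len(n)
      while (length(todo)) {
        cand <- draw_bg(length(todo))
        margin_ok <- cand$start > 5000 &
          cand$start + rl - 1 < unname(sizes[cand$chrom]) - 5000
        hit <- countOverlaps(GRanges(cand$chrom, IRanges(cand$start, cand$start + rl - 1)),
                             gene_gr) > 0L
        keep <- margin_ok & !hit
        res[todo[keep], c("chrom", "start") := cand[keep]]
        todo <- todo[!keep]
      }
      res
    }
    r <- draw_intergenic(n4)
    rs <- r$start; rchrom <- r$chrom
    rstrand <- sample(c("+", "-"), n4, replace = TRUE)
    nasc <- stats::runif(n4) < nf
    rdna <- !nasc & stats::runif(n4) < qp / (1 - nf)
    bg <- !nasc & !rdna
    d <- data.table(chrom = rep(NA_character_, n4), start = rep(NA_real_, n4))
    if (any(nasc)) d[which(nasc), c("chrom", "start") :=
                       place_nascent(rchrom[nasc], rs[nasc], rs[nasc] + rl - 1)]
    if (any(rdna)) d[which(rdna), `:=`(chrom = config$rdna_chrom,
      start = floor(stats::runif(sum(rdna), 1, config$rdna_length - rl + 1)))]
    if (any(bg)) {
      wi <- which(bg)
      d[wi, c("chrom", "start") := draw_bg(length(wi))]
      d[wi, c("chrom", "start") :=
          enforce_far(d[wi], rchrom[wi], rs[wi], rs[wi] + rl - 1,
                      function(bad) draw_bg(length(bad)))]
    }
    add("other", rep(NA_character_, n4), rchrom, rs, rstrand, d$chrom, d$start, nasc)
  }

  ## deterministic boundary probes ---------------------------------------------
  if (isTRUE(config$boundary_probes)) {
    sg <- genes[rna_class == "nsaRNA"][1L]
    for (g in c(nd - 1L, nd, nd + 1L)) {
      rs <- sg$start
      ds <- rs + rl - 1 + g + 1
      add("nsaRNA", sg$species, sg$chrom, rs, sg$strand, sg$chrom, ds, g <= nd)
    }
    j1 <- jt[exon_left == TRUE][1L]
    for (iov in c(config$min_intron_overlap, config$min_intron_overlap - 1L)) {
      rs <- j1$jexon - (rl - iov) + 1L
      other_ch <- setdiff(names(config$chroms), j1$chrom)[1L]
      dd <- draw_bg(1L, chrom = other_ch)
      cls <- if (iov >= config$min_intron_overlap) "p_pre_mRNA" else "other"
      add(cls, NA_character_, j1$chrom, rs, j1$strand, dd$chrom, dd$start, FALSE)
    }
  }

  n_probe <- if (isTRUE(config$boundary_probes)) 5L else 0L
  pairs <- rbindlist(out)
  pairs[, read_id := sprintf("r%06d", .I)]
  data.table::setcolorder(pairs, c("read_id", "rna_chrom", "rna_start", "rna_end",
                                   "rna_strand", "dna_chrom", "dna_start",
                                   "dna_end", "dna_strand"))
  truth <- rbindlist(truth)
  truth[, read_id := pairs$read_id]
  truth[, probe := FALSE]
  if (n_probe > 0L) truth[(.N - n_probe + 1L):.N, probe := TRUE]
  mid <- floor((pairs$dna_start + pairs$dna_end) / 2)
  truth[, in_peak := countOverlaps(GRanges(pairs$dna_chrom, IRanges(mid, mid)),
                                   peaks) > 0L]
  data.table::setcolorder(truth, c("read_id", "rna_class", "species",
                                   "nascent", "in_peak", "probe"))
  list(pairs = pairs[], truth = truth[], peaks = peaks, background = bf)
}

#' Recall and precision of called peaks against planted truth
#'
#' A planted domain counts as recovered when some called peak reaches a
#' Jaccard index (intersection over union of bp) of at least `min_jaccard`
#' with it; precision is the symmetric statement for called peaks.
#'
#' @param called,truth_peaks `GRanges`.
#' @param min_jaccard Jaccard threshold.
#' @return list with `recall` and `precision`.
#' @export
evaluate_peaks <- function(called, truth_peaks, min_jaccard = 0.5) {
  if (length(truth_peaks) == 0L)
    return(list(recall = NA_real_, precision = if (length(called)) 0 else NA_real_))
  if (length(called) == 0L) return(list(recall = 0, precision = NA_real_))
  h <- findOverlaps(truth_peaks, called, ignore.strand = TRUE)
  j <- rep(0, length(h))
  if (length(h)) {
    inter <- width(pintersect(granges(truth_peaks)[queryHits(h)],
                              granges(called)[subjectHits(h)]))
    uni <- width(truth_peaks)[queryHits(h)] + width(called)[subjectHits(h)] - inter
    j <- inter / uni
  }
  rec_hit <- tapply(j, queryHits(h), max)
  prec_hit <- tapply(j, subjectHits(h), max)
  recall <- sum(rec_hit >= min_jaccard) / length(truth_peaks)
  precision <- sum(prec_hit >= min_jaccard) / length(called)
  list(recall = recall, precision = precision)
}
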