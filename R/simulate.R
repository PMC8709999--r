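## Spike-in simulator: synthetic genomes with multi-exon gene models,
## in-silico cloning of spliced cDNAs into a vector backbone, read simulation
## at configurable length/layout/coverage, and analytic construction of the
## contaminated alignment (soft clips computed from the known junctions)
## with a read-level truth table. Fully deterministic given a seed; no
## external aligner involved.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## shortest genomic anchor the emulated aligner will place
MIN_ANCHOR <- 20L

#' Simulate a synthetic genome with a multi-exon gene model
#'
#' Random contigs carrying `n_genes` genes laid out with intergenic gaps;
#' each gene has one transcript with 3-6 exons of 150-400 bp separated by
#' 300-1200 bp introns (defaults emulate compact exome-like loci). Strands
#' alternate so both orientations are represented in the boundary universe.
#'
#' @param n_genes number of genes (default 48, half on each strand).
#' @param n_contigs contigs to distribute genes over (default 2).
#' @param seed RNG seed.
#' @param exon_count,exon_len,intron_len,intergenic integer ranges
#'   `c(min, max)` sampled per gene/exon.
#' @return list with `genome` (named [Biostrings::DNAStringSet]) and `model`
#'   (a [gene_model] with the genome attached as `sequence_source`).
#' @export
sim_genome <- function(n_genes = 48L, n_contigs = 2L, seed = 1L,
                       exon_count = c(3L, 6L), exon_len = c(150L, 400L),
                       intron_len = c(300L, 1200L),
                       intergenic = c(1500L, 4000L)) {
  with_seed(seed, {
    contig_of <- rep(seq_len(n_contigs), length.out = n_genes)
    seqs <- character(n_contigs)
    exon_rows <- list()
    for (ctg in seq_len(n_contigs)) {
      parts <- character(0)
      cursor <- 0L
      for (g in which(contig_of == ctg)) {
        gap <- sample(intergenic[1]:intergenic[2], 1L)
        parts <- c(parts, rand_dna(gap))
        cursor <- cursor + gap
        n_ex <- sample(exon_count[1]:exon_count[2], 1L)
        strand <- if (g %% 2L == 0L) "-" else "+"
        for (k in seq_len(n_ex)) {
          el <- sample(exon_len[1]:exon_len[2], 1L)
          parts <- c(parts, rand_dna(el))
          exon_rows[[length(exon_rows) + 1L]] <- data.frame(
            chrom = paste0("ctg", ctg), start = cursor, end = cursor + el,
            strand = strand, gene_id = sprintf("G%03d", g),
            transcript_id = sprintf("TX%03d", g), stringsAsFactors = FALSE)
          cursor <- cursor + el
          if (k < n_ex) {
            il <- sample(intron_len[1]:intron_len[2], 1L)
            parts <- c(parts, rand_dna(il))
            cursor <- cursor + il
          }
        }
      }
      parts <- c(parts, rand_dna(1000L))
      seqs[ctg] <- paste(parts, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("ctg", seq_len(n_contigs))
    model <- gene_model(do.call(rbind, exon_rows), sequence_source = genome)
    list(genome = genome, model = model)
  })
}

#' Simulate a cloning-vector backbone with an insert slot
#'
#' Random backbone with a designated slot (standing in for the reporter gene
#' that in-silico cloning replaces with the tested cDNA). Coordinates are
#' 0-based half-open.
#'
#' @param seed RNG seed.
#' @param backbone_len total backbone length outside the slot (default 2000).
#' @param slot_len length of the replaceable slot (default 900).
#' @return list with `seq`, `slot_start`, `slot_end`.
#' @export
sim_vector <- function(seed = 1L, backbone_len = 2000L, slot_len = 900L) {
  with_seed(seed, {
    left <- backbone_len %/% 2L
    list(seq = rand_dna(backbone_len + slot_len),
         slot_start = left, slot_end = left + slot_len)
  })
}

#' Clone a cDNA into a vector backbone
#'
#' Replaces the vector's slot contents with the spliced (intron-free) cDNA
#' and records the two vector-insert junction coordinates.
#'
#' @param vector list with `seq`, `slot_start`, `slot_end` (see
#'   [sim_vector()]).
#' @param cdna non-empty spliced transcript sequence.
#' @return list with `seq` (construct) and `junctions` (0-based insert
#'   start/end within the construct).
#' @examples
#' v <- list(seq = "AAAXXXTTT", slot_start = 3, slot_end = 6)
#' clone_insert(v, "GGCC")  # "AAAGGCCTTT", junctions 3 and 7
#' @export
clone_insert <- function(vector, cdna) {
  stopifnot(nzchar(cdna))
  if (is.null(vector$slot_start) || is.null(vector$slot_end) ||
      vector$slot_end <= vector$slot_start)
    stop("vector has no insert slot")
  L <- nchar(vector$seq)
  seq <- paste0(substr(vector$seq, 1L, vector$slot_start), cdna,
                substr(vector$seq, vector$slot_end + 1L, L))
  list(seq = seq,
       junctions = c(vector$slot_start, vector$slot_start + nchar(cdna)))
}

#' Simulation configuration
#'
#' @param read_length read length in bp (the paper's regimes use 30, 35, 50,
#'   100, 120, 150).
#' @param layout `"paired"` or `"single"`.
#' @param fragment_size insert size for paired layout (default 350 bp).
#' @param coverage target fold coverage of the template.
#' @param error_rate per-base substitution rate (default 0: the error model
#'   is unspecified upstream, and junction arithmetic is exact).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(read_length = 150L, layout = c("paired", "single"),
                       fragment_size = 350L, coverage = 100,
                       error_rate = 0, seed = 0L) {
  layout <- match.arg(layout)
  stopifnot(read_length > 0L, coverage > 0, error_rate >= 0, error_rate < 1)
  if (layout == "paired" && fragment_size < read_length)
    stop("fragment_size must be >= read_length for paired layout")
  structure(list(read_length = as.integer(read_length), layout = layout,
                 fragment_size = as.integer(fragment_size),
                 coverage = coverage, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate reads from a template sequence
#'
#' Uniform fragment start positions; fragment count
#' `ceil(coverage * template_length / (read_length * reads_per_fragment))`.
#' Paired fragments yield a forward R1 and a reverse-complemented R2 from the
#' fragment ends. Deterministic given `cfg$seed`.
#'
#' @param template template sequence (character scalar).
#' @param cfg a [sim_config()].
#' @param id_prefix read-name prefix.
#' @param fastq optional path; when given, reads are written as FASTQ
#'   (interleaved for paired layout).
#' @return data.frame with `qname`, `mate` (0 for single-end), `tstart0`,
#'   `tend0` (template span, 0-based half-open), `seq` (read orientation).
#' @export
simulate_reads <- function(template, cfg, id_prefix = "sim", fastq = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- nchar(template)
  rl <- cfg$read_length
  rpf <- if (cfg$layout == "paired") 2L else 1L
  frag <- if (cfg$layout == "paired") min(cfg$fragment_size, L) else min(rl, L)
  n <- as.integer(ceiling(cfg$coverage * L / (rl * rpf)))
  with_seed(cfg$seed, {
    starts <- sample.int(L - frag + 1L, n, replace = TRUE) - 1L
    if (cfg$layout == "paired") {
      r1 <- data.frame(qname = sprintf("%s_%d", id_prefix, seq_len(n)),
                       mate = 1L, tstart0 = starts, tend0 = starts + rl,
                       stringsAsFactors = FALSE)
      r2 <- data.frame(qname = r1$qname, mate = 2L,
                       tstart0 = starts + frag - rl, tend0 = starts + frag,
                       stringsAsFactors = FALSE)
      reads <- rbind(r1, r2)
      fwd <- substring(template, reads$tstart0 + 1L, reads$tend0)
      reads$seq <- ifelse(reads$mate == 2L, revcomp(fwd), fwd)
    } else {
      reads <- data.frame(qname = sprintf("%s_%d", id_prefix, seq_len(n)),
                          mate = 0L, tstart0 = starts, tend0 = starts + rl,
                          stringsAsFactors = FALSE)
      reads$seq <- substring(template, reads$tstart0 + 1L, reads$tend0)
    }
    if (cfg$error_rate > 0) {
      reads$seq <- vapply(reads$seq, function(s) {
        nerr <- stats::rbinom(1L, nchar(s), cfg$error_rate)
        if (nerr == 0L) return(s)
        pos <- sample.int(nchar(s), nerr)
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
  })
  if (!is.null(fastq)) {
    id <- ifelse(reads$mate > 0L, paste0(reads$qname, "/", reads$mate),
                 reads$qname)
    writeLines(rbind(paste0("@", id), reads$seq, "+",
                     strrep("I", nchar(reads$seq))), fastq)
  }
  reads
}

## ---------------------------------------------------------------------------
## analytic alignment-record construction

## segment map of a construct: vector flanks plus the genomic exons of a
## (plus-strand) transcript in construct coordinate order
construct_segmap <- function(model, transcript_id, junctions, construct_len) {
  tx <- model$exons[model$exons$transcript_id == transcript_id, , drop = FALSE]
  if (any(tx$strand == "-"))
    stop("analytic spike-in supports plus-strand transcripts only")
  tx <- tx[order(tx$start), ]
  widths <- tx$end - tx$start
  cstart <- junctions[1L] + c(0L, cumsum(widths))[seq_len(nrow(tx))]
  segs <- data.frame(type = "exon", chrom = tx$chrom,
                     cstart = cstart, cend = cstart + widths,
                     gstart = tx$start, gend = tx$end,
                     stringsAsFactors = FALSE)
  vec <- data.frame(type = "vector", chrom = NA_character_,
                    cstart = c(0L, junctions[2L]),
                    cend = c(junctions[1L], construct_len),
                    gstart = NA_integer_, gend = NA_integer_,
                    stringsAsFactors = FALSE)
  rbind(vec[1L, ], segs, vec[2L, ])
}

## build an MD tag string for an all-M alignment with mismatches at the
## given 0-based offsets
md_string <- function(m_len, mism_off) {
  if (length(mism_off) == 0L) return(as.character(m_len))
  mism_off <- sort(mism_off)
  out <- character(0)
  prev <- 0L
  for (o in mism_off) {
    out <- c(out, as.character(o - prev), "X")   # placeholder base
    prev <- o + 1L
  }
  c(out, as.character(m_len - prev))
}

## Place contaminant reads from one construct onto the genome. Emulated
## aligner behaviour: longest genomic segment anchors the alignment and the
## rest is soft-clipped; 1-2 bp clips are absorbed as mismatched aligned
## bases (MD tag); junction-spanning reads of <= 30 bp and reads whose
## longest anchor is < 20 bp go unmapped.
place_construct_reads <- function(reads, segmap, genome_chars, read_length) {
  n <- nrow(reads)
  out <- data.frame(qname = reads$qname, mate = reads$mate,
                    mapped = FALSE, rname = NA_character_,
                    pos1 = NA_integer_, cigar = NA_character_,
                    seq = NA_character_, md = NA_character_,
                    reflen = NA_integer_, stringsAsFactors = FALSE)
  exon_segs <- segmap[segmap$type == "exon", , drop = FALSE]
  inner_bounds <- setdiff(unique(c(segmap$cstart, segmap$cend)),
                          c(min(segmap$cstart), max(segmap$cend)))
  ## reference-forward read sequence (R2 was simulated reverse-complemented)
  fwd_all <- reads$seq
  is_r2 <- reads$mate == 2L
  if (any(is_r2)) fwd_all[is_r2] <- revcomp(reads$seq[is_r2])
  tstart <- reads$tstart0
  tend <- reads$tend0
  for (i in seq_len(n)) {
    s <- tstart[i]
    e <- tend[i]
    os <- pmax(s, exon_segs$cstart)
    oe <- pmin(e, exon_segs$cend)
    len <- oe - os
    if (all(len <= 0L)) next                      # pure vector read: unmapped
    spans <- any(inner_bounds > s & inner_bounds < e)
    if (read_length <= 30L && spans) next         # short reads never clipped
    a <- which.max(len)
    if (len[a] < MIN_ANCHOR) next
    seg <- exon_segs[a, ]
    m_start_c <- os[a]
    m_len <- len[a]
    gpos0 <- seg$gstart + (m_start_c - seg$cstart)
    lclip <- m_start_c - s
    rclip <- e - oe[a]
    ctg <- genome_chars[[seg$chrom]]
    mism <- integer(0)
    ## absorb 1-2 bp clips as mismatched aligned bases (recorded in MD):
    ## short overhangs are annotated as mismatches rather than clips
    fwd <- fwd_all[i]
    if (lclip > 0L && lclip <= 2L && gpos0 - lclip >= 0L) {
      ref <- substr(ctg, gpos0 - lclip + 1L, gpos0)
      obs <- substr(fwd, 1L, lclip)
      gpos0 <- gpos0 - lclip
      diff_off <- which(strsplit(ref, "")[[1L]] != strsplit(obs, "")[[1L]]) - 1L
      mism <- c(mism, diff_off)
      m_len <- m_len + lclip
      lclip <- 0L
    }
    if (rclip > 0L && rclip <= 2L &&
        gpos0 + m_len + rclip <= nchar(ctg)) {
      gend0 <- gpos0 + m_len
      ref <- substr(ctg, gend0 + 1L, gend0 + rclip)
      obs <- substr(fwd, nchar(fwd) - rclip + 1L, nchar(fwd))
      diff_off <- which(strsplit(ref, "")[[1L]] != strsplit(obs, "")[[1L]]) - 1L
      mism <- c(mism, m_len + diff_off)
      m_len <- m_len + rclip
      rclip <- 0L
    }
    cigar <- paste0(if (lclip > 0L) paste0(lclip, "S"), m_len, "M",
                    if (rclip > 0L) paste0(rclip, "S"))
    ## MD needs the actual reference base at mismatches
    md <- if (length(mism) == 0L) as.character(m_len) else {
      toks <- md_string(m_len, mism)
      xi <- which(toks == "X")
      refbase <- substring(ctg, gpos0 + sort(mism) + 1L, gpos0 + sort(mism) + 1L)
      toks[xi] <- refbase
      paste(toks, collapse = "")
    }
    out$mapped[i] <- TRUE
    out$rname[i] <- seg$chrom
    out$pos1[i] <- gpos0 + 1L
    out$cigar[i] <- cigar
    out$seq[i] <- fwd                 # reference-forward orientation in SAM
    out$md[i] <- md
    out$reflen[i] <- m_len
  }
  out
}

## assemble SAM flags and mate fields for placed reads (records paired by
## qname); returns a records data.frame ready for write_sam
finalize_records <- function(placed, layout) {
  rec <- placed
  rec$flag <- 0L
  rec$rnext <- "*"
  rec$pnext <- 0L
  rec$tlen <- 0L
  if (layout == "single") {
    rec$flag <- ifelse(rec$mapped, 0L, 4L)
    rec$rname[!rec$mapped] <- "*"
    rec$pos1[!rec$mapped] <- 0L
    rec$cigar[!rec$mapped] <- "*"
    return(rec)
  }
  idx1 <- which(rec$mate == 1L)
  idx2 <- match(rec$qname[idx1], rec$qname[rec$mate == 2L])
  idx2 <- which(rec$mate == 2L)[idx2]
  for (k in seq_along(idx1)) {
    i <- idx1[k]; j <- idx2[k]
    m1 <- rec$mapped[i]; m2 <- rec$mapped[j]
    f1 <- FLAG_PAIRED + FLAG_FIRST
    f2 <- FLAG_PAIRED + FLAG_LAST
    if (m1 && m2) {
      f1 <- f1 + FLAG_PROPER + FLAG_MREVERSE
      f2 <- f2 + FLAG_PROPER + FLAG_REVERSE
      rec$rnext[c(i, j)] <- "="
      rec$pnext[i] <- rec$pos1[j]; rec$pnext[j] <- rec$pos1[i]
      lo <- min(rec$pos1[i], rec$pos1[j])
      hi <- max(rec$pos1[i] + rec$reflen[i], rec$pos1[j] + rec$reflen[j])
      rec$tlen[i] <- if (rec$pos1[i] <= rec$pos1[j]) hi - lo else lo - hi
      rec$tlen[j] <- -rec$tlen[i]
    } else if (m1 || m2) {
      mi <- if (m1) i else j          # mapped one
      ui <- if (m1) j else i
      f_m <- (if (m1) f1 else f2) + FLAG_MUNMAPPED
      f_u <- (if (m1) f2 else f1) + FLAG_UNMAPPED
      if (m1) { f1 <- f_m; f2 <- f_u } else { f2 <- f_m; f1 <- f_u }
      rec$rname[ui] <- rec$rname[mi]
      rec$pos1[ui] <- rec$pos1[mi]
      rec$cigar[ui] <- "*"
      rec$rnext[c(i, j)] <- "="
      rec$pnext[i] <- rec$pos1[j]; rec$pnext[j] <- rec$pos1[i]
    } else {
      f1 <- f1 + FLAG_UNMAPPED + FLAG_MUNMAPPED
      f2 <- f2 + FLAG_UNMAPPED + FLAG_MUNMAPPED
      rec$rname[c(i, j)] <- "*"
      rec$pos1[c(i, j)] <- 0L
      rec$cigar[c(i, j)] <- "*"
    }
    rec$flag[i] <- f1
    rec$flag[j] <- f2
  }
  rec
}

#' Simulate a contamination-free background alignment
#'
#' Clip-free reads over the gene-model exons (padded by `flank`, emulating an
#' exome/open-chromatin experiment) or uniformly over the whole genome. All
#' records are perfect-match (`M`-only, `MD` = read length), so any detected
#' candidate on such a background is a false positive.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param model a [gene_model] (used in `"exome"` mode).
#' @param cfg a [sim_config()]; `coverage` applies to the covered regions.
#' @param mode `"exome"` (exon +/- flank) or `"genome"`.
#' @param flank padding around exons in exome mode (default 200 bp).
#' @param id_prefix read-name prefix.
#' @return records data.frame (internal SAM layout) with attribute `truth`.
#' @export
sim_background <- function(genome, model, cfg, mode = c("exome", "genome"),
                           flank = 200L, id_prefix = "bg") {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "sim_config"))
  rl <- cfg$read_length
  rpf <- if (cfg$layout == "paired") 2L else 1L
  frag <- if (cfg$layout == "paired") cfg$fragment_size else rl
  chars <- lapply(as.list(genome), as.character)
  clens <- vapply(chars, nchar, integer(1))
  if (mode == "exome") {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      model$exons$chrom,
      IRanges::IRanges(pmax(1L, model$exons$start + 1L - flank),
                       model$exons$end + flank)))
    reg <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start0 = GenomicRanges::start(gr) - 1L,
                      end0 = GenomicRanges::end(gr), stringsAsFactors = FALSE)
    reg$end0 <- pmin(reg$end0, clens[reg$chrom])
  } else {
    reg <- data.frame(chrom = names(clens), start0 = 0L, end0 = clens,
                      stringsAsFactors = FALSE)
  }
  reg <- reg[reg$end0 - reg$start0 >= frag, , drop = FALSE]
  rows <- list()
  with_seed(cfg$seed, {
    for (i in seq_len(nrow(reg))) {
      L <- reg$end0[i] - reg$start0[i]
      n <- as.integer(ceiling(cfg$coverage * L / (rl * rpf)))
      starts <- reg$start0[i] + sample.int(L - frag + 1L, n, replace = TRUE) - 1L
      qn <- sprintf("%s_%s_%d_%d", id_prefix, reg$chrom[i], i, seq_len(n))
      ctg <- chars[[reg$chrom[i]]]
      if (cfg$layout == "paired") {
        p1 <- starts; p2 <- starts + frag - rl
        rows[[length(rows) + 1L]] <- data.frame(
          qname = rep(qn, 2L), mate = rep(c(1L, 2L), each = n),
          mapped = TRUE, rname = reg$chrom[i], pos1 = c(p1, p2) + 1L,
          cigar = paste0(rl, "M"),
          seq = substring(ctg, c(p1, p2) + 1L, c(p1, p2) + rl),
          md = as.character(rl), reflen = rl,
          flag = rep(c(99L, 147L), each = n),
          rnext = "=", pnext = c(p2, p1) + 1L,
          tlen = rep(c(frag, -frag), each = n), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          qname = qn, mate = 0L, mapped = TRUE, rname = reg$chrom[i],
          pos1 = starts + 1L, cigar = paste0(rl, "M"),
          seq = substring(ctg, starts + 1L, starts + rl),
          md = as.character(rl), reflen = rl, flag = 0L,
          rnext = "*", pnext = 0L, tlen = 0L, stringsAsFactors = FALSE)
      }
    }
  })
  rec <- do.call(rbind, rows)
  truth <- data.frame(qname = rec$qname, mate = rec$mate,
                      origin = "background", source_cdna = NA_character_,
                      mapped = TRUE, stringsAsFactors = FALSE)
  attr(rec, "truth") <- truth
  rec
}

#' Write alignment records as a sorted, indexed BAM
#'
#' @param records internal records data.frame (from [sim_background()] /
#'   [align_and_spike()]).
#' @param genome named [Biostrings::DNAStringSet] providing `@SQ` lines.
#' @param out output BAM path (`.bam`).
#' @return path of the indexed BAM.
#' @export
write_alignment <- function(records, genome, out) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  md <- ifelse(is.na(records$md), "", paste0("\tMD:Z:", records$md))
  lines <- paste0(records$qname, "\t", records$flag, "\t", records$rname,
                  "\t", records$pos1, "\t",
                  ifelse(records$flag %% 8L >= 4L, 0L, 60L), "\t",
                  records$cigar, "\t", records$rnext, "\t", records$pnext,
                  "\t", records$tlen, "\t", records$seq, "\t*", md)
  writeLines(c(hdr, lines), sam)
  dest <- sub("\\.bam$", "", out)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Spike contaminant construct reads into a background alignment
#'
#' Contaminant reads are placed analytically against the genomic exon
#' coordinates with soft clips computed from the known vector-insert and
#' exon-exon junctions (see details in the package vignette); merged with the
#' background records, sorted and indexed, with a per-read truth table.
#'
#' @param background records data.frame from [sim_background()].
#' @param contaminants named list: per spiked transcript, a list with
#'   `reads` (from [simulate_reads()]) and `segmap` (internal, from the
#'   spiking helpers); usually assembled by [simulate_contaminated()].
#' @param genome named [Biostrings::DNAStringSet].
#' @param cfg the [sim_config()] used for the contaminant reads.
#' @param out output BAM path.
#' @return list with `bam` and `truth` (data.frame: `qname`, `mate`,
#'   `origin`, `source_cdna`, `mapped`).
#' @export
align_and_spike <- function(background, contaminants, genome, cfg, out) {
  chars <- lapply(as.list(genome), as.character)
  placed_all <- list()
  truth_all <- list(attr(background, "truth"))
  for (tx in names(contaminants)) {
    ct <- contaminants[[tx]]
    placed <- place_construct_reads(ct$reads, ct$segmap, chars,
                                    cfg$read_length)
    rec <- finalize_records(placed, cfg$layout)
    placed_all[[tx]] <- rec
    truth_all[[length(truth_all) + 1L]] <- data.frame(
      qname = rec$qname, mate = rec$mate, origin = "contaminant",
      source_cdna = tx, mapped = rec$mapped, stringsAsFactors = FALSE)
  }
  cols <- c("qname", "flag", "rname", "pos1", "cigar", "rnext", "pnext",
            "tlen", "seq", "md")
  rec <- rbind(background[, cols],
               do.call(rbind, lapply(placed_all, function(x) x[, cols])))
  bam <- write_alignment(rec, genome, out)
  list(bam = bam, truth = do.call(rbind, truth_all))
}

#' End-to-end contaminated-experiment simulation
#'
#' Generates (or accepts) a synthetic genome and model, clones `n_cdnas`
#' spliced plus-strand cDNAs into the vector backbone, simulates construct
#' reads at the configured coverage, simulates a clip-free exome-like
#' background, and writes the merged, sorted, indexed contaminated BAM with
#' its truth table.
#'
#' @param world optional list with `genome` and `model` (from
#'   [sim_genome()]); generated from `seed` when omitted.
#' @param n_cdnas number of transcripts to spike (default 20).
#' @param cfg [sim_config()] for the contaminant reads.
#' @param bg_coverage background coverage over exon regions (default 10).
#' @param out output BAM path.
#' @param seed master seed: drives world generation, transcript choice and
#'   per-construct read seeds.
#' @param vector optional [sim_vector()] result.
#' @return list with `bam`, `truth`, `spiked` (transcript ids), `model`,
#'   `genome`, `vector`, `constructs`.
#' @export
simulate_contaminated <- function(out, world = NULL, n_cdnas = 20L,
                                  cfg = sim_config(), bg_coverage = 10,
                                  seed = 1L, vector = NULL) {
  if (is.null(world)) world <- sim_genome(seed = seed)
  if (is.null(vector)) vector <- sim_vector(seed = seed + 101L)
  model <- world$model
  plus_tx <- unique(model$exons$transcript_id[model$exons$strand == "+"])
  if (length(plus_tx) < n_cdnas)
    stop("not enough plus-strand transcripts to spike")
  spiked <- with_seed(seed + 7L, sort(sample(plus_tx, n_cdnas)))
  contaminants <- list()
  constructs <- list()
  for (k in seq_along(spiked)) {
    tx <- spiked[k]
    cdna <- spliced_transcript_seq(model, tx)
    cons <- clone_insert(vector, cdna)
    ccfg <- cfg
    ccfg$seed <- cfg$seed + 1000L + k
    reads <- simulate_reads(cons$seq, ccfg, id_prefix = paste0("cdna_", tx))
    contaminants[[tx]] <- list(
      reads = reads,
      segmap = construct_segmap(model, tx, cons$junctions, nchar(cons$seq)))
    constructs[[tx]] <- cons
  }
  bg_cfg <- cfg
  bg_cfg$coverage <- bg_coverage
  bg_cfg$seed <- seed + 31L
  background <- sim_background(world$genome, model, bg_cfg)
  res <- align_and_spike(background, contaminants, world$genome, cfg, out)
  c(res, list(spiked = spiked, model = model, genome = world$genome,
              vector = vector, constructs = constructs))
}

#' Score detection calls against the simulation truth
#'
#' Read-level: recall = called true mapped contaminant reads / true mapped
#' contaminant reads; precision = called true / called mapped; F1 their
#' harmonic mean. cDNA-level: same definitions over transcript identities.
#' Zero denominators yield `NA` (undefined), never 0.
#'
#' @param called read-level: data.frame with `qname` and `mate` (or a
#'   character vector of `"qname/mate"` keys); cDNA-level: character vector
#'   of transcript ids.
#' @param truth truth table from the simulator.
#' @param level `"read"` or `"cdna"`.
#' @param spiked for `level = "cdna"`: the true spiked transcript ids.
#' @return list with `recall`, `precision`, `f1`, plus the underlying counts.
#' @export
score_detection <- function(called, truth, level = c("read", "cdna"),
                            spiked = NULL) {
  level <- match.arg(level)
  if (level == "read") {
    key <- function(q, m) paste0(q, "/", m)
    called_keys <- if (is.data.frame(called)) key(called$qname, called$mate)
                   else as.character(called)
    called_keys <- unique(called_keys)
    truth$key <- key(truth$qname, truth$mate)
    true_set <- truth$key[truth$origin == "contaminant" & truth$mapped]
    mapped_set <- truth$key[truth$mapped]
    called_mapped <- intersect(called_keys, mapped_set)
    tp <- length(intersect(called_mapped, true_set))
    recall <- if (length(true_set) == 0L) NA_real_ else tp / length(true_set)
    precision <- if (length(called_mapped) == 0L) NA_real_
                 else tp / length(called_mapped)
  } else {
    stopifnot(!is.null(spiked))
    called <- unique(as.character(called))
    tp <- length(intersect(called, spiked))
    recall <- if (length(spiked) == 0L) NA_real_ else tp / length(spiked)
    precision <- if (length(called) == 0L) NA_real_ else tp / length(called)
  }
  f1 <- if (is.na(recall) || is.na(precision) || recall + precision == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(recall = recall, precision = precision, f1 = f1, tp = tp)
}

#' Contaminant read calls of a finished scan
#'
#' The read-level call set: records classified as bona fide contaminant
#' (clip/rescue evidence at boundaries of reported transcripts, plus their
#' mates). Ambiguous reads removed during decontamination are a
#' coverage-rebalancing step, not calls, and are excluded.
#'
#' @param scan a `cdna_scan`.
#' @param bam the scanned BAM (needed to recover mate records).
#' @return data.frame with `qname` and `mate` of called records.
#' @export
called_contaminant_reads <- function(scan, bam = scan$bam) {
  stopifnot(inherits(scan, "cdna_scan"))
  tx_rep <- scan$transcripts$transcript_id[scan$transcripts$reported]
  ex <- scan$exons[scan$exons$transcript_id %in% tx_rep, , drop = FALSE]
  if (nrow(ex) == 0L)
    return(data.frame(qname = character(0), mate = integer(0)))
  keys <- c(boundary_key(ex$chrom, ex$start, "left"),
            boundary_key(ex$chrom, ex$end, "right"))
  ev <- scan$evidence[scan$evidence$key %in% keys, , drop = FALSE]
  ## both mates of an evidence fragment are called
  paired_qn <- unique(ev$qname[ev$mate > 0L])
  out <- unique(rbind(
    data.frame(qname = ev$qname, mate = ev$mate, stringsAsFactors = FALSE),
    data.frame(qname = rep(paired_qn, 2L),
               mate = rep(c(1L, 2L), each = length(paired_qn)),
               stringsAsFactors = FALSE)))
  out[order(out$qname, out$mate), , drop = FALSE]
}
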