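## Detection of cDNA contamination: clipped-read counting at exon boundaries,
## beta-binomial enrichment against a genome-wide background, harmonic-mean /
## BH combination, consensus refinement and mismatch rescue.

## ---------------------------------------------------------------------------
## bulk boundary counting

## Count, for every deduplicated boundary, the reads covering the boundary
## base and the soft-clip evidence whose junction falls within +/- window of
## the boundary on the matching side. A clipped read whose junction lies
## inside the exon does not cover the boundary base, so n_t is the union of
## covering reads and evidence reads (keeps 0 <= n_c <= n_t).
## Offset sign: negative = junction inside the exon, positive = outside.
boundary_tables <- function(reads, bounds, window = 5L, min_clip = 3L) {
  counts <- bounds[, c("key", "chrom", "pos", "side")]
  counts$n_cov <- 0L
  counts$n_c <- 0L
  counts$n_c_exact <- 0L
  counts$n_extra <- 0L
  ev <- list()
  for (ch in unique(bounds$chrom)) {
    bi <- which(bounds$chrom == ch)
    ri <- which(reads$chrom == ch)
    if (length(ri) == 0L) next
    b <- bounds[bi, ]
    r <- reads[ri, ]
    bbase <- ifelse(b$side == "left", b$pos, b$pos - 1L)
    rspan <- IRanges::IRanges(r$start0 + 1L, r$end0)  # shift to 1-based
    cov_hits <- IRanges::findOverlaps(IRanges::IRanges(bbase + 1L, bbase + 1L),
                                      rspan)
    counts$n_cov[bi] <- tabulate(S4Vectors::queryHits(cov_hits),
                                 nbins = length(bi))
    cov_pairs <- paste(S4Vectors::queryHits(cov_hits),
                       S4Vectors::subjectHits(cov_hits))

    for (side in c("left", "right")) {
      bs <- which(b$side == side)
      if (side == "left") {
        rc <- which(r$lclip >= min_clip)
        j <- r$start0[rc]
      } else {
        rc <- which(r$rclip >= min_clip)
        j <- r$end0[rc]
      }
      if (length(bs) == 0L || length(rc) == 0L) next
      win_hits <- IRanges::findOverlaps(
        IRanges::IRanges(b$pos[bs] - window + 1L, b$pos[bs] + window + 1L),
        IRanges::IRanges(j + 1L, j + 1L))
      if (length(win_hits) == 0L) next
      qh <- S4Vectors::queryHits(win_hits)
      sh <- S4Vectors::subjectHits(win_hits)
      bidx <- bs[qh]                       # chrom-local index into b
      rloc <- rc[sh]                       # chrom-local index into r
      off <- if (side == "left") b$pos[bidx] - j[sh] else j[sh] - b$pos[bidx]
      raw <- clip_seq(r$seq[rloc], r$lclip[rloc], r$rclip[rloc], side)
      overhang <- if (side == "left") str_rev(raw) else raw
      ev[[length(ev) + 1L]] <- data.frame(
        key = b$key[bidx],
        row = ri[rloc],
        qname = r$qname[rloc],
        mate = r$mate[rloc],
        offset = off,
        overhang = overhang,
        kind = "clip",
        covers = paste(bidx, rloc) %in% cov_pairs,
        stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(key = character(0), row = integer(0), qname = character(0),
               mate = integer(0), offset = integer(0), overhang = character(0),
               kind = character(0), covers = logical(0),
               stringsAsFactors = FALSE)
  if (nrow(evidence)) {
    tab <- table(evidence$key)
    counts$n_c <- as.integer(tab[counts$key])
    counts$n_c[is.na(counts$n_c)] <- 0L
    tab0 <- table(evidence$key[evidence$offset == 0L])
    counts$n_c_exact <- as.integer(tab0[counts$key])
    counts$n_c_exact[is.na(counts$n_c_exact)] <- 0L
    tabx <- table(evidence$key[!evidence$covers])
    counts$n_extra <- as.integer(tabx[counts$key])
    counts$n_extra[is.na(counts$n_extra)] <- 0L
  }
  counts$n_t <- counts$n_cov + counts$n_extra
  list(counts = counts, evidence = evidence)
}

## ---------------------------------------------------------------------------
## single-boundary surface

#' Scan one exon boundary for clipped-read evidence
#'
#' Counts reads overlapping a boundary base (`n_t`; duplicates, secondary and
#' supplementary alignments and reads below the mapping-quality floor are
#' excluded) and soft-clipped reads whose clip junction lies within
#' `+/- window` of the boundary on the outward side (`n_c`). Overhangs are
#' returned oriented away from the exon: position 1 is the base adjacent to
#' the junction.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param chrom,pos,side boundary: contig, 0-based position (exon start for
#'   `side = "left"`, half-open exon end for `side = "right"`).
#' @param window junction tolerance in bp (default 5).
#' @param mapq mapping-quality floor (default 0).
#' @param min_clip minimum soft-clip length counted as evidence (default 3;
#'   1-2 bp overhangs are handled by the mismatch rescue path).
#' @return list with `n_t`, `n_c`, `overhangs`, `clip_offsets` (signed bp,
#'   negative = inside the exon).
#' @export
scan_boundary <- function(bam, chrom, pos, side = c("left", "right"),
                          window = 5L, mapq = 0L, min_clip = 3L) {
  side <- match.arg(side)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!chrom %in% names(hdr)) {
    warning("contig '", chrom, "' absent from alignment header; boundary skipped")
    return(list(n_t = 0L, n_c = 0L, overhangs = character(0),
                clip_offsets = integer(0)))
  }
  lo <- max(1L, pos - window - 400L)
  region <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, pos + window + 400L))
  reads <- load_reads(bam, region, mapq = mapq)
  bounds <- data.frame(chrom = chrom, pos = as.integer(pos), side = side,
                       key = boundary_key(chrom, pos, side),
                       stringsAsFactors = FALSE)
  bt <- boundary_tables(reads, bounds, window = window, min_clip = min_clip)
  list(n_t = bt$counts$n_t[1L], n_c = bt$counts$n_c[1L],
       overhangs = bt$evidence$overhang, clip_offsets = bt$evidence$offset)
}

## ---------------------------------------------------------------------------
## mismatch rescue

## Reads extending 1-2 bp past a boundary with the extension recorded as
## mismatches (MD tag) rather than clips; rescued when the extension, in
## away-from-exon orientation, is a prefix of the clip consensus.
rescue_from_reads <- function(reads, chrom, pos, side, consensus, max_e = 2L) {
  empty <- data.frame(row = integer(0), qname = character(0),
                      mate = integer(0), ext = character(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(consensus)) return(empty)
  if (side == "left") {
    cand <- which(reads$chrom == chrom & reads$lclip == 0L &
                  reads$start0 >= pos - max_e & reads$start0 < pos)
  } else {
    cand <- which(reads$chrom == chrom & reads$rclip == 0L &
                  reads$end0 > pos & reads$end0 <= pos + max_e)
  }
  if (length(cand) == 0L) return(empty)
  keep <- logical(length(cand))
  exts <- character(length(cand))
  for (i in seq_along(cand)) {
    rr <- reads[cand[i], ]
    if (is.na(rr$md)) next
    e <- if (side == "left") pos - rr$start0 else rr$end0 - pos
    mm <- md_mismatches(rr$cigar, rr$md, rr$seq)
    if (is.null(mm)) next
    refw <- rr$end0 - rr$start0
    want <- if (side == "left") 0:(e - 1L) else (refw - e):(refw - 1L)
    if (!all(want %in% mm$ref_off)) next
    bases <- mm$read_base[match(want, mm$ref_off)]
    if (anyNA(bases)) next
    ext <- paste(bases, collapse = "")
    if (side == "left") ext <- str_rev(ext)  # away-from-exon orientation
    if (identical(substr(consensus, 1L, e), ext)) {
      keep[i] <- TRUE
      exts[i] <- ext
    }
  }
  data.frame(row = cand[keep], qname = reads$qname[cand[keep]],
             mate = reads$mate[cand[keep]], ext = exts[keep],
             stringsAsFactors = FALSE)
}

#' Rescue short overhang reads annotated as mismatches
#'
#' Reads whose 1-2 bp extension past the boundary is recorded as mismatches
#' (via the MD tag) rather than a soft clip are added to the clipped count
#' when the extension is a prefix of the clip consensus at that boundary.
#' Alignments lacking MD annotations disable rescue with a warning.
#'
#' @inheritParams scan_boundary
#' @param consensus non-empty consensus overhang (away-from-exon orientation,
#'   from [build_consensus()]).
#' @return list with `count` and `read_ids` (qnames).
#' @export
rescue_overhang_reads <- function(bam, chrom, pos, side = c("left", "right"),
                                  consensus, mapq = 0L) {
  side <- match.arg(side)
  stopifnot(nzchar(consensus))
  lo <- max(1L, pos - 400L)
  region <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, pos + 400L))
  reads <- load_reads(bam, region, mapq = mapq)
  if (nrow(reads) && all(is.na(reads$md))) {
    warning("alignment lacks MD annotations; mismatch rescue disabled")
    return(list(count = 0L, read_ids = character(0)))
  }
  res <- rescue_from_reads(reads, chrom, as.integer(pos), side, consensus)
  list(count = nrow(res), read_ids = res$qname)
}

## ---------------------------------------------------------------------------
## background model

#' Build the genome-wide clipped-read background
#'
#' Sums, over all deduplicated exon boundaries of the model, the total
#' boundary-overlapping reads (`N_t`) and the soft-clip evidence counts
#' (`N_c`, no mismatch rescue). These parameterise the beta-binomial null as
#' `alpha = N_c`, `beta = N_t - N_c + 1`.
#'
#' @param bam path to a sorted, indexed BAM, or an internal read table.
#' @param model a [gene_model].
#' @inheritParams scan_boundary
#' @return object of class `background_model`: list with `N_c`, `N_t`,
#'   `alpha`, `beta`.
#' @export
build_background <- function(bam, model, window = 5L, mapq = 0L,
                             min_clip = 3L) {
  stopifnot(inherits(model, "gene_model"))
  reads <- if (is.data.frame(bam)) bam else
    load_reads(bam, model_regions(model, bam, window), mapq = mapq)
  bt <- boundary_tables(reads, model$boundaries, window = window,
                        min_clip = min_clip)
  background_from_counts(bt$counts)
}

background_from_counts <- function(counts) {
  N_t <- sum(counts$n_t)
  N_c <- sum(counts$n_c)
  if (N_t == 0L) stop("no reads overlap gene model")
  structure(list(N_c = N_c, N_t = N_t, alpha = N_c, beta = N_t - N_c + 1),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: N_c = %d clipped of N_t = %d boundary reads (alpha = %g, beta = %g)\n",
              x$N_c, x$N_t, x$alpha, x$beta))
  invisible(x)
}

## exon regions (padded) intersected with the alignment header; contigs
## absent from the header are skipped with a warning
model_regions <- function(model, bam, window = 5L, pad = 10L) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  ex <- model$exons
  missing_ctg <- setdiff(unique(ex$chrom), names(hdr))
  if (length(missing_ctg)) {
    warning("contig(s) absent from alignment header, boundaries skipped: ",
            paste(missing_ctg, collapse = ", "))
    ex <- ex[!(ex$chrom %in% missing_ctg), , drop = FALSE]
  }
  if (nrow(ex) == 0L) stop("no gene-model contig present in alignment")
  gr <- GenomicRanges::GRanges(ex$chrom,
          IRanges::IRanges(pmax(1L, ex$start + 1L - window - pad),
                           ex$end + window + pad))
  GenomicRanges::reduce(gr)
}

## ---------------------------------------------------------------------------
## per-exon statistics

## p-values per boundary from a counts table (uses exact or windowed n_c)
counts_pvalues <- function(counts, bg, use = c("exact", "window")) {
  use <- match.arg(use)
  nc <- if (use == "exact") counts$n_c_exact else counts$n_c
  p <- rep(1, nrow(counts))
  idx <- which(nc > 0L)
  for (i in idx) {
    p[i] <- boundary_pvalue(counts$n_t[i], nc[i], bg)
  }
  p
}

## per-exon table joining left/right boundary p-values
exon_pvalue_table <- function(exons, counts, p) {
  lk <- boundary_key(exons$chrom, exons$start, "left")
  rk <- boundary_key(exons$chrom, exons$end, "right")
  li <- match(lk, counts$key)
  ri <- match(rk, counts$key)
  data.frame(exon_id = exons$exon_id,
             transcript_id = exons$transcript_id,
             key_left = lk, key_right = rk,
             p_left = p[li], p_right = p[ri],
             n_t_left = counts$n_t[li], n_c_left = counts$n_c[li],
             n_t_right = counts$n_t[ri], n_c_right = counts$n_c[ri],
             p_exon = combine_exon_pvalues(p[li], p[ri]),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## two-pass candidate calling

#' First-pass screen for candidate contaminant transcripts
#'
#' Uses exact-boundary soft clips only (no window, no rescue): boundary
#' p-values under the background model, harmonic-mean combination per exon
#' and per transcript. Transcripts with transcript-level P < `alpha_level`,
#' or with more than 30\% of exons individually below `alpha_level`, survive;
#' the list is truncated to the `num_initial` most significant.
#'
#' @param bam BAM path (or internal read table).
#' @param model a [gene_model].
#' @param bg a `background_model` from [build_background()].
#' @param alpha_level screen significance level (default 0.05).
#' @param num_initial cap on transcripts passed to refinement (default 1000).
#' @inheritParams scan_boundary
#' @return character vector of screened transcript ids (may be empty).
#' @export
initial_screen <- function(bam, model, bg, alpha_level = 0.05,
                           num_initial = 1000L, window = 5L, mapq = 0L,
                           min_clip = 3L) {
  reads <- if (is.data.frame(bam)) bam else
    load_reads(bam, model_regions(model, bam, window), mapq = mapq)
  bt <- boundary_tables(reads, model$boundaries, window = window,
                        min_clip = min_clip)
  screen_from_tables(model, bt$counts, bg, alpha_level, num_initial)
}

screen_from_tables <- function(model, counts, bg, alpha_level = 0.05,
                               num_initial = 1000L) {
  if (all(counts$n_c_exact == 0L)) return(character(0))
  p <- counts_pvalues(counts, bg, use = "exact")
  et <- exon_pvalue_table(model$exons, counts, p)
  tx <- split(et$p_exon, et$transcript_id)
  tx_p <- vapply(tx, hmp, numeric(1))
  frac_sig <- vapply(tx, function(pp) mean(pp < alpha_level), numeric(1))
  keep <- tx_p < alpha_level | frac_sig > 0.30   # screen: strictly more than 30%
  ids <- names(tx)[keep]
  ids[order(tx_p[keep])][seq_len(min(length(ids), num_initial))]
}

#' Neighbor-exon match of a clip consensus
#'
#' A candidate exon's clip consensus is expected to continue into the
#' neighboring exon of the same transcript (cDNA junction) or into vector
#' sequence. Both arguments are in away-from-exon orientation. A boundary
#' with no neighboring exon (first/last exon) passes automatically, since its
#' overhang is expected to be vector sequence; an empty consensus is no
#' evidence and fails.
#'
#' @param consensus consensus overhang from [build_consensus()].
#' @param neighbor_seq neighboring-exon sequence oriented away from the exon,
#'   or `NA` when no neighbor exists.
#' @param min_match minimum consensus length for a genuine match (default 3).
#' @return logical scalar.
#' @export
neighbor_or_vector_match <- function(consensus, neighbor_seq, min_match = 3L) {
  if (is.na(neighbor_seq)) return(TRUE)       # terminal boundary: vector side
  if (!nzchar(consensus) || nchar(consensus) < min_match) return(FALSE)
  probe <- substr(consensus, 1L, min(nchar(consensus), nchar(neighbor_seq)))
  nchar(probe) >= min_match && grepl(probe, neighbor_seq, fixed = TRUE)
}

## away-oriented neighbor sequence for one exon side; NA when no neighbor or
## no reference is attached (treated as pass-through with a warning upstream)
neighbor_seq_away <- function(model, exon, side, k) {
  if (is.null(model$sequence_source)) return(NA_character_)
  nb <- neighbor_exon_sequence(model, exon, side, k = k)
  if (!nzchar(nb)) return(NA_character_)
  if (side == "left") str_rev(nb) else nb
}

#' Refine screened transcripts and call candidate contaminants
#'
#' For each screened transcript: re-scan its boundaries with the `+/-window`
#' junction tolerance, build clip consensus sequences, rescue 1-2 bp
#' mismatch-annotated overhangs matching the consensus, recompute boundary
#' p-values with the augmented counts, combine per exon (harmonic mean) and
#' correct across all tested exons of all screened transcripts (BH). An exon
#' passes when `q <= qvalue` and its consensus matches a neighboring exon
#' (terminal boundaries pass automatically); a transcript is reported when at
#' least `min_exon_frac` of its exons pass.
#'
#' @inheritParams initial_screen
#' @param screened transcript ids from [initial_screen()].
#' @param qvalue exon-level FDR threshold (default 0.05).
#' @param min_exon_frac reported-transcript threshold (default 0.30).
#' @return list with `exons` and `transcripts` data.frames and the evidence
#'   read table (see [detect_cdna()] for the assembled object).
#' @export
call_candidates <- function(bam, model, bg, screened, window = 5L,
                            qvalue = 0.05, min_exon_frac = 0.30, mapq = 0L,
                            min_clip = 3L) {
  reads <- if (is.data.frame(bam)) bam else
    load_reads(bam, model_regions(model, bam, window), mapq = mapq)
  refine_candidates(reads, model, bg, screened, window = window,
                    qvalue = qvalue, min_exon_frac = min_exon_frac,
                    min_clip = min_clip)
}

refine_candidates <- function(reads, model, bg, screened, window = 5L,
                              qvalue = 0.05, min_exon_frac = 0.30,
                              min_clip = 3L, neighbor_k = 40L) {
  empty_ex <- data.frame(exon_id = character(0), transcript_id = character(0),
                         stringsAsFactors = FALSE)
  empty_tx <- data.frame(transcript_id = character(0), gene_id = character(0),
                         n_exons = integer(0), frac_significant = numeric(0),
                         reported = logical(0), stringsAsFactors = FALSE)
  if (length(screened) == 0L)
    return(list(exons = empty_ex, transcripts = empty_tx,
                evidence = NULL))
  ex <- model$exons[model$exons$transcript_id %in% screened, , drop = FALSE]
  bset <- unique(rbind(
    data.frame(chrom = ex$chrom, pos = ex$start, side = "left",
               stringsAsFactors = FALSE),
    data.frame(chrom = ex$chrom, pos = ex$end, side = "right",
               stringsAsFactors = FALSE)))
  bset$key <- boundary_key(bset$chrom, bset$pos, bset$side)
  bt <- boundary_tables(reads, bset, window = window, min_clip = min_clip)
  counts <- bt$counts
  evidence <- bt$evidence

  no_md <- nrow(reads) > 0L && all(is.na(reads$md))
  if (no_md)
    warning("alignment lacks MD annotations; mismatch rescue disabled")

  ## per boundary: consensus from clip overhangs, then mismatch rescue
  counts$consensus <- ""
  counts$n_rescued <- 0L
  rescue_rows <- list()
  active <- which(counts$n_c > 0L)
  for (i in active) {
    ov <- evidence$overhang[evidence$key == counts$key[i]]
    cons <- build_consensus(ov)
    counts$consensus[i] <- cons
    if (!no_md && nzchar(cons)) {
      rs <- rescue_from_reads(reads, counts$chrom[i], counts$pos[i],
                              counts$side[i], cons)
      if (nrow(rs)) {
        counts$n_rescued[i] <- nrow(rs)
        rescue_rows[[length(rescue_rows) + 1L]] <- data.frame(
          key = counts$key[i], row = rs$row, qname = rs$qname,
          mate = rs$mate, offset = ifelse(counts$side[i] == "left",
                                          counts$pos[i] - reads$start0[rs$row],
                                          reads$end0[rs$row] - counts$pos[i]),
          overhang = rs$ext, kind = "rescue", covers = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rescue_rows))
    evidence <- rbind(evidence, do.call(rbind, rescue_rows))

  counts$n_c_aug <- counts$n_c + counts$n_rescued
  p <- rep(1, nrow(counts))
  for (i in which(counts$n_c_aug > 0L)) {
    p[i] <- boundary_pvalue(counts$n_t[i], counts$n_c_aug[i], bg)
  }

  lk <- boundary_key(ex$chrom, ex$start, "left")
  rk <- boundary_key(ex$chrom, ex$end, "right")
  li <- match(lk, counts$key)
  ri <- match(rk, counts$key)
  et <- data.frame(exon_id = ex$exon_id, transcript_id = ex$transcript_id,
                   gene_id = ex$gene_id, chrom = ex$chrom,
                   start = ex$start, end = ex$end,
                   exon_index = ex$exon_index,
                   n_t_left = counts$n_t[li], n_c_left = counts$n_c_aug[li],
                   n_t_right = counts$n_t[ri], n_c_right = counts$n_c_aug[ri],
                   p_left = p[li], p_right = p[ri],
                   consensus_left = counts$consensus[li],
                   consensus_right = counts$consensus[ri],
                   stringsAsFactors = FALSE)
  et$p_exon <- combine_exon_pvalues(et$p_left, et$p_right)
  et$q_exon <- adjust_qvalues(et$p_exon)   # family: all exons of screened set

  no_ref <- is.null(model$sequence_source)
  if (no_ref)
    warning("model has no sequence_source; neighbor-exon matching skipped ",
            "(treated as matching)")
  et$neighbor_match <- vapply(seq_len(nrow(et)), function(i) {
    if (no_ref) return(TRUE)
    exrow <- ex[i, ]
    nb_l <- neighbor_seq_away(model, exrow, "left",
                              max(neighbor_k, nchar(et$consensus_left[i])))
    nb_r <- neighbor_seq_away(model, exrow, "right",
                              max(neighbor_k, nchar(et$consensus_right[i])))
    neighbor_or_vector_match(et$consensus_left[i], nb_l) ||
      neighbor_or_vector_match(et$consensus_right[i], nb_r)
  }, logical(1))
  et$pass <- et$q_exon <= qvalue & et$neighbor_match

  tx_ids <- unique(et$transcript_id)
  tx <- data.frame(
    transcript_id = tx_ids,
    gene_id = et$gene_id[match(tx_ids, et$transcript_id)],
    n_exons = as.integer(table(et$transcript_id)[tx_ids]),
    stringsAsFactors = FALSE)
  frac <- vapply(split(et$pass, et$transcript_id), mean, numeric(1))
  tx$frac_significant <- frac[tx$transcript_id]
  tx$reported <- tx$frac_significant >= min_exon_frac   # final rule: >= 30%
  tx <- tx[order(-tx$frac_significant, tx$transcript_id), , drop = FALSE]
  rownames(tx) <- NULL

  list(exons = et, transcripts = tx, evidence = evidence)
}

## ---------------------------------------------------------------------------
## main entry point

#' Detect cDNA contamination in a sequencing alignment
#'
#' Two-pass scan of a coordinate-sorted, indexed BAM against an exon-level
#' gene model: a fast screen on exact-boundary soft clips under the
#' beta-binomial background, then refinement of screened transcripts with a
#' `+/-window` junction tolerance, clip-consensus building, 1-2 bp mismatch
#' rescue, BH correction and neighbor-exon matching. Reported transcripts are
#' optionally attributed to a cloning-vector or retrocopy origin with
#' [infer_source()].
#'
#' The scan is single-threaded and fully deterministic (chromosome, then
#' position order): repeated runs on the same inputs give byte-identical
#' reports.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param model a [gene_model] (ideally with a `sequence_source` so
#'   neighbor-exon matching is active).
#' @param window junction tolerance in bp around each boundary (default 5).
#' @param qvalue exon-level FDR threshold (default 0.05).
#' @param min_exon_frac fraction of passing exons needed to report a
#'   transcript (default 0.30).
#' @param num_initial_potential_cdna cap on screened transcripts carried into
#'   refinement (default 1000).
#' @param mapq mapping-quality floor for counted reads (default 0).
#' @param min_clip minimum soft-clip length counted as evidence (default 3).
#' @param vector_db,repeat_db optional FASTA paths (cloning-vector /
#'   repeat-consensus databases) for source inference.
#' @param suppress_retrocopy hide retrocopy/retrocopy-likely calls from the
#'   reported set (recommended for genomic data).
#' @param verbose emit progress messages.
#' @return an object of class `cdna_scan`: list with `transcripts` (candidate
#'   table with `reported` flag and `source` call), `exons` (per-exon
#'   statistics and consensus sequences), `background`, `evidence`
#'   (supporting read table), `screened`, `params`.
#' @seealso [clean_alignment()], [write_candidates()]
#' @export
detect_cdna <- function(bam, model, window = 5L, qvalue = 0.05,
                        min_exon_frac = 0.30,
                        num_initial_potential_cdna = 1000L, mapq = 0L,
                        min_clip = 3L, vector_db = NULL, repeat_db = NULL,
                        suppress_retrocopy = FALSE, verbose = FALSE) {
  stopifnot(inherits(model, "gene_model"))
  regions <- model_regions(model, bam, window)
  reads <- load_reads(bam, regions, mapq = mapq)
  if (nrow(reads) == 0L) stop("no reads overlap gene model")
  msg("loaded ", nrow(reads), " reads over ", length(regions),
      " model regions", verbose = verbose)

  bt <- boundary_tables(reads, model$boundaries, window = window,
                        min_clip = min_clip)
  bg <- background_from_counts(bt$counts)
  msg("background: ", bg$N_c, " clipped of ", bg$N_t, " boundary reads",
      verbose = verbose)

  screened <- screen_from_tables(model, bt$counts, bg,
                                 num_initial = num_initial_potential_cdna)
  msg(length(screened), " transcript(s) pass initial screen",
      verbose = verbose)

  res <- refine_candidates(reads, model, bg, screened, window = window,
                           qvalue = qvalue, min_exon_frac = min_exon_frac,
                           min_clip = min_clip)
  tx <- res$transcripts
  tx$source <- rep(NA_character_, nrow(tx))

  if (nrow(tx)) {
    for (i in which(tx$reported)) {
      sc <- transcript_source(res$exons, res$evidence, tx$transcript_id[i],
                              vector_db = vector_db, repeat_db = repeat_db)
      tx$source[i] <- sc$label
    }
    if (suppress_retrocopy) {
      hide <- tx$reported &
        tx$source %in% c("retrocopy", "retrocopy-likely")
      tx$reported[hide] <- FALSE
    }
  }

  structure(list(transcripts = tx, exons = res$exons, evidence = res$evidence,
                 background = bg, screened = screened,
                 bam = bam,
                 params = list(window = window, qvalue = qvalue,
                               min_exon_frac = min_exon_frac,
                               num_initial_potential_cdna = num_initial_potential_cdna,
                               mapq = mapq, min_clip = min_clip,
                               suppress_retrocopy = suppress_retrocopy)),
            class = "cdna_scan")
}

## 5'/3' terminal consensus + clip offsets of a transcript, fed to
## infer_source. Genomic left end = outward (left) boundary of the first
## genomic exon; right end analogous. Consensus is stored away-from-exon:
## natural orientation for database queries needs the left one reversed.
transcript_source <- function(exon_table, evidence, transcript_id,
                              vector_db = NULL, repeat_db = NULL) {
  et <- exon_table[exon_table$transcript_id == transcript_id, , drop = FALSE]
  et <- et[order(et$start), ]
  first <- et[1L, ]
  last <- et[nrow(et), ]
  key5 <- boundary_key(first$chrom, first$start, "left")
  key3 <- boundary_key(last$chrom, last$end, "right")
  off5 <- evidence$offset[evidence$key == key5 & evidence$kind == "clip"]
  off3 <- evidence$offset[evidence$key == key3 & evidence$kind == "clip"]
  infer_source(str_rev(first$consensus_left), last$consensus_right,
               offsets_5p = off5, offsets_3p = off3,
               vector_db = vector_db, repeat_db = repeat_db)
}

#' Write the candidate report
#'
#' Tab-separated candidate table (one row per screened transcript, with the
#' `reported` flag, per-transcript passing-exon fraction, terminal consensus
#' sequences and inferred source). Coordinates in the companion exon report
#' are printed 1-based inclusive for human review. Output is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param scan a `cdna_scan` from [detect_cdna()].
#' @param path output TSV path.
#' @param exon_path optional path for the per-exon report.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(scan, path, exon_path = NULL) {
  stopifnot(inherits(scan, "cdna_scan"))
  tx <- scan$transcripts
  et <- scan$exons
  tx$consensus_5p <- vapply(tx$transcript_id, function(id) {
    e <- et[et$transcript_id == id, , drop = FALSE]
    e <- e[order(e$start), ]
    str_rev(e$consensus_left[1L])
  }, character(1))
  tx$consensus_3p <- vapply(tx$transcript_id, function(id) {
    e <- et[et$transcript_id == id, , drop = FALSE]
    e <- e[order(e$start), ]
    e$consensus_right[nrow(e)]
  }, character(1))
  tx$n_supporting <- vapply(tx$transcript_id, function(id) {
    sum(et$n_c_left[et$transcript_id == id],
        et$n_c_right[et$transcript_id == id])
  }, numeric(1))
  utils::write.table(format_num_df(tx), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(exon_path)) {
    out <- et
    out$start <- out$start + 1L   # print 1-based inclusive
    utils::write.table(format_num_df(out), exon_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## deterministic numeric formatting for reports
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 6,
                                               format = "g")
  }
  df
}

#' @export
print.cdna_scan <- function(x, ...) {
  n_rep <- sum(x$transcripts$reported)
  cat("cdna_scan:", length(x$screened), "screened transcript(s),",
      n_rep, "reported candidate(s)\n")
  print(x$background)
  if (n_rep) {
    rep_tx <- x$transcripts[x$transcripts$reported, ]
    for (i in seq_len(nrow(rep_tx))) {
      cat(sprintf("  %s (%s): %.0f%% exons passing, source: %s\n",
                  rep_tx$transcript_id[i], rep_tx$gene_id[i],
                  100 * rep_tx$frac_significant[i],
                  rep_tx$source[i] %||% "unknown"))
    }
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.cdna_scan <- function(object, ...) {
  cat("Candidate cDNA scan of", object$bam, "\n")
  print(object)
  if (nrow(object$exons)) {
    cat("\nPer-exon results (screened transcripts):\n")
    cols <- c("exon_id", "n_c_left", "n_c_right", "p_exon", "q_exon",
              "neighbor_match", "pass")
    print(object$exons[, cols], digits = 3)
  }
  invisible(object)
}

#' @exportS3Method base::as.data.frame
as.data.frame.cdna_scan <- function(x, ...) x$transcripts
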