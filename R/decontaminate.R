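## Decontamination: classify reads in reported candidate exons as
## contaminant / genomic / ambiguous, remove contaminants plus a matching
## fraction of ambiguous reads, and write a clean alignment.

#' Ambiguous reads to remove for one exon
#'
#' `nint(R_c / (R_c + R_g) * R_a)`, halves rounded away from zero; 0 when no
#' unambiguous read exists. Removing this fraction of ambiguous reads matches
#' the contaminant-to-genomic ratio observed at the exon boundaries, so
#' estimated true signal inside the exon is preserved.
#'
#' @param R_c,R_g,R_a contaminant / genomic / ambiguous fragment counts.
#' @return integer count in `[0, R_a]`.
#' @examples
#' ambiguous_removal_count(10, 30, 20)  # 5
#' @export
ambiguous_removal_count <- function(R_c, R_g, R_a) {
  stopifnot(R_c >= 0, R_g >= 0, R_a >= 0)
  if (R_c + R_g == 0) return(0L)
  min(nint(R_c / (R_c + R_g) * R_a), as.integer(R_a))
}

#' Classify one read against a candidate exon
#'
#' Three classes: `contaminant` (clip/rescue evidence at a flagged boundary,
#' or mate of such a read), `genomic` (aligned across a boundary into
#' flanking sequence without clip evidence, or properly paired with a mate
#' mapped outside the exon), `ambiguous` (fully contained in the exon with no
#' disambiguating mate).
#'
#' @param read one-row read record (internal load format: `qname`, `flag`,
#'   `chrom`, `start0`, `end0`, `mrnm`, `mpos1`).
#' @param exon one-row exon (`chrom`, `start`, `end`, 0-based half-open).
#' @param evidence_qnames qnames of clip/rescue evidence reads at flagged
#'   boundaries.
#' @return `"contaminant"`, `"genomic"` or `"ambiguous"`.
#' @export
classify_read <- function(read, exon, evidence_qnames) {
  if (read$qname %in% evidence_qnames) return("contaminant")
  if (read$start0 < exon$start || read$end0 > exon$end) return("genomic")
  if (has_flag(read$flag, FLAG_PAIRED) && has_flag(read$flag, FLAG_PROPER) &&
      !is.na(read$mpos1)) {
    mate_out <- is.na(read$mrnm) || read$mrnm != exon$chrom ||
      read$mpos1 - 1L < exon$start || read$mpos1 - 1L >= exon$end
    if (mate_out) return("genomic")
  }
  "ambiguous"
}

#' Plan contaminant-read removal for reported candidates
#'
#' Walks the exons of reported transcripts in scan order (chromosome, then
#' position); each fragment (qname) is claimed by the first exon it overlaps
#' and classified contaminant / genomic / ambiguous (fragment-level: a pair
#' is contaminant if either mate carries clip/rescue evidence, genomic if
#' either mate disambiguates it). Per exon, `R_na =
#' nint(R_c/(R_c+R_g) * R_a)` ambiguous fragments are drawn uniformly without
#' replacement with the seeded generator. Counts are fragment counts, so the
#' removal set size equals `R_na` exactly and no orphaned mates remain.
#'
#' @param bam path to the (sorted, indexed) alignment to clean.
#' @param scan a `cdna_scan` from [detect_cdna()] (alternatively a candidate
#'   TSV path, with `model` supplied).
#' @param model the [gene_model]; required when `scan` is a TSV path.
#' @param seed RNG seed for ambiguous sampling (recorded in the plan).
#' @param mapq,window,min_clip counting parameters, as in [detect_cdna()].
#' @return object of class `clean_plan`: `exons` table (R_c, R_g, R_a, R_na),
#'   `removal_ids` (qnames), `contaminant_ids`, `seed`.
#' @export
plan_decontamination <- function(bam, scan, model = NULL, seed = 0L,
                                 mapq = 0L, window = 5L, min_clip = 3L) {
  if (inherits(scan, "cdna_scan")) {
    tx_rep <- scan$transcripts$transcript_id[scan$transcripts$reported]
    exons <- scan$exons[scan$exons$transcript_id %in% tx_rep, , drop = FALSE]
    evidence <- scan$evidence
    window <- scan$params$window
    min_clip <- scan$params$min_clip
    mapq <- scan$params$mapq
  } else {
    if (is.null(model))
      stop("a gene_model is required when candidates come from a TSV file")
    cand <- utils::read.table(scan, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    tx_rep <- cand$transcript_id[as.logical(cand$reported)]
    exons <- model$exons[model$exons$transcript_id %in% tx_rep, , drop = FALSE]
    evidence <- if (length(tx_rep))
      evidence_for_transcripts(bam, model, tx_rep, window = window,
                               mapq = mapq, min_clip = min_clip)
  }
  empty_plan <- structure(list(
    exons = data.frame(exon_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       R_c = integer(0), R_g = integer(0), R_a = integer(0),
                       R_na = integer(0), stringsAsFactors = FALSE),
    removal_ids = character(0), contaminant_ids = character(0),
    seed = seed), class = "clean_plan")
  if (length(tx_rep) == 0L || nrow(exons) == 0L) return(empty_plan)

  exons <- exons[order(exons$chrom, exons$start, exons$end), , drop = FALSE]
  ## evidence restricted to boundaries of reported transcripts
  keys <- c(boundary_key(exons$chrom, exons$start, "left"),
            boundary_key(exons$chrom, exons$end, "right"))
  contam_qnames <- unique(evidence$qname[evidence$key %in% keys])

  gr <- GenomicRanges::GRanges(exons$chrom,
          IRanges::IRanges(pmax(1L, exons$start + 1L - window - 10L),
                           exons$end + window + 10L))
  reads <- load_reads(bam, gr, mapq = mapq)

  claimed <- character(0)
  plan_rows <- vector("list", nrow(exons))
  removed_ambiguous <- character(0)
  removed_by_exon <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(exons))) {
      e <- exons[i, ]
      ov <- which(reads$chrom == e$chrom & reads$start0 < e$end &
                  reads$end0 > e$start)
      keep_ov <- ov[!(reads$qname[ov] %in% claimed)]
      frags <- unique(reads$qname[keep_ov])
      if (length(frags)) {
        ## vectorised record-level genomic evidence, then fragment roll-up
        rg <- reads[keep_ov, c("qname", "flag", "start0", "end0", "mrnm",
                               "mpos1")]
        spans_out <- rg$start0 < e$start | rg$end0 > e$end
        mate_out <- has_flag(rg$flag, FLAG_PAIRED) &
          has_flag(rg$flag, FLAG_PROPER) & !is.na(rg$mpos1) &
          (is.na(rg$mrnm) | rg$mrnm != e$chrom |
             rg$mpos1 - 1L < e$start | rg$mpos1 - 1L >= e$end)
        rec_gen <- spans_out | mate_out
        frag_gen <- vapply(split(rec_gen, rg$qname), any, logical(1))
        cls <- ifelse(frags %in% contam_qnames, "contaminant",
                      ifelse(frag_gen[frags], "genomic", "ambiguous"))
      } else cls <- character(0)
      R_c <- sum(cls == "contaminant")
      R_g <- sum(cls == "genomic")
      R_a <- sum(cls == "ambiguous")
      R_na <- ambiguous_removal_count(R_c, R_g, R_a)
      amb <- sort(frags[cls == "ambiguous"])
      drop <- if (R_na > 0L) sample(amb, R_na) else character(0)
      removed_ambiguous <- c(removed_ambiguous, drop)
      removed_by_exon[[e$exon_id]] <- drop
      claimed <- c(claimed, frags)
      plan_rows[[i]] <- data.frame(exon_id = e$exon_id, chrom = e$chrom,
                                   start = e$start, end = e$end,
                                   R_c = R_c, R_g = R_g, R_a = R_a,
                                   R_na = R_na, stringsAsFactors = FALSE)
    }
  })
  plan <- do.call(rbind, plan_rows)
  structure(list(exons = plan,
                 removal_ids = sort(unique(c(contam_qnames,
                                             removed_ambiguous))),
                 contaminant_ids = sort(contam_qnames),
                 removed_ambiguous = sort(removed_ambiguous),
                 removed_by_exon = removed_by_exon,
                 seed = seed),
            class = "clean_plan")
}

## Evidence reads (clip + consensus-matched rescue) for given transcripts,
## used when candidates arrive as a TSV and the scan object is not at hand.
evidence_for_transcripts <- function(bam, model, transcript_ids, window = 5L,
                                     mapq = 0L, min_clip = 3L) {
  ex <- model$exons[model$exons$transcript_id %in% transcript_ids, ,
                    drop = FALSE]
  if (nrow(ex) == 0L) stop("transcript ids absent from model")
  gr <- GenomicRanges::GRanges(ex$chrom,
          IRanges::IRanges(pmax(1L, ex$start + 1L - window - 10L),
                           ex$end + window + 10L))
  reads <- load_reads(bam, gr, mapq = mapq)
  bset <- unique(rbind(
    data.frame(chrom = ex$chrom, pos = ex$start, side = "left",
               stringsAsFactors = FALSE),
    data.frame(chrom = ex$chrom, pos = ex$end, side = "right",
               stringsAsFactors = FALSE)))
  bset$key <- boundary_key(bset$chrom, bset$pos, bset$side)
  bt <- boundary_tables(reads, bset, window = window, min_clip = min_clip)
  evidence <- bt$evidence
  no_md <- nrow(reads) > 0L && all(is.na(reads$md))
  for (i in which(bt$counts$n_c > 0L)) {
    if (no_md) break
    cons <- build_consensus(
      evidence$overhang[evidence$key == bt$counts$key[i] &
                        evidence$kind == "clip"])
    if (!nzchar(cons)) next
    rs <- rescue_from_reads(reads, bt$counts$chrom[i], bt$counts$pos[i],
                            bt$counts$side[i], cons)
    if (nrow(rs)) {
      evidence <- rbind(evidence, data.frame(
        key = bt$counts$key[i], row = rs$row, qname = rs$qname,
        mate = rs$mate, offset = 0L, overhang = rs$ext, kind = "rescue",
        covers = TRUE, stringsAsFactors = FALSE))
    }
  }
  evidence
}

#' Write a decontaminated alignment
#'
#' Removes every record of the planned qnames (both mates, plus secondary and
#' supplementary alignments of removed reads) from the alignment and writes a
#' sorted, indexed clean BAM. Records of retained reads are unmodified; the
#' header gains a `@PG` line recording tool, version, seed and parameters
#' (via samtools when available).
#'
#' @param bam input BAM (sorted, indexed).
#' @param plan a `clean_plan` from [plan_decontamination()].
#' @param out output BAM path.
#' @param force overwrite an existing output file.
#' @return the `clean_plan`, invisibly, with `out` recorded.
#' @export
write_clean_alignment <- function(bam, plan, out, force = FALSE) {
  stopifnot(inherits(plan, "clean_plan"))
  if (file.exists(out) && !force)
    stop("output exists: ", out, " (use force = TRUE)")
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("input BAM must be indexed: ", bam)
  drop <- plan$removal_ids
  tmp <- tempfile(fileext = ".bam")
  rules <- S4Vectors::FilterRules(list(keep = function(x) !(x$qname %in% drop)))
  Rsamtools::filterBam(bam, tmp, filter = rules,
                       param = Rsamtools::ScanBamParam(what = "qname"),
                       indexDestination = FALSE)
  add_pg_line(tmp, out, plan$seed)
  unlink(tmp)
  Rsamtools::indexBam(out)
  plan$out <- out
  invisible(plan)
}

## append a @PG header line (samtools reheader); falls back to a plain copy
## with a warning when samtools is unavailable
add_pg_line <- function(bam, out, seed) {
  if (!nzchar(Sys.which("samtools"))) {
    warning("samtools not found; clean BAM written without @PG header line")
    file.copy(bam, out, overwrite = TRUE)
    return(invisible(out))
  }
  hdr <- system2("samtools", c("view", "-H", shQuote(bam)), stdout = TRUE)
  ver <- as.character(utils::packageVersion("cdnascreen"))
  pg <- paste("@PG", "ID:cdnascreen", "PN:cdnascreen",
              paste0("VN:", ver),
              paste0("CL:clean --seed ", seed), sep = "\t")
  hf <- tempfile(fileext = ".sam")
  writeLines(c(hdr, pg), hf)
  status <- system2("samtools", c("reheader", shQuote(hf), shQuote(bam)),
                    stdout = out)
  unlink(hf)
  if (status != 0L) stop("samtools reheader failed")
  invisible(out)
}

#' Detect-then-clean convenience wrapper
#'
#' Plans removal from a finished scan (or candidate TSV) and writes the clean
#' alignment in one call.
#'
#' @inheritParams plan_decontamination
#' @param out output BAM path.
#' @param force overwrite an existing output file.
#' @return the `clean_plan`, invisibly.
#' @export
clean_alignment <- function(bam, scan, out, model = NULL, seed = 0L,
                            force = FALSE) {
  plan <- plan_decontamination(bam, scan, model = model, seed = seed)
  write_clean_alignment(bam, plan, out, force = force)
}

#' @export
print.clean_plan <- function(x, ...) {
  cat("clean_plan:", nrow(x$exons), "candidate exon(s),",
      length(x$contaminant_ids), "contaminant fragment(s),",
      length(x$removal_ids), "fragment(s) removed (seed ", x$seed, ")\n")
  if (nrow(x$exons)) print(x$exons, row.names = FALSE)
  invisible(x)
}

#' Write the per-exon removal report
#'
#' @param plan a `clean_plan`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_clean_report <- function(plan, path) {
  out <- plan$exons
  if (nrow(out)) out$start <- out$start + 1L   # 1-based inclusive for review
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
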