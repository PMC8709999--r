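#' Exon-level gene model
#'
#' Container for the exon intervals that define every boundary position
#' tested for clipped-read enrichment. Coordinates are 0-based half-open
#' internally (alignment convention); GTF input is converted on parse.
#' Strand affects exon numbering (`exon_index` follows transcript order:
#' ascending genomic order on `+`, descending on `-`) but boundary testing is
#' strand-agnostic, since clips are genomic-side events.
#'
#' @param exons data.frame with columns `chrom`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand` (`+`/`-`), `gene_id`,
#'   `transcript_id`, and optionally `exon_index` (assigned from coordinates
#'   when absent).
#' @param sequence_source optional reference sequence for neighbor-exon
#'   lookup: a [Rsamtools::FaFile], a path to an indexed FASTA, or a named
#'   [Biostrings::DNAStringSet].
#' @return an object of class `gene_model`: list with `exons` (sorted by
#'   chrom, start), `boundaries` (deduplicated `chrom`/`pos`/`side` table) and
#'   `sequence_source`.
#' @seealso [build_model_from_gtf()], [read_gene_model()],
#'   [neighbor_exon_sequence()]
#' @export
gene_model <- function(exons, sequence_source = NULL) {
  required <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols))
    stop("exon table lacks columns: ", paste(missing_cols, collapse = ", "))
  exons$chrom <- as.character(exons$chrom)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons$strand <- as.character(exons$strand)
  exons$gene_id <- as.character(exons$gene_id)
  exons$transcript_id <- as.character(exons$transcript_id)
  if (any(exons$start >= exons$end))
    stop("exon with start >= end")
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")

  ## drop transcripts with internally overlapping exons (warn)
  bad <- vapply(split(exons, exons$transcript_id), function(tx) {
    tx <- tx[order(tx$start), ]
    nrow(tx) > 1L && any(tx$start[-1L] < tx$end[-nrow(tx)])
  }, logical(1))
  if (any(bad)) {
    warning("dropping transcript(s) with overlapping exons: ",
            paste(names(bad)[bad], collapse = ", "))
    exons <- exons[!(exons$transcript_id %in% names(bad)[bad]), , drop = FALSE]
  }
  if (nrow(exons) == 0L) stop("gene model is empty")

  ## exon_index in transcript order (strand-aware)
  if (is.null(exons$exon_index) || anyNA(exons$exon_index)) {
    idx <- unlist(lapply(split(seq_len(nrow(exons)), exons$transcript_id),
      function(i) {
        o <- order(exons$start[i])
        r <- integer(length(i))
        r[o] <- if (exons$strand[i[1L]] == "+") seq_along(i)
                else rev(seq_along(i))
        r
      }))
    exons$exon_index <- NA_integer_
    exons$exon_index[unlist(split(seq_len(nrow(exons)), exons$transcript_id))] <- idx
  }
  exons$exon_index <- as.integer(exons$exon_index)
  for (tx in split(exons$exon_index, exons$transcript_id)) {
    if (!setequal(tx, seq_along(tx)))
      stop("exon_index values within a transcript must be consecutive from 1")
  }

  exons <- exons[order(exons$chrom, exons$start, exons$end, exons$transcript_id), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  exons$exon_id <- paste0(exons$transcript_id, ":", exons$exon_index)

  bounds <- rbind(
    data.frame(chrom = exons$chrom, pos = exons$start, side = "left",
               stringsAsFactors = FALSE),
    data.frame(chrom = exons$chrom, pos = exons$end, side = "right",
               stringsAsFactors = FALSE))
  bounds <- unique(bounds)
  bounds <- bounds[order(bounds$chrom, bounds$pos, bounds$side), , drop = FALSE]
  rownames(bounds) <- NULL
  bounds$key <- boundary_key(bounds$chrom, bounds$pos, bounds$side)

  structure(list(exons = exons, boundaries = bounds,
                 sequence_source = sequence_source),
            class = "gene_model")
}

boundary_key <- function(chrom, pos, side) paste(chrom, pos, side, sep = ":")

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$exons), "exons,",
      length(unique(x$exons$transcript_id)), "transcripts,",
      nrow(x$boundaries), "distinct boundaries on",
      length(unique(x$exons$chrom)), "contig(s)\n")
  invisible(x)
}

#' Build a gene model from a GTF annotation
#'
#' Reads a GTF (1-based, inclusive; ensGene/GENCODE dialects with `gene_id`
#' and `transcript_id` attributes), keeps rows of the requested feature type,
#' and converts coordinates to the internal 0-based half-open convention.
#' Single-exon transcripts are retained; transcripts with overlapping exons
#' are dropped with a warning. Malformed GTF rows raise an error naming the
#' offending line.
#'
#' @param gtf_path path to a GTF file.
#' @param feature_filter feature rows to keep (default `"exon"`).
#' @param sequence_source optional reference FASTA / DNAStringSet passed to
#'   [gene_model()].
#' @return a [gene_model].
#' @export
build_model_from_gtf <- function(gtf_path, feature_filter = "exon",
                                 sequence_source = NULL) {
  lines <- readLines(gtf_path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    ln <- which(body)[which(nfield < 9L)[1L]]
    stop("unparseable GTF line ", ln, " in ", gtf_path,
         " (expected >= 9 tab-separated fields)")
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf",
                            feature.type = feature_filter)
  if (length(gr) == 0L)
    stop("no '", feature_filter, "' rows in ", gtf_path)
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$gene_id) || is.null(meta$transcript_id))
    stop("GTF attributes must include gene_id and transcript_id")
  exons <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),            # inclusive end == half-open end
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(meta$gene_id),
    transcript_id = as.character(meta$transcript_id),
    stringsAsFactors = FALSE)
  exons$strand[exons$strand == "*"] <- "+"
  gene_model(exons, sequence_source = sequence_source)
}

#' Write / read the tabular gene-model interchange format
#'
#' Tab-separated with header `chrom start end strand gene_id transcript_id
#' exon_index`; coordinates 0-based half-open, matching the in-memory model,
#' so write/read round-trips are identity. Users may append custom
#' amplicon/transcript rows absent from the source GTF before re-reading.
#'
#' @param model a [gene_model].
#' @param path output (or input) file path.
#' @param sequence_source optional reference passed to [gene_model()] on read.
#' @return `write_gene_model` returns `path` invisibly; `read_gene_model`
#'   returns a [gene_model].
#' @export
write_gene_model <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  cols <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id",
            "exon_index")
  utils::write.table(model$exons[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path, sequence_source = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          gene_id = "character",
                                          transcript_id = "character"))
  gene_model(tab, sequence_source = sequence_source)
}

## fetch reference sequence [start0, end0) for a contig from FaFile / FASTA
## path / DNAStringSet; errors if the contig is absent
ref_fetch <- function(src, chrom, start0, end0) {
  if (end0 <= start0) return("")
  if (is.character(src)) src <- Rsamtools::FaFile(src)
  if (methods::is(src, "FaFile")) {
    info <- Rsamtools::seqinfo(src)
    if (!chrom %in% GenomeInfoDb::seqnames(info))
      stop("contig '", chrom, "' absent from reference FASTA")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
    return(as.character(Rsamtools::scanFa(src, gr)[[1L]]))
  }
  if (methods::is(src, "DNAStringSet") || is.character(names(src))) {
    if (!chrom %in% names(src))
      stop("contig '", chrom, "' absent from reference sequences")
    return(as.character(Biostrings::subseq(src[[chrom]], start0 + 1L, end0)))
  }
  stop("unsupported sequence_source")
}

#' Sequence of the neighboring exon next to a boundary
#'
#' Returns the `k` reference bases of the same-transcript exon genomically
#' adjacent to the queried side of `exon`: the end of the previous exon for
#' `side = "left"`, the start of the next exon for `side = "right"`. Returns
#' `""` when no neighbor exists (first/last exon in genomic order). `k`
#' larger than the neighbor is clamped to the whole neighbor.
#'
#' @param model a [gene_model] with a `sequence_source`.
#' @param exon one row of `model$exons` (or its `exon_id` string).
#' @param side `"left"` or `"right"` (genomic side of the queried boundary).
#' @param k number of bases to return.
#' @return character scalar (natural genomic orientation), possibly `""`.
#' @export
neighbor_exon_sequence <- function(model, exon, side = c("left", "right"),
                                   k = 20L) {
  side <- match.arg(side)
  stopifnot(inherits(model, "gene_model"), k > 0)
  if (is.null(model$sequence_source))
    stop("model has no sequence_source")
  if (is.character(exon) && length(exon) == 1L)
    exon <- model$exons[model$exons$exon_id == exon, , drop = FALSE]
  if (nrow(exon) != 1L) stop("exon must identify exactly one model row")
  sibs <- model$exons[model$exons$transcript_id == exon$transcript_id, ,
                      drop = FALSE]
  if (side == "left") {
    prev <- sibs[sibs$end <= exon$start, , drop = FALSE]
    if (nrow(prev) == 0L) return("")
    nb <- prev[which.max(prev$end), ]
    s0 <- max(nb$start, nb$end - k)
    ref_fetch(model$sequence_source, nb$chrom, s0, nb$end)
  } else {
    nxt <- sibs[sibs$start >= exon$end, , drop = FALSE]
    if (nrow(nxt) == 0L) return("")
    nb <- nxt[which.min(nxt$start), ]
    e0 <- min(nb$end, nb$start + k)
    ref_fetch(model$sequence_source, nb$chrom, nb$start, e0)
  }
}

#' Spliced (intron-free) transcript sequence
#'
#' Concatenates the exon sequences of a transcript in transcript order; for
#' minus-strand transcripts the result is the reverse complement of the
#' genomic concatenation, i.e. the cDNA sense sequence.
#'
#' @param model a [gene_model] with a `sequence_source`.
#' @param transcript_id transcript identifier present in the model.
#' @return character scalar cDNA sequence.
#' @export
spliced_transcript_seq <- function(model, transcript_id) {
  tx <- model$exons[model$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(tx) == 0L) stop("unknown transcript: ", transcript_id)
  tx <- tx[order(tx$start), ]
  seqs <- mapply(function(s, e) ref_fetch(model$sequence_source, tx$chrom[1L], s, e),
                 tx$start, tx$end)
  genomic <- paste(seqs, collapse = "")
  if (tx$strand[1L] == "-") revcomp(genomic) else genomic
}
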