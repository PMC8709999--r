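## Internal alignment access: bulk read loading with the counting filters
## (primary, non-duplicate, mapped, mapping-quality floor), CIGAR soft-clip
## decomposition and MD-tag mismatch extraction.

## flag bits
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MUNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MREVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_LAST <- 0x80L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

## Load primary mapped reads, optionally restricted to regions (GRanges).
## Returns a data.frame with 0-based half-open aligned spans and soft-clip
## lengths at each end. Reads below the mapq floor are dropped (mapq 255 =
## unavailable is kept, matching raw-count semantics).
load_reads <- function(bam, regions = NULL, mapq = 0L) {
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
            "mrnm", "mpos")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- if (is.null(regions)) {
    Rsamtools::ScanBamParam(what = what, tag = "MD", flag = flag)
  } else {
    Rsamtools::ScanBamParam(what = what, tag = "MD", flag = flag,
                            which = GenomicRanges::reduce(regions))
  }
  res <- Rsamtools::scanBam(bam, param = param)
  df <- do.call(rbind, lapply(res, function(r) {
    n <- length(r$qname)
    data.frame(qname = r$qname,
               flag = r$flag,
               chrom = as.character(r$rname),
               pos1 = r$pos,
               mapq = r$mapq,
               cigar = r$cigar,
               seq = if (n) as.character(r$seq) else character(0),
               mrnm = as.character(r$mrnm),
               mpos1 = r$mpos,
               md = if (is.null(r$tag$MD)) rep(NA_character_, n)
                    else as.character(r$tag$MD),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(qname = character(0), flag = integer(0),
                     chrom = character(0), pos1 = integer(0),
                     mapq = integer(0), cigar = character(0),
                     seq = character(0), mrnm = character(0),
                     mpos1 = integer(0), md = character(0),
                     stringsAsFactors = FALSE)
  }
  if (!is.null(regions) && nrow(df)) {
    ## scanBam 'which' emits a record once per overlapped range
    df <- df[!duplicated(paste(df$qname, df$flag, df$chrom, df$pos1, df$cigar)), ,
             drop = FALSE]
  }
  if (mapq > 0L && nrow(df)) {
    keep <- is.na(df$mapq) | df$mapq == 255L | df$mapq >= mapq
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df)) {
    df$start0 <- df$pos1 - 1L
    df$end0 <- df$start0 +
      GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
    clips <- cigar_clips(df$cigar)
    df$lclip <- clips$left
    df$rclip <- clips$right
    df$mate <- ifelse(has_flag(df$flag, FLAG_FIRST), 1L,
                      ifelse(has_flag(df$flag, FLAG_LAST), 2L, 0L))
  } else {
    df$start0 <- df$end0 <- df$lclip <- df$rclip <- df$mate <- integer(0)
  }
  rownames(df) <- NULL
  df
}

## soft-clip lengths at each read end (hard clips may precede/follow)
cigar_clips <- function(cigar) {
  left <- suppressWarnings(as.integer(
    sub("^(?:[0-9]+H)?([0-9]+)S.*$", "\\1", cigar, perl = TRUE)))
  left[is.na(left) | !grepl("^(?:[0-9]+H)?[0-9]+S", cigar, perl = TRUE)] <- 0L
  right <- suppressWarnings(as.integer(
    sub("^.*?([0-9]+)S(?:[0-9]+H)?$", "\\1", cigar, perl = TRUE)))
  right[is.na(right) | !grepl("[0-9]+S(?:[0-9]+H)?$", cigar, perl = TRUE)] <- 0L
  ## a cigar that is pure clip (e.g. "36S") would match both; such records
  ## are unmapped and filtered upstream
  list(left = left, right = right)
}

## clipped read bases at one end, as stored in the record (soft-clipped bases
## are present in SEQ; hard-clipped bases are not)
clip_seq <- function(seq, lclip, rclip, side) {
  if (side == "left") {
    ifelse(lclip > 0L, substr(seq, 1L, lclip), "")
  } else {
    n <- nchar(seq)
    ifelse(rclip > 0L, substr(seq, n - rclip + 1L, n), "")
  }
}

## Parse one CIGAR string into ops/lengths
cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  list(ops = ops, lens = lens)
}

## Map aligned-reference offsets (0-based within the aligned span) to read
## indices (1-based in SEQ) for one record; positions under D/N gaps map NA.
ref_to_read_map <- function(cigar) {
  co <- cigar_ops(cigar)
  refw <- sum(co$lens[co$ops %in% c("M", "D", "N", "=", "X")])
  map <- rep(NA_integer_, refw)
  ri <- 0L   # ref offset consumed
  qi <- 0L   # read index consumed
  for (k in seq_along(co$ops)) {
    op <- co$ops[k]; len <- co$lens[k]
    if (op %in% c("M", "=", "X")) {
      map[(ri + 1L):(ri + len)] <- (qi + 1L):(qi + len)
      ri <- ri + len; qi <- qi + len
    } else if (op %in% c("D", "N")) {
      ri <- ri + len
    } else if (op %in% c("I", "S")) {
      qi <- qi + len
    }
  }
  map
}

## Mismatch positions from the MD tag: returns 0-based offsets within the
## aligned reference span plus the read base observed there. NULL when the
## record has no MD tag.
md_mismatches <- function(cigar, md, seq) {
  if (is.na(md)) return(NULL)
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1L]]
  off <- 0L
  mm_off <- integer(0)
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      off <- off + as.integer(t)
    } else if (startsWith(t, "^")) {
      off <- off + nchar(t) - 1L
    } else {
      mm_off <- c(mm_off, off)
      off <- off + 1L
    }
  }
  if (length(mm_off) == 0L)
    return(data.frame(ref_off = integer(0), read_base = character(0)))
  map <- ref_to_read_map(cigar)
  ## MD offsets are relative to aligned (M/D/N) space and skip inserted bases,
  ## consistent with ref_to_read_map
  idx <- map[mm_off + 1L]
  data.frame(ref_off = mm_off,
             read_base = ifelse(is.na(idx), NA_character_,
                                substring(seq, idx, idx)),
             stringsAsFactors = FALSE)
}
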