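## Shared fixtures: a tiny hand-specified genome + three-exon gene model, and
## helpers to write toy alignments / GTFs. Everything is generated in code at
## test time; nothing binary ships with the package.

## deterministic 1 kb contig (seeded, independent of the package RNG use)
toy_genome <- local({
  set.seed(4242)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""))
  names(g) <- "chr1"
  g
})

toy_ref <- as.character(toy_genome[["chr1"]])

## T1: exons [100,200), [300,400), [500,600) on +; T2 single exon sharing a
## start with T1 exon2 (boundary dedup case)
toy_model <- function(sequence_source = toy_genome) {
  exons <- data.frame(
    chrom = "chr1",
    start = c(100L, 300L, 500L, 300L),
    end = c(200L, 400L, 600L, 420L),
    strand = "+",
    gene_id = c("G1", "G1", "G1", "G2"),
    transcript_id = c("T1", "T1", "T1", "T2"),
    stringsAsFactors = FALSE)
  gene_model(exons, sequence_source = sequence_source)
}

## reference substring helper, 0-based half-open
refseq <- function(start0, end0) substr(toy_ref, start0 + 1L, end0)

## build a SAM record row in the simulator's internal layout
sam_row <- function(qname, flag, pos0, cigar, seq, md = NA_character_,
                    rname = "chr1", rnext = "*", pnext = 0L, tlen = 0L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos1 = pos0 + 1L,
             cigar = cigar, rnext = rnext, pnext = pnext, tlen = tlen,
             seq = seq, md = md, stringsAsFactors = FALSE)
}

## write rows (list of sam_row results) to a sorted indexed BAM
toy_bam <- function(rows, genome = toy_genome,
                    path = tempfile(fileext = ".bam")) {
  rec <- do.call(rbind, rows)
  write_alignment(rec, genome, path)
}

## a perfect-match read of given span
match_read <- function(qname, start0, len = 36L, flag = 0L) {
  sam_row(qname, flag, start0, paste0(len, "M"), refseq(start0, start0 + len),
          md = as.character(len))
}

## a read left-soft-clipped at junction j0 (aligned part starts at j0), with
## given clipped bases prepended
lclip_read <- function(qname, j0, clip, mlen = 26L, flag = 0L) {
  sam_row(qname, flag, j0, paste0(nchar(clip), "S", mlen, "M"),
          paste0(clip, refseq(j0, j0 + mlen)), md = as.character(mlen))
}

## a read right-soft-clipped at junction j0 (aligned part ends at j0)
rclip_read <- function(qname, j0, clip, mlen = 26L, flag = 0L) {
  sam_row(qname, flag, j0 - mlen, paste0(mlen, "M", nchar(clip), "S"),
          paste0(refseq(j0 - mlen, j0), clip), md = as.character(mlen))
}

## a read whose last `e` aligned bases extend past j0 and mismatch the
## reference (observed bases given); MD records the true reference bases
ext_right_read <- function(qname, j0, obs, mlen = 30L, flag = 0L) {
  e <- nchar(obs)
  start0 <- j0 + e - mlen
  ref_main <- refseq(start0, j0)
  ref_ext <- refseq(j0, j0 + e)
  md <- paste0(mlen - e,
               paste(vapply(seq_len(e), function(i) {
                 paste0(substr(ref_ext, i, i), if (i < e) "0" else "")
               }, character(1)), collapse = ""))
  sam_row(qname, flag, start0, paste0(mlen, "M"), paste0(ref_main, obs),
          md = md)
}

## background coverage for a boundary region: n perfect reads overlapping pos0
cover_reads <- function(prefix, pos0, n, len = 36L) {
  lapply(seq_len(n), function(i)
    match_read(paste0(prefix, i), pos0 - len + 2L + (i %% (len - 4L)), len))
}

## small GTF writer (1-based inclusive)
toy_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- vapply(rows, function(r) {
    paste(r$chrom, "src", r$feature %||% "exon", r$start, r$end, ".",
          r$strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s";', r$gene, r$tx),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## one moderately sized spike-in fixture shared across test files (built
## once per test session; ~10 s)
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_contaminated(
        out = file.path(tempdir(), "cached_sim.bam"),
        n_cdnas = 4L,
        cfg = sim_config(read_length = 150L, layout = "paired",
                         coverage = 80, seed = 42L),
        bg_coverage = 10, seed = 42L)
    }
    cache
  }
})
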