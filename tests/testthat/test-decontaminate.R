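## Read classification, the ambiguous-removal formula in action, clean-BAM
## writing, mate consistency and reproducibility.

test_that("classify_read separates contaminant, genomic and ambiguous", {
  exon <- data.frame(chrom = "chr1", start = 300L, end = 420L)
  mk <- function(qname, start0, end0, flag = 0L, mrnm = NA, mpos1 = NA)
    data.frame(qname = qname, flag = flag, chrom = "chr1", start0 = start0,
               end0 = end0, mrnm = mrnm, mpos1 = mpos1,
               stringsAsFactors = FALSE)
  ## clip evidence at a flagged boundary
  expect_equal(classify_read(mk("c1", 300, 326), exon, "c1"), "contaminant")
  ## spans the boundary into the intron without clip evidence
  expect_equal(classify_read(mk("g1", 290, 326), exon, "c1"), "genomic")
  ## proper mate mapped outside the exon
  expect_equal(classify_read(mk("g2", 310, 346, flag = 3L, mrnm = "chr1",
                                mpos1 = 600L), exon, character(0)),
               "genomic")
  ## fully inside with an inside mate: ambiguous
  expect_equal(classify_read(mk("a1", 310, 346, flag = 3L, mrnm = "chr1",
                                mpos1 = 351L), exon, character(0)),
               "ambiguous")
  expect_equal(classify_read(mk("a2", 310, 346), exon, character(0)),
               "ambiguous")
})

## hand fixture around transcript T2 (single exon [300, 420)):
##   2 contaminant clips, 2 genomic spanning reads, 4 ambiguous insiders
##   -> R_na = nint(2/4 * 4) = 2
t2_fixture <- function() {
  clip <- "GGATCCGGAT"
  toy_bam(c(
    list(lclip_read("c1", 300, clip), lclip_read("c2", 300, clip)),
    list(match_read("g1", 290, 40), match_read("g2", 285, 40)),
    lapply(1:4, function(i) match_read(paste0("a", i), 320 + 4L * i, 36))))
}

t2_candidates <- function() {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(transcript_id = "T2", reported = TRUE),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("the plan applies R_na = nint(Rc/(Rc+Rg) * Ra) with exact removal counts", {
  bam <- t2_fixture()
  plan <- plan_decontamination(bam, t2_candidates(), model = toy_model(),
                               seed = 7L)
  row <- plan$exons[plan$exons$exon_id == "T2:1", ]
  expect_equal(row$R_c, 2L)
  expect_equal(row$R_g, 2L)
  expect_equal(row$R_a, 4L)
  expect_equal(row$R_na, 2L)
  expect_length(plan$removed_by_exon[["T2:1"]], 2L)
  expect_setequal(plan$contaminant_ids, c("c1", "c2"))
  expect_true(all(plan$removed_ambiguous %in% paste0("a", 1:4)))
  expect_length(plan$removal_ids, 4L)
})

test_that("clean BAM drops exactly the planned reads and adds a PG line", {
  bam <- t2_fixture()
  plan <- plan_decontamination(bam, t2_candidates(), model = toy_model(),
                               seed = 7L)
  out <- tempfile(fileext = ".bam")
  write_clean_alignment(bam, plan, out)
  kept <- Rsamtools::scanBam(out,
    param = Rsamtools::ScanBamParam(what = "qname"))[[1]]$qname
  expect_length(kept, 8L - length(plan$removal_ids))
  expect_true(all(!kept %in% plan$removal_ids))
  expect_setequal(setdiff(c("g1", "g2"), kept), character(0))
  if (nzchar(Sys.which("samtools"))) {
    hdr <- system2("samtools", c("view", "-H", out), stdout = TRUE)
    expect_true(any(grepl("^@PG\tID:cdnascreen", hdr)))
  }
  ## output collision requires force
  expect_error(write_clean_alignment(bam, plan, out), "force")
  expect_silent(write_clean_alignment(bam, plan, out, force = TRUE))
})

test_that("a zero-candidate plan passes the alignment through unchanged", {
  bam <- toy_bam(cover_reads("b", 300, 6))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(transcript_id = character(0),
                                reported = logical(0)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  plan <- plan_decontamination(bam, f, model = toy_model())
  expect_length(plan$removal_ids, 0L)
  out <- tempfile(fileext = ".bam")
  write_clean_alignment(bam, plan, out)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "cigar"))
  expect_identical(Rsamtools::scanBam(bam, param = p),
                   Rsamtools::scanBam(out, param = p))
})

test_that("removal is reproducible under a seed and removes whole fragments", {
  sim <- cached_sim()
  scan <- detect_cdna(sim$bam, sim$model)
  p1 <- plan_decontamination(sim$bam, scan, seed = 11L)
  p2 <- plan_decontamination(sim$bam, scan, seed = 11L)
  expect_identical(p1$removal_ids, p2$removal_ids)
  expect_identical(p1$exons, p2$exons)
  ## per-exon removed counts equal the formula exactly
  for (i in seq_len(nrow(p1$exons))) {
    e <- p1$exons[i, ]
    expect_equal(length(p1$removed_by_exon[[e$exon_id]] %||% character(0)),
                 ambiguous_removal_count(e$R_c, e$R_g, e$R_a))
  }
  ## cleaning never leaves an orphaned mate: qname sets come out whole
  out <- tempfile(fileext = ".bam")
  write_clean_alignment(sim$bam, p1, out)
  kept <- Rsamtools::scanBam(out, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag")))[[1]]
  paired <- kept$qname[bitwAnd(kept$flag, 0x1L) != 0L &
                       bitwAnd(kept$flag, 0x900L) == 0L]
  expect_true(all(table(paired) == 2L))
})
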