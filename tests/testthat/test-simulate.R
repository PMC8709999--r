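## Simulator: in-silico cloning, read-count arithmetic, determinism,
## analytic junction placement and the scoring metrics.

test_that("clone_insert splices the cDNA into the vector slot", {
  v <- list(seq = "AAAXXXTTT", slot_start = 3L, slot_end = 6L)
  cons <- clone_insert(v, "GGCC")
  expect_equal(cons$seq, "AAAGGCCTTT")
  expect_equal(cons$junctions, c(3L, 7L))
  ## length conservation with a spliced 3-exon transcript
  m <- toy_model()
  cdna <- spliced_transcript_seq(m, "T1")
  vec <- sim_vector(seed = 5)
  c2 <- clone_insert(vec, cdna)
  slot_len <- vec$slot_end - vec$slot_start
  expect_equal(nchar(c2$seq), nchar(vec$seq) - slot_len + nchar(cdna))
  ## a vector without a slot is rejected
  expect_error(clone_insert(list(seq = "AAA", slot_start = 1L,
                                 slot_end = 1L), "GG"), "slot")
})

test_that("fragment counts follow the coverage formula and runs are deterministic", {
  set.seed(1); template10k <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                                    collapse = "")
  cfg <- sim_config(read_length = 150, layout = "paired", coverage = 100,
                    seed = 9)
  reads <- simulate_reads(template10k, cfg)
  expect_equal(nrow(reads), 2L * ceiling(100 * 10000 / (150 * 2)))  # 3334 pairs
  template1k <- substr(template10k, 1, 1000)
  cfg_se <- sim_config(read_length = 50, layout = "single", coverage = 5,
                       seed = 9)
  expect_equal(nrow(simulate_reads(template1k, cfg_se)), 100L)
  ## identical seeds give identical FASTQ bytes
  f1 <- tempfile(); f2 <- tempfile()
  simulate_reads(template1k, cfg_se, fastq = f1)
  simulate_reads(template1k, cfg_se, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  ## paired layout requires fragment >= read length
  expect_error(sim_config(read_length = 150, fragment_size = 100), "fragment")
})

test_that("junction-spanning reads get analytic soft clips; short reads do not", {
  ## toy world: one +-strand 2-exon gene, exon1 60 bp / exon2 90 bp
  set.seed(12)
  g <- Biostrings::DNAStringSet(paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                                      collapse = ""))
  names(g) <- "c1"
  m <- gene_model(data.frame(chrom = "c1", start = c(100L, 300L),
                             end = c(160L, 390L), strand = "+", gene_id = "G",
                             transcript_id = "TX", stringsAsFactors = FALSE),
                  sequence_source = g)
  cdna <- spliced_transcript_seq(m, "TX")       # 150 bp
  vec <- sim_vector(seed = 2, backbone_len = 600, slot_len = 200)
  cons <- clone_insert(vec, cdna)
  segmap <- cdnascreen:::construct_segmap(m, "TX", cons$junctions,
                                          nchar(cons$seq))
  j5 <- cons$junctions[1]
  ## read = exactly the 150 bp cDNA: 60 bp of exon1 + 90 bp of exon2
  reads <- data.frame(qname = c("jr", "inside"), mate = 0L,
                      tstart0 = c(j5, j5 + 60L),
                      tend0 = c(j5 + 150L, j5 + 150L),
                      seq = c(cdna, substr(cdna, 61, 150)),
                      stringsAsFactors = FALSE)
  placed <- cdnascreen:::place_construct_reads(
    reads, segmap, list(c1 = as.character(g[[1]])), 150L)
  jr <- placed[placed$qname == "jr", ]
  expect_true(jr$mapped)
  expect_equal(jr$cigar, "60S90M")              # anchored at the longer exon2
  expect_equal(jr$pos1, 301L)
  expect_equal(substr(jr$seq, 1, 60), refstr <- substr(cdna, 1, 60))
  ## fully-inside read is a plain match record
  expect_equal(placed$cigar[placed$qname == "inside"], "90M")
  ## 30 bp junction read goes unmapped (aligner emits no clips at <= 30 bp)
  r30 <- data.frame(qname = "short", mate = 0L, tstart0 = j5 + 45L,
                    tend0 = j5 + 75L, seq = substr(cdna, 46, 75),
                    stringsAsFactors = FALSE)
  p30 <- cdnascreen:::place_construct_reads(
    r30, segmap, list(c1 = as.character(g[[1]])), 30L)
  expect_false(p30$mapped)
})

test_that("truth table covers every emitted record exactly once", {
  sim <- cached_sim()
  expect_false(any(duplicated(paste(sim$truth$qname, sim$truth$mate))))
  n_rec <- Rsamtools::countBam(sim$bam)$records
  expect_equal(n_rec, nrow(sim$truth))
  ## background + contaminant partition
  expect_setequal(unique(sim$truth$origin), c("background", "contaminant"))
})

test_that("scoring follows the recall/precision/F1 definitions", {
  truth <- data.frame(qname = c("t1", "t2", "b1"), mate = 0L,
                      origin = c("contaminant", "contaminant", "background"),
                      source_cdna = c("TX", "TX", NA), mapped = TRUE,
                      stringsAsFactors = FALSE)
  perfect <- data.frame(qname = c("t1", "t2"), mate = 0L)
  m <- score_detection(perfect, truth)
  expect_equal(c(m$recall, m$precision, m$f1), c(1, 1, 1))
  ## no calls: recall 0, precision undefined (never 0)
  none <- score_detection(data.frame(qname = character(0), mate = integer(0)),
                          truth)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  ## cDNA level: 8 of 10 true plus 1 false call
  called <- c(sprintf("TX%02d", 1:8), "FALSEPOS")
  mc <- score_detection(called, truth = NULL, level = "cdna",
                        spiked = sprintf("TX%02d", 1:10))
  expect_equal(mc$recall, 0.8)
  expect_equal(mc$precision, 8 / 9)
  expect_equal(mc$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
})

test_that("a clip-free synthetic background yields zero candidates", {
  world <- sim_genome(n_genes = 12, seed = 77)
  cfg <- sim_config(read_length = 100, layout = "paired", coverage = 15,
                    seed = 77)
  bg <- sim_background(world$genome, world$model, cfg)
  bam <- write_alignment(bg, world$genome,
                         tempfile(fileext = ".bam"))
  scan <- detect_cdna(bam, world$model)
  expect_equal(sum(scan$transcripts$reported), 0L)
  expect_length(scan$screened, 0L)
})
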