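## Boundary scanning, mismatch rescue, background construction and the
## two-pass screen/refine pipeline on hand-built and simulated alignments.

test_that("scan_boundary counts clips at and around a boundary", {
  clip <- "GGATCCGGAT"
  bam <- toy_bam(c(
    list(lclip_read("clip_exact", 300, clip)),      # junction at boundary
    list(lclip_read("clip_in3", 303, clip)),        # 3 bp inside the exon
    list(lclip_read("clip_far", 320, clip)),        # outside the +/-5 window
    list(match_read("span", 290, 36)),              # plain coverage
    list(match_read("short_clip", 298, 36))))
  ev <- scan_boundary(bam, "chr1", 300, "left", window = 5)
  expect_equal(ev$n_c, 2L)
  expect_setequal(ev$clip_offsets, c(0L, -3L))      # negative = inside exon
  ## overhang oriented away from the exon: position 1 adjacent to junction
  expect_true(all(ev$overhangs %in% paste(rev(strsplit(clip, "")[[1]]),
                                          collapse = "")))
  ## n_t includes plain spanning reads and all evidence reads
  expect_gte(ev$n_t, 4L)
  expect_lte(ev$n_c, ev$n_t)
})

test_that("fully matching reads and sub-minimum clips are not clip evidence", {
  bam <- toy_bam(c(
    list(match_read("m1", 285, 36)),
    list(lclip_read("tiny", 300, "GG"))))           # 2 bp < min_clip
  ev <- scan_boundary(bam, "chr1", 300, "left")
  expect_equal(ev$n_c, 0L)
  expect_equal(ev$n_t, 2L)
  ## absent contig is skipped with a warning, not an error
  expect_warning(ev2 <- scan_boundary(bam, "chrMISSING", 300, "left"),
                 "absent")
  expect_equal(ev2$n_t, 0L)
})

test_that("1-2 bp mismatch overhangs are rescued only when they match the consensus", {
  ref_at_400 <- refseq(400, 401)
  obs1 <- setdiff(c("A", "C", "G", "T"), ref_at_400)[1]
  bam <- toy_bam(c(
    list(ext_right_read("ext1", 400, obs1)),
    list(match_read("fill", 380, 36))))
  ## extension is a prefix of the consensus -> rescued
  r <- rescue_overhang_reads(bam, "chr1", 400, "right",
                             consensus = paste0(obs1, "ATT"))
  expect_equal(r$count, 1L)
  expect_equal(r$read_ids, "ext1")
  ## prefix mismatch -> not rescued
  other <- setdiff(c("A", "C", "G", "T"), c(ref_at_400, obs1))[1]
  r2 <- rescue_overhang_reads(bam, "chr1", 400, "right",
                              consensus = paste0(other, "ATT"))
  expect_equal(r2$count, 0L)
})

test_that("extensions longer than 2 bp are not rescued and no-MD input warns", {
  ref_ext <- refseq(400, 403)
  obs3 <- paste(vapply(strsplit(ref_ext, "")[[1]], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1)), collapse = "")
  bam <- toy_bam(list(ext_right_read("ext3", 400, obs3)))
  r <- rescue_overhang_reads(bam, "chr1", 400, "right",
                             consensus = paste0(obs3, "A"))
  expect_equal(r$count, 0L)
  ## alignment without MD tags: rescue disabled with a warning
  row <- match_read("nomd", 380, 36); row$md <- NA_character_
  bam2 <- toy_bam(list(row))
  expect_warning(r3 <- rescue_overhang_reads(bam2, "chr1", 400, "right",
                                             consensus = "ACGT"),
                 "MD")
  expect_equal(r3$count, 0L)
})

test_that("background model counts clips once per deduplicated boundary", {
  m <- toy_model()
  ## clip-free alignment: N_c = 0, beta = N_t + 1
  bam0 <- toy_bam(cover_reads("b", 300, 10))
  bg0 <- build_background(bam0, m)
  expect_equal(bg0$N_c, 0L)
  expect_equal(bg0$alpha, 0L)
  expect_equal(bg0$beta, bg0$N_t + 1)
  ## boundary chr1:300 left is shared by T1 exon2 and T2 exon1: the clipped
  ## read contributes once to N_c even though two transcripts share it
  bam1 <- toy_bam(c(list(lclip_read("c1", 300, "GGATCCGGAT")),
                    cover_reads("b", 300, 10)))
  bg1 <- build_background(bam1, m)
  expect_equal(bg1$N_c, 1L)
  expect_equal(bg1$alpha, 1L)
  expect_equal(bg1$beta, bg1$N_t - 1L + 1L)
  ## no overlap at all is a hard error
  empty <- toy_bam(list(match_read("far", 900, 36)))
  expect_error(build_background(empty, toy_model()), "no reads overlap")
})

test_that("neighbor_or_vector_match applies the decision table", {
  ## match found in neighbor sequence
  expect_true(neighbor_or_vector_match("GATTC", "GATTCCA"))
  ## empty consensus is no evidence
  expect_false(neighbor_or_vector_match("", "GATTCCA"))
  ## terminal boundary (no neighbor): pass-through
  expect_true(neighbor_or_vector_match("ANYTHING", NA_character_))
  expect_true(neighbor_or_vector_match("", NA_character_))
  ## below the minimum match length
  expect_false(neighbor_or_vector_match("GA", "GATTCCA"))
  ## consensus longer than the fetched neighbor: leading bases decide
  expect_true(neighbor_or_vector_match("GATTC", "GATT"))
})

test_that("clip-free alignments screen to an empty candidate list", {
  m <- toy_model()
  bam <- toy_bam(c(cover_reads("a", 100, 8), cover_reads("b", 300, 8),
                   cover_reads("c", 500, 8)))
  bg <- build_background(bam, m)
  expect_identical(initial_screen(bam, m, bg), character(0))
  scan <- detect_cdna(bam, m)
  expect_equal(sum(scan$transcripts$reported), 0L)
})

test_that("a spiked cDNA is screened, refined and reported end to end", {
  sim <- cached_sim()
  scan <- detect_cdna(sim$bam, sim$model)
  expect_setequal(
    scan$transcripts$transcript_id[scan$transcripts$reported], sim$spiked)
  ## screened list honors the num_initial cap, keeping the most significant
  bg <- build_background(sim$bam, sim$model)
  one <- initial_screen(sim$bam, sim$model, bg, num_initial = 1L)
  expect_length(one, 1L)
  expect_true(one %in% sim$spiked)
  ## per-exon q-values live in [0,1] and passing exons require both the FDR
  ## threshold and the neighbor match
  expect_true(all(scan$exons$q_exon >= 0 & scan$exons$q_exon <= 1))
  expect_true(all(scan$exons$pass == (scan$exons$q_exon <= 0.05 &
                                      scan$exons$neighbor_match)))
})

test_that("the 30% exon rule gates transcript reporting", {
  sim <- cached_sim()
  scan <- detect_cdna(sim$bam, sim$model)
  tx <- scan$transcripts
  expect_true(all(tx$reported == (tx$frac_significant >= 0.30)))
})

test_that("detection output is byte-identical across repeated runs", {
  sim <- cached_sim()
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_candidates(detect_cdna(sim$bam, sim$model), f1)
  write_candidates(detect_cdna(sim$bam, sim$model), f2)
  expect_identical(readLines(f1), readLines(f2))
})
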