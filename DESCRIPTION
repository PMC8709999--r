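Package: cdnascreen
Title: Detection and Removal of cDNA Contamination in DNA Sequencing Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cloned or retrocopied cDNA contamination in DNA sequencing
    alignments (ChIP-seq, ATAC-seq, WES, WGS) by testing for enrichment of
    soft-clipped reads at annotated exon boundaries under a beta-binomial
    background model, combining boundary evidence with the harmonic-mean
    p-value and Benjamini-Hochberg correction. Candidate cDNAs are refined with
    clip-consensus sequences, mismatch-rescued short overhangs and
    neighbor-exon matching, attributed to a cloning-vector or retrocopy origin,
    and optionally removed from the alignment while preserving the estimated
    true genomic signal. A deterministic spike-in simulator generates synthetic
    genomes, in-silico cloned vector constructs and contaminated alignments
    with read-level truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: samtools (header rewriting); NCBI BLAST+ blastn and
    makeblastdb (optional, cDNA source inference)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
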