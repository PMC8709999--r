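---
title: "Detecting and removing cDNA contamination in DNA sequencing alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and removing cDNA contamination in DNA sequencing alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdnascreen)
```

## The problem

Functional-genomics experiments routinely introduce genes on cloning vectors.
Reads derived from such a cloned cDNA — or from trace vector DNA contaminating
a library — map back to the endogenous gene locus and masquerade as genuine
ChIP-seq/ATAC-seq signal or exome coverage, producing spurious peak calls,
copy-number gains and variant calls. Because a cDNA is intron-free, its reads
only partially align at exon boundaries: the part of the read that continues
into the next exon (or into vector backbone) does not match the intron, and
the aligner soft-clips it. Genuine genomic reads, by contrast, cross exon
boundaries fully aligned. `cdnascreen` exploits this asymmetry: it tests every
annotated exon boundary for an excess of clipped reads, aggregates boundary
evidence into exon- and transcript-level calls, attributes candidates to a
vector or a retrocopy origin, and can remove the contaminant reads while
preserving the estimated true signal.

Endogenous retrocopies (reverse-transcribed, genome-reinserted gene copies)
are also intron-free and produce the same clip signature at the parent locus;
the source-inference step and the `suppress_retrocopy` option exist to keep
these from being treated as contamination in genomic (WES/WGS) data.

## Detection model

For a boundary, let `n_t` be the number of reads overlapping the boundary
base and `n_c` the number of soft-clipped (plus rescued, see below) reads
whose clip junction falls within a window of the boundary on the outward
side. Genome-wide totals over all deduplicated model boundaries, `N_c`
clipped of `N_t` overlapping reads, parameterise a beta-binomial null with
`alpha = N_c` and `beta = N_t - N_c + 1`; the boundary p-value is the tail
probability

```
P(X >= n_c) = 1 - sum_{x=0}^{n_c-1} C(n_t, x) B(alpha + x, n_t - x + beta) / B(alpha, beta).
```

The two boundary p-values of an exon are dependent (they share reads), so
they are combined with the unweighted harmonic-mean p-value
`2 / (1/p_left + 1/p_right)`. Combined exon p-values are corrected with
Benjamini–Hochberg, and an exon is a candidate when `q <= 0.05` *and* its
clip consensus matches the neighboring exon (see below). A transcript is
reported when at least 30% of its exons pass.

Detection is two-pass. The screen uses exact-boundary soft clips only and
keeps transcripts whose transcript-level harmonic-mean p-value is below 0.05
or that have *more than* 30% of exons individually below 0.05 (the screen
uses the strict inequality, the final call the inclusive one; both thresholds
appear in the method's description and the distinction is immaterial at
typical exon counts, but it is fixed here so results are deterministic). The
screened list is truncated to the `num_initial_potential_cdna` most
significant transcripts. The refinement pass then re-scans only those
transcripts with the ±`window` junction tolerance, builds consensus
sequences, rescues mismatch-annotated overhangs, recomputes the statistics
and applies the BH correction across all exons of all screened transcripts —
that family scoping matches the two-pass design, rather than correcting
genome-wide.

The transcript-level combination in the screen is the harmonic mean across
exon-level harmonic means; the method description does not name a
transcript-level combiner, and using the same combiner at both levels is the
consistent choice.

### Clip evidence, consensus and rescue

Soft clips shorter than `min_clip = 3` bp are not counted as clip evidence:
a 1–2 bp clip is indistinguishable from sequencing error, and aligners
typically absorb 1–2 bp overhangs as mismatched aligned bases rather than
clips. Those reads are recovered by the *rescue* path instead: a read whose
alignment extends 1–2 bp past the boundary with the extension recorded as
mismatches (MD tag) is added to `n_c` when the extension is a prefix of the
clip consensus at that boundary. Alignments without MD tags disable rescue
with a warning.

Overhangs are stored oriented away from the exon (position 1 adjacent to the
junction), and the consensus is per-column: among overhangs long enough to
reach a column, the base with frequency ≥ 80% is appended; the consensus
stops at the first column without such a base. For an internal boundary the
consensus is expected to continue into the adjacent exon of the same
transcript; a substring match at either boundary keeps the exon. Terminal
boundaries (first/last exon) have no neighboring exon — their overhang is
expected to be vector sequence — and pass the neighbor check automatically.
An empty consensus is no evidence and fails the check. When the model has no
reference sequence attached, neighbor matching cannot be evaluated and is
treated as passing, with a warning.

### Counting conventions

* Reads counted: primary, mapped, non-duplicate records at or above the
  `mapq` floor (default 0, i.e. raw-count semantics; the floor is a knob).
  `n_t` counts alignment records, not fragments.
* A clipped read whose junction is up to `window` bp *inside* the exon does
  not cover the boundary base; to keep `0 <= n_c <= n_t`, `n_t` is defined
  as the union of boundary-covering reads and clip/rescue evidence reads.
* Offsets are signed: negative = junction inside the exon, positive =
  outside; the window is symmetric (default ±5 bp).
* Boundaries shared by several transcripts are deduplicated before
  background totals are formed, so shared reads are counted once.

### Numerical choices

The tail probability is computed in log space from the pmf ratio recurrence
`pmf(x+1)/pmf(x) = (n_t - x)/(x + 1) * (alpha + x)/(beta + n_t - x - 1)`,
and survival values are obtained by summing the pmf from the upper tail
(reverse cumulative sum), so small tails retain full relative precision
instead of cancelling in `1 - cdf`. The test suite checks this route against
an independent direct-summation oracle written with `lchoose`/`lbeta`
arithmetic. `n_c = 0` returns 1 by convention. A perfectly clip-free
background (`alpha = 0`) is degenerate; for `n_c > 0` alpha is clamped to a
half-count pseudocount (0.5) with a warning — any positive clamp preserves
the ranking of boundaries, and a realistic experiment always carries some
background clipping. Exact zero p-values (impossible from the tail formula,
possible from user input) are clamped to the smallest positive double before
harmonic-mean combination. All rounding in removal counts is half away from
zero (`nint`). Scans iterate in (chromosome, position) order and use no
randomness, so detection output is byte-identical across runs.

## Source inference

Terminal overhang consensus sequences (5' and 3' ends of a candidate) are
queried with blastn against a cloning-vector database (UniVec-style FASTA)
and a repeat-consensus database (RepBase-style FASTA); the highest-scoring
hit with E-value ≤ 10 wins. A vector hit labels the candidate `vector`. A
repeat hit labels it `retrocopy` only when the representative clip distance
exceeds 5 bp (retrocopies typically retain UTR sequence that displaces the
clip from the annotated boundary); a repeat hit at ≤ 5 bp falls through to
the distance heuristic, which the method description leaves open. Without a
usable hit the representative distance decides: ≤ 5 bp `vector-likely`,
> 10 bp `retrocopy-likely`, otherwise `unknown`. The representative distance
is the median absolute clip offset over both ends (the description names the
distance but not an aggregator; the median is robust to stray clips). When
the two ends disagree, vector evidence wins — one confirmed vector junction
suffices for contamination. Queries shorter than 8 bp return no hit (short
queries at E ≤ 10 are noise), and a missing blastn degrades gracefully to
the distance rules. With no databases configured, only `-likely`/`unknown`
labels are possible.

## Decontamination

Reads in reported candidate exons fall into three classes: *contaminant*
(clip/rescue evidence at a flagged boundary, or mate of such a read),
*genomic* (aligned across a boundary into flanking sequence without clip
evidence, or properly paired with a mate outside the exon), and *ambiguous*
(fully inside the exon, nothing to disambiguate). All contaminant fragments
are removed; of `R_a` ambiguous fragments,

```
R_na = nint(R_c / (R_c + R_g) * R_a)
```

are drawn uniformly without replacement with a seeded generator and removed,
so the surviving in-exon coverage matches the genomic fraction estimated at
the boundaries and true promoter/exon signal is preserved.

Counts are *fragment* (read-name) counts, not record counts. Two stated
requirements — both mates of a removed read must go, and the ambiguous
removal set must equal `R_na` exactly — conflict at record level whenever
`R_na` is odd and ambiguous reads come in fully-internal pairs; counting
fragments satisfies both exactly. Fragments overlapping two flagged exons
are claimed by the first exon in scan order and planned once. Removal is by
read name, which also drops secondary/supplementary alignments of removed
reads and leaves no orphaned mates. Records outside candidate exons are
never modified or dropped; the output header gains a `@PG` line recording
tool, version and seed. The detect and clean steps are deliberately
separate so candidates can be reviewed before any read is destroyed.

## The simulator: what it emulates, and what it does not

The simulator reproduces the method's validation design at desk scale: cDNAs
are spliced from a synthetic gene model, cloned in silico into a vector
backbone by replacing its insert slot, sequenced as uniform random fragments
(paired 2×`read_length` with 350 bp fragments, or single-end) to a target
coverage, and spiked into a clip-free background. Instead of invoking a real
aligner, alignment records are constructed analytically from the known
junctions: the longest genomic segment of a read anchors the alignment and
the remainder is soft-clipped. (A read spanning an exon–exon junction is
therefore anchored at the *longer* exon segment — the choice a local aligner
makes — not at the first exon.) Junction overhangs of 1–2 bp are absorbed as
mismatched aligned bases with a faithful MD tag, which exercises the rescue
path end to end; junction-spanning reads of ≤ 30 bp are emitted unmapped,
mirroring the observation that the standard aligner produces no clipped
reads at that length; reads whose longest genomic segment is under 20 bp are
likewise unmapped. Each record carries a truth label (background/contaminant,
source transcript, mapped), so recall and precision are exact.

Defaults state the simulated world: 48 genes (half per strand) of 3–6 exons
of 150–400 bp with 300–1200 bp introns on two contigs; a 2 kb backbone with
a 900 bp slot; 350 bp fragments; background coverage 10× over exon regions
±200 bp (exome-like, so the boundary-read scale needed for a stable
background is reached at desk scale; a uniform whole-genome mode exists);
sequencing error 0 (no error model is specified upstream, and exact
junction arithmetic keeps tests sharp — a substitution rate is available for
robustness experiments). Spiked transcripts are drawn from the plus strand
only: the analytic record construction is then a direct coordinate map,
while minus-strand genes still populate the model and the background (a
minus-strand cDNA would behave identically up to reverse complement).

A green simulation test therefore establishes the statistical machinery,
the junction arithmetic and the removal contract — it does not establish
robustness to real aligner idiosyncrasies (multi-mapping, indels near
junctions, supplementary split reads), homologous gene families, adapter
read-through (adapter trimming remains a recommended pre-step), or
non-uniform coverage. The spike-in hook accepts any user-supplied records
table, so a real aligned background can be substituted for fidelity runs.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window` | 5 bp | junction tolerance around a boundary |
| `qvalue` | 0.05 | exon-level FDR threshold |
| `min_exon_frac` | 0.30 | fraction of passing exons to report a transcript |
| `num_initial_potential_cdna` | 1000 | cap on screened transcripts (the original analyses used up to 5000; no default is stated upstream, so the cap is exposed) |
| `mapq` | 0 | mapping-quality floor for counted reads |
| `min_clip` | 3 bp | shortest soft clip counted as evidence |
| `seed` (clean) | 0 | ambiguous-removal RNG seed, always recorded |

## Known limitations

* Vector backbone reads that never map to the reference are invisible here;
  dedicated read-screening tools cover that complementary niche.
* Detection requires a gene model; unannotated or custom constructs must be
  appended to the model file (the interchange format accepts extra rows).
* Source inference depends on overhang length: short-read experiments will
  often yield `-likely`/`unknown` labels.
* Single-threaded by design; the deterministic scan order is part of the
  reproducibility contract.
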