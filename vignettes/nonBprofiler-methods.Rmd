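---
title: "Profiling non-B DNA and coverage depletion in GC-rich genes"
author: "nonBprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling non-B DNA and coverage depletion in GC-rich genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonBprofiler)
```

## The problem

A persistent class of vertebrate genes — in birds especially — is missing
from genome assemblies even though their transcripts are routinely
observed. These genes are GC-rich (often 60–80% GC), their introns and
flanking regions are frequently built almost entirely from short tandem
repeats, and their sequences carry dense arrays of determinants of non-B
DNA structure: G-quadruplex (G4) motifs, and inverted repeats able to fold
into intrastrand hairpins. Such regions depress both the sampling and the
accuracy of sequencing reads. In long-read datasets the symptoms are a
large deficit of aligned bases relative to the dataset's nominal
fold-coverage (down to 5–11% of the expectation), elevated per-read error
(15–25% where 11–15% is routine; beyond ~25% reads become unalignable),
and patchy alignments with uncovered stretches.

`nonBprofiler` packages the complete analysis chain needed to study this
phenomenon quantitatively, and — because the interesting genes are by
definition missing from reference data — a synthetic-data generator that
emulates the gene architectures involved, with machine-readable truth, so
every stage is testable offline.

## Pipeline overview

1. **Annotation** (`scanG4`, `scanTandem`, `scanDyad`, `nonbAnnotation`):
   interval annotations of non-B determinants on a query sequence.
2. **Recruitment** (`recruitReads`): k-mer seeded, banded local alignment
   of a read set against the query, with the length/identity thresholds
   used for long-read searches (min read length 400, min alignment length
   400).
3. **Coverage statistics** (`expectedCoverageBp`, `depletionPercent`,
   `depthProfile`, `coverageReport`): observed aligned bases against the
   expectation `query length × copy number × dataset fold-coverage`,
   plus per-position depth, patchiness and error-rate summaries.
4. **Model building** (`orientReads`, `buildConsensus`,
   `inferGeneStructure`, `modelStats`): consensus reconstruction from
   noisy reads with N-tracts, and exon/intron inference from a cDNA.
5. **Simulation** (`generateGene`, `simulateLongReads`,
   `simulateShortReads`): synthetic gene architectures and reads whose
   sampling and error depend on non-B context.

`runSimulate`, `runProfile` and `runReconstruct` orchestrate these stages
from a validated configuration (`pipelineConfig`), writing FASTA/FASTQ,
BED6, bedGraph, GFF3, TSV and JSON artifacts plus a run manifest. A thin
command-line wrapper (`inst/scripts/nonbprofiler.R`) exposes the same five
stages as subcommands.

## Motif models and conventions

**G4.** The scanner implements the strict motif: four runs of at least
three guanines separated by loops of 1–12 bases, where a loop base may be
any of A, C, G, T (including G). Two conventions needed fixing because the
motif alone does not determine a unique hit set:

* G runs are *maximal*: a run of, say, six G is absorbed into one run
  rather than split to let a motif start earlier. Matches are taken
  leftmost and non-overlapping per strand (the quadparser convention),
  which makes counts deterministic.
* A literal `N` is an *unknown* base, not a wildcard: it cannot be
  asserted to satisfy the motif, so it breaks both runs and loops.

Both strands are scanned; minus-strand hits are reported on forward
coordinates. The minimal motif spans 15 bp (`G3 N1 G3 N1 G3 N1 G3`).

**Tandem repeats.** The default detector is exact: for each period
`p ≤ 20`, maximal runs of `seq[i] == seq[i - p]` with at least 3 copies
and 12 bp length. Exactness is what makes the detector verifiable against
a brute-force enumerator; an approximate mode (bridging isolated
single-base interruptions up to a mismatch fraction) exists for noisy
consensus sequences but is excluded from oracle testing. When one stretch
is describable at several periods (a dinucleotide repeat is also a
4-periodic repeat), only the smallest-period description is kept.

**Dyads.** Arms are matched by reverse complement with Hamming mismatches
only (no gaps), at most one by default, loop at most 50 bp. An arm must
match at its innermost and outermost base pairs — mismatches are interior
only; without the inner-pair condition a mismatch adjacent to the loop
would let any palindrome grow spuriously by one. Overlapping candidates
are reduced to local maxima by arm length (ties: smaller loop, then
leftmost). This detector intentionally stops at sequence candidates; no
thermodynamic stability scoring is attempted.

**GC content** excludes `N` and other ambiguity codes from both numerator
and denominator, and is undefined (`NA`) when no unambiguous base exists.

## Read recruitment and alignment

Recruitment replaces external search tools with an in-package
seed-and-extend aligner so that results are reproducible and free of
version drift. Exact k-mers (default `k = 13`; seeds containing `N` never
match) are collected for the read and its reverse complement, clustered
by diagonal, and each cluster is extended by a banded local alignment
(Smith–Waterman/Gotoh) with scores match +1, mismatch −2, gap open −2,
gap extend −1, and band half-width `max(32, 0.2 × read length)`. These
choices tolerate the ~25% error regime the method must survive; a gap of
length L costs `2 + L`, matching the affine convention of
`Biostrings::pairwiseAlignment`, which serves as the independent
full-matrix oracle in the tests.

Identity counts **all** alignment columns, gaps included — the stricter of
the common conventions — so `alignmentErrorRate` is exactly
`100 − identity`. One best alignment per read per locus is retained
(score, then length, then leftmost); alignments under 75% identity are
flagged low-confidence, reflecting the empirical unalignability of reads
beyond ~25% error. Decision rules follow the stated thresholds exactly
and strictly: a database hit is *positive* iff more than 90% of the query
aligns at identity above 95%; a read file is *contaminated* iff at least
2.5% of its reads align to a contaminant reference.

k = 13 exact seeding is less sensitive than a word-size-5 BLAST search;
at ≥25% error recruitment sensitivity is exercised only against simulated
truth, where the seeded aligner recovers every read the thresholds admit.

## Coverage accounting

`expectedCoverageBp` is the plain product `query length × copy number ×
dataset fold-coverage`; the dataset depth is always a user input (e.g.
60X or 180X), never estimated. The query length is the length of the
supplied sequence — accession coordinate conventions (inclusive vs
half-open) are the caller's concern. `depletionPercent` returns the
observed/expected ratio at full precision; rounding is left to the
caller. Observed bases sum query-interval lengths over retained
alignments; because only one alignment per read per locus is kept,
re-alignment cannot inflate the count. Patchiness is the percent of query
positions with zero alignment depth.

## Consensus building

`buildConsensus` aligns each oriented read to the current model with the
recruitment scoring, accumulates per-column votes, and calls per column:

* majority base among contributing reads; ties broken by the fixed order
  A < C < G < T, and a gap loses ties to bases (a deterministic stand-in
  for the manual curation such alignments traditionally receive);
* a column whose votes are mostly gaps is deleted;
* a new column opens where a strict plurality (> half of the reads
  spanning the junction) insert the same base — conservative, so
  error-driven insertions do not expand the model;
* columns with fewer than `minDepth = 5` non-gap reads are called `N`
  (the depth at which individual long reads were considered to support a
  region), so unalignable or under-covered sections surface as N tracts
  rather than guesses.

Align-and-call iterates until the model is unchanged (at most 5 rounds;
the procedure converges in 1–2 rounds in practice because the seed is
either a cDNA or a near-correct model). At 15 reads with 12% total error
the consensus recovers the simulated truth at ≥99.9% identity in the
package's tests, consistent with the ~15-pass accuracy rule of thumb for
long reads.

`inferGeneStructure` maps a cDNA onto the genomic model with exon-scale
thresholds, splits alignments at deletion runs ≥40 bp (introns), trims
blocks that double-use cDNA bases at ambiguous boundaries, and then
slides each intron boundary by up to ±5 bp — only where the flanking
sequence makes the placement ambiguous, so the spliced product is
unchanged — to expose GT/AG first, then CG/AG (the atypical pair observed
in avian leptin), before accepting a noncanonical pair. The applied shift
and the classification are recorded per intron.

## The simulator: what it emulates, and what it does not

`generateGene` builds genes whose exons are random sequence at a
requested GC percent (achieved exactly up to rounding) and whose introns
are concatenated tandem-repeat blocks — the architecture in which GC-rich
avian genes are found, where tandem motifs are essentially the only
intron content. The truth annotation is produced by running the package's
own scanners on the finished sequence, so truth and detection share one
definition of "non-B".

`simulateLongReads` embeds the gene in 2 kb of random 45%-GC flank per
side, draws candidate reads with log-normal lengths until the naive depth
is reached, and keeps each candidate with probability `(1 − d)^f`, where
`d` is the configured depletion and `f` the fraction of the read
overlapping non-B truth. The exponent form interpolates smoothly between
unaffected reads (`f = 0`) and fully-embedded reads (`f = 1`, acceptance
`1 − d`); the underlying biology reports only net outcomes, and does not
distinguish loss at library construction from loss at sequencing, so the
simulator does not either. Kept reads receive per-position substitutions,
insertions and deletions at class-dependent rates — defaults 12% total
(sub:ins:del = 2:3:1, a long-read-like composition) over background and
20% total over non-B positions, the middle of the 15–25% band — and are
reverse-complemented with probability one half. `simulateShortReads` is
the error-free fixed-length analogue with dropout as the acceptance
probability.

Candidate counts are calibrated to the number of admissible start
positions, so the configured depth is the per-position coverage away from
source edges (for full-length reads it is simply the read count). Without
this calibration interior coverage runs ~`L/(L − readLen + 1)` above
nominal, which would bias depletion estimates by several points.

All randomness flows from one integer seed per call; identical calls are
byte-identical.

**Limitations.** The error model is flat per class: no homopolymer
length-dependent indels, no chimeric reads, no quality values beyond a
constant. Depletion acts per read, not per polymerase kinetics. A passing
depletion-recovery test therefore shows that the *measurement chain*
(simulate → recruit → depth → ratio) is unbiased and correctly scaled —
not that real instruments behave like the model. One practical
consequence discovered in testing and worth stating: in a tract built
from a *single* repeated motif, read placement is ambiguous and alignment
positions pile toward the tract centre, distorting depth locally even
with a perfect aligner. Statistical validation therefore uses tracts
built from dozens of distinct motif blocks (locally repetitive, globally
unique) — closer to real intron architecture, which mixes several motifs
— and measures depth on the tract interior, one read length in from the
edges, to avoid boundary mixtures of depleted and undepleted reads.

## Numerical and testing choices

* Coordinates are 1-based closed inside R (IRanges/GRanges convention)
  and 0-based half-open in BED/bedGraph/TSV outputs; GFF3 is 1-based per
  its own specification.
* Scanner results are validated against brute-force enumerators (explicit
  character-walking implementations, independent of the production code)
  on hundreds of random sequences; the banded aligner is validated
  against `pairwiseAlignment` on instances up to 2 kb. Co-optimal
  alignments may trade a mismatch against gaps, so oracle equality is
  asserted on the optimal *score*.
* Depletion recovery is asserted within 3 percentage points of
  `100 × (1 − d)` for `d ∈ {0, 0.5, 0.9, 0.95}` at 60X over a ~5.9 kb
  tract, averaging five seeded replicates; a single replicate at this
  scale has ~3–4% relative sampling error at `d = 0`, so averaging is
  required for the estimate (not the band) to stabilise.
* Statistical tests use problem sizes of 1–7 kb genes and tens to
  hundreds of reads; these keep the full suite at a few minutes while
  leaving every assertion's sampling error well inside its tolerance.
* The exact-mode tandem detector's default minimum run length (12 bp)
  admits a 9-bp-unit motif only from two copies; a 10 bp dinucleotide run
  (5 copies) is below the default and must be requested with
  `minLen = 10`.

## What the acceptance computation reproduces

`scripts/acceptance.R` rebuilds a 5 kb, 65% GC synthetic gene from 15
full-length simulated reads at 12% total error, starting from a perfect
seed model, and reports the global alignment identity between consensus
and truth — the desk-scale counterpart of the "15 aligned reads give over
99% accuracy" benchmark. Dataset-scale results (catalogue counts,
archive-wide hit rates, real gene models) require the public read
archives and are deliberately out of scope.
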