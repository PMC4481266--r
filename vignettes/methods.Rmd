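---
title: "Methods: transcript refinement and reference-error detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript refinement and reference-error detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`txrefine` refines a fragmented short-read transcript assembly against a
reference genome and then turns the RNA-seq variant calls inside those
transcripts into a screen for small errors in the reference sequence
itself. This vignette documents the models and procedures, the
parameters that matter, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## Coordinates and data model

All internal coordinates are 0-based half-open; GTF is converted to and
from 1-based inclusive at the file boundary and VCF positions stay
1-based. Transcripts are tibbles with one row per exon; an intron is
identified by (chrom, start, end, strand) and *exact* equality of that
key is the concordance unit — exon termini are deliberately not
compared, because assembled 5′ starts and 3′ ends are far more variable
than splice sites. Strand `"."` is a first-class value because
strand-selection protocols can fail; unstranded transcripts are built in
forward genomic orientation and the ORF scanner examines both strands.

## Fragment merging

Two independent merge routes reunite fragmented models.

**Read-linked merging.** Long reads of ≥ 50 nt are reduced to their first
and last 25 bp; a pair is dropped if either segment's mean phred quality
is below 28 (boundary inclusive; a per-base-minimum mode is available as
`quality_mode = "min"` since either reading of a single quality cutoff is
defensible). Segments are aligned to the spliced transcript sequences
exhaustively in both orientations, allowing 1 mismatch; a segment with
more than 3 placements is suppressed entirely rather than reported at its
best 3 — the conservative reading when the goal is to avoid false joins
(a `max_hits` switch restores the other behavior). A read links two
models when the segments hit different transcripts in consistent
orientation on one genomic strand with a span gap ≤ 200,000 bp; the gap
is measured between the closest span ends (midpoint distance would mix
gene length into the rule).

A candidate link is then *refined*: the full read is split at every
position, the prefix placed contiguously within the upstream model's
terminal exon and the suffix within the downstream model's first exon,
minimizing total mismatches (cap 2). The implied intron — prefix end to
suffix start — is accepted only if an annotated intron on the same
chromosome lies within 10 bp at the donor **and** 10 bp at the acceptor;
requiring both ends is the stricter reading of a "within 10 bp" rule and
is the default (`tolerance`). Among mismatch-co-optimal splits, a split
whose intron matches annotation is preferred — the programmatic analogue
of resolving a tie by inspection. A split that would place the junction
strictly inside an exon is rejected (`junction_inside_exon`) because
honoring it would require trimming exonic bases, violating the guarantee
that merging never loses exonic sequence; junctions at or beyond the
terminal exon boundary only extend exons.

**Junction merging.** Non-canonical (non GT-AG in the transcript's
orientation) splice junctions connect two models when the donor
coincides exactly with the end of one model's last exon and the acceptor
with the start of another's first exon. Exact coincidence is the
attachment rule; anything looser would need an arbitrary second
tolerance, and junction coordinates come from the same alignments as the
models. Ambiguous attachments (two models sharing a terminal boundary)
are skipped and logged rather than guessed.

All accepted links are closed transitively: if A links B and B links C,
one merged model results, with the exon union of its members.

## Evidence filtering

Single- and two-exon models are kept only if some evidence sequence
(long reads pooled with coding sequences) aligns with bit score ≥ 400.
The aligner is an exact Smith–Waterman with affine gaps (match +1,
mismatch −2, gap open −5, gap extend −2; a gap of length L costs
`open + L·extend`; N never matches), implemented in C++ and verified
against an independent quadratic DP in the tests. Raw scores convert to
bits as `(λS − ln K)/ln 2` with λ = 1.28, K = 0.46 — the standard
ungapped approximations for +1/−2 scoring, exposed in
`scoring_scheme()` because the cutoff, not the constants, is the
operative rule. The comparison is ≥ 400 (keep at the boundary), matching
the phrasing of a cut-off chosen "to retain". A raw score of 0 is
reported as 0 bits by convention so that absent similarity never passes
any positive threshold. Models with ≥ 3 exons are never filtered: their
splice structure is already evidence.

## Annotation concordance

Gene loci are single-linkage connected components of exonic overlap
(≥ 1 bp, same chromosome and strand, `"."` compatible with both).
Because a locus definition is genuinely underdetermined at this level,
`cluster_loci(mode = "gene_id")` alternatively accepts assembler gene
ids; positional clustering is the default since it needs no upstream
trust. Span overlap with annotated genes is strand-agnostic (a plain
chr:start–stop rule); intron concordance is exact and strand-aware.
Venn regions are labelled E/R/O for Ensembl/RefSeq/OtherRefSeq with
`none` for unannotated. Unplaced-contig transcripts are recognized by a
configurable chromosome-name pattern (default `"Un"`).

## Variant pipeline

Hard filters use strict inequalities — a metric exactly at its threshold
passes — and a record missing a metric skips that rule instead of
failing. That choice is load-bearing: callers omit rank-sum metrics at
homozygous sites, and homozygous sites are exactly where candidate
reference errors live; failing on absence would discard the signal the
pipeline exists to find. HaplotypeScore applies only in genomic mode.
Records whose alleles are neither a pure SNP nor a pure indel
("mixed") are filtered under the indel rules, the conservative bucket.

Indels are normalized by trimming shared suffix then prefix (keeping one
anchor base) and left-shifting through homopolymer runs to the unique
canonical form; normalization is idempotent and the tests verify that
representations at different in-run offsets both canonicalize
identically and produce identical edited sequences. All matching —
against known-variant sets, across comparison datasets, and between RNA
and genomic calls — happens on normalized (chrom, pos, ref, alt) keys;
a position-only mode exists for comparison against allele-less
resources. Support tables bin each allele by the number of comparison
datasets containing it, with 0 reported as "not validated".

Multi-allelic records are stored as one record (one "variant position")
and expanded to per-allele rows for analysis, so position counts and
allele counts stay distinct.

## ORF consequence and error calls

Each variant is applied to its host transcript's spliced sequence one at
a time; co-applying variant pairs is out of scope. The ORF definition is
ATG→stop inclusive, no internal in-frame stop, scanned over three frames
of the sequence and of its reverse complement (both strands by default,
because strandedness is assumed unreliable); ties prefer the forward
scan, then the smaller start offset. A `stop_to_stop` mode reproduces
the looser convention of some ORF finders for sensitivity analysis;
effect labels compare lengths under one convention, so the choice does
not affect classification, only reported absolute lengths. ORFs
truncated by the sequence end are not counted.

An ORF-extending variant is classified by the genotype of the matching
hard-filter-passing genomic record: homozygous-alternate support makes
it a candidate reference error; a mixed call is a real heterozygous
polymorphism; no match is unsupported. Mechanism flags are computed
independently of support: a homopolymer slip adds or removes a base
equal to the genomic base on *either* flank of the normalized event
(which flank is not specified by the underlying idea, so both are
checked); an intron-mimicking deletion has the length of some annotated
intron whose start lies within 10 bp of the deletion start.

## The synthetic-data generator

`simulate_dataset()` builds, from one seed, a reference genome (default
2 chromosomes ≤ 100 kb plus an unplaced contig), 30 genes with GT-AG
introns except a configured non-canonical fraction (0.1), 8 read-linked
and 2 junction-linked fragmentations with 2 linking reads each, 6
unsupported noise models, and 16 ORF-extending variants: 10 homozygous
(3 SNPs, 3 insertions, 4 deletions, one of them a 70 bp
intron-mimicking deletion), 3 heterozygous and 3 unsupported decoys,
plus 4 neutral and 8 single-rule-violating records, and 5 comparison
sets each containing a variant with probability 0.6. These sizes keep a
full run around 15 s on one CPU while leaving every Venn region, filter
rule, support class and mechanism flag populated.

Everything is expressed in reference coordinates, as a real pipeline
would see it. Planted errors are constructed, not sampled: each host
gene's spliced sequence is designed with a long clean ORF, the copy
written into the reference is corrupted (duplicated run base, dropped
base, premature-stop substitution, inserted junk), and the recorded
variant is exactly the edit that reverses the corruption — so the
extending effect holds by construction and is re-verified at emit time.
Two deliberate design details prevent artifacts: sequence upstream of a
planted frameshift (and the junk segment itself) is adenine-free, so no
off-frame ATG can read through the corruption into the stop-free
designed CDS and hand the *corrupted* copy the longer ORF; and
homopolymer variants are re-expressed at right-shifted offsets in half
the comparison sets to exercise normalization.

What the generator does **not** emulate: realistic coverage and
error-rate distributions, quality-score structure beyond pass/fail
boundaries, paralogy and repeats (segment multi-mapping is therefore
rare rather than common), alternative splicing within a locus, and the
assembler's own failure modes beyond clean two-way fragmentation.
Passing the planted-truth suite therefore demonstrates that the decision
logic is implemented exactly, not that the thresholds themselves are
optimal for any particular real dataset.

## Numerical conventions and degenerate inputs

* Strict inequalities at hard-filter thresholds; boundary-inclusive
  comparisons (≥) for bit score 400, mean segment quality 28 and read
  length 50.
* A fully trimmed read is returned empty and flagged, not dropped
  silently; an orphaned mate is dropped and counted.
* Empty evidence databases exclude all 1–2-exon models with a warning.
* `merge_transcript_set` refuses to merge models on conflicting strands
  (an invariant violation upstream, not a resolvable tie).
* Reference-mismatching variant records raise an error during
  normalization rather than propagating silently.
* All randomness flows from one integer seed; identical seeds give
  byte-identical files.

## Known limitations

Split-alignment refinement searches only the terminal exons flanking a
candidate junction, so a linking read whose arm spans more than one exon
of a fragment is rejected rather than spliced — acceptable at desk
scale, conservative in effect. The merge report, not an interactive
review, stands in for manual evaluation of connections. BAM parsing,
genome-scale homology search and genotype-likelihood computation are
explicitly out of scope; alignment records enter as plain tables, and
the local aligner is exact rather than seeded, trading speed for
verifiability.
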